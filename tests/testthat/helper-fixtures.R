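# fixtures built in code; all randomness goes through an explicit seed

demo_records <- function() {
  data.frame(
    taxon_id = c("t1", "t2", "t3", "t4"),
    species = c("spA", "spB", "spC", "spD"),
    family = c("famX", "famX", "famY", "famZ"),
    order = c("ord1", "ord1", "ord1", "ord2"),
    guild = c("predator", "herbivore", "predator", "scavenger"),
    count = c(10L, 5L, 3L, 2L),
    stringsAsFactors = FALSE)
}

demo_table <- function() community_table(demo_records())

# small random community table built independently of simulate_community
random_table <- function(seed, n_taxa = NULL) {
  set.seed(seed)
  if (is.null(n_taxa)) n_taxa <- sample(3:25, 1L)
  n_fam <- sample.int(max(1L, n_taxa %/% 2), 1L)
  n_ord <- sample.int(n_fam, 1L)
  fam <- sample.int(n_fam, n_taxa, replace = TRUE)
  ord_of_fam <- sample.int(n_ord, n_fam, replace = TRUE)
  community_table(data.frame(
    taxon_id = sprintf("r%03d", seq_len(n_taxa)),
    species = sprintf("sp%03d", seq_len(n_taxa)),
    family = sprintf("f%02d", fam),
    order = sprintf("o%02d", ord_of_fam[fam]),
    guild = sample(c("herbivore", "predator", "scavenger", "unknown"),
                   n_taxa, replace = TRUE),
    count = sample(0:60, n_taxa, replace = TRUE),
    stringsAsFactors = FALSE))
}

# random positive abundance vector for likelihood oracles
random_counts <- function(seed, S = NULL, max_count = 200L) {
  set.seed(seed)
  if (is.null(S)) S <- sample(5:40, 1L)
  sort(sample.int(max_count, S, replace = TRUE), decreasing = TRUE)
}

# independent draw of S counts from the zero-truncated log-series pmf,
# by inverse-cdf on an explicitly accumulated table (oracle sampler)
oracle_rlogseries <- function(S, x, nmax = 5e5) {
  p <- exp(seq_len(nmax) * log(x) - log(seq_len(nmax)) - log(-log1p(-x)))
  cp <- cumsum(p)
  findInterval(runif(S) * cp[nmax], cp) + 1L
}
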