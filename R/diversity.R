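#' Shannon-Wiener diversity
#'
#' Computes `H = -sum(p_i log p_i)` in natural log (nats) with
#' `p_i = n_i / N` taken from the observed counts (no bias correction),
#' together with richness S and total abundance N. When `N >= 2` the
#' sampling variance of H and, when `S >= 2`, the Shannon evenness
#' `J = H / log(S)` are filled in as well.
#'
#' @param counts an [abundance_vector()] or positive numeric counts.
#' @return A `diversity_summary`: list with `H`, `varH`, `S`, `N`, `J`
#'   (`varH` is `NA` for N < 2; `J` is `NA` for S = 1, where evenness is
#'   undefined).
#' @seealso [shannon_variance()], [evenness()], [hutcheson_test()]
#' @export
#' @examples
#' shannon(c(5, 5, 5, 5))$H  # log(4)
shannon <- function(counts) {
  av <- as_abundance(counts)
  n <- av$counts
  S <- length(n)
  N <- sum(n)
  p <- n / N
  H <- -sum(p * log(p))
  out <- list(H = H,
              varH = if (N >= 2) shannon_variance(av) else NA_real_,
              S = S, N = N,
              J = if (S >= 2) H / log(S) else NA_real_)
  class(out) <- "diversity_summary"
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("H = %.4f nats (var %.3g), S = %d, N = %d, J = %s\n",
              x$H, x$varH, x$S, x$N,
              if (is.na(x$J)) "undefined" else sprintf("%.4f", x$J)))
  invisible(x)
}

#' Sampling variance of the Shannon index
#'
#' Hutcheson's large-sample variance of H:
#' `varH = (sum p (log p)^2 - (sum p log p)^2) / N + (S - 1) / (2 N^2)`.
#'
#' @param counts an [abundance_vector()] or positive numeric counts with
#'   total `N >= 2`.
#' @return The estimated variance (a non-negative scalar).
#' @export
shannon_variance <- function(counts) {
  av <- as_abundance(counts)
  n <- av$counts
  N <- sum(n)
  if (N < 2) stop("variance of H needs N >= 2 individuals", call. = FALSE)
  S <- length(n)
  p <- n / N
  lp <- log(p)
  max(0, (sum(p * lp^2) - sum(p * lp)^2) / N + (S - 1) / (2 * N^2))
}

#' Shannon evenness
#'
#' `J = H / log(S)`; undefined (returned as `NA`) for a single group,
#' where `log(S) = 0`.
#'
#' @param x a `diversity_summary` from [shannon()], or counts.
#' @return Evenness in `[0, 1]`, or `NA` when S = 1.
#' @export
evenness <- function(x) {
  if (!inherits(x, "diversity_summary")) x <- shannon(x)
  if (x$S < 2) return(NA_real_)
  x$H / log(x$S)
}

#' Hutcheson's t-test for two Shannon indices
#'
#' Modification of the two-sample t-test for diversity indices:
#' `t = (H_a - H_b) / sqrt(varH_a + varH_b)` with Welch-type degrees of
#' freedom `df = (varH_a + varH_b)^2 / (varH_a^2/N_a + varH_b^2/N_b)` and a
#' two-sided p-value from the t distribution. Swapping the samples negates
#' t and leaves p unchanged.
#'
#' @param a,b abundance vectors (or positive numeric counts) for the two
#'   samples; each needs `N >= 2`.
#' @return An object of class `htest` with the t statistic, degrees of
#'   freedom, p-value, and the two H estimates.
#' @export
#' @examples
#' hutcheson_test(c(10, 10, 10), c(28, 1, 1))
hutcheson_test <- function(a, b) {
  sa <- shannon(a)
  sb <- shannon(b)
  va <- sa$varH
  vb <- sb$varH
  if (is.na(va) || is.na(vb)) {
    stop("both samples need N >= 2 individuals", call. = FALSE)
  }
  if (va + vb <= 0) {
    stop("degenerate input: both samples have zero variance of H ",
         "(single-species samples)", call. = FALSE)
  }
  t_stat <- (sa$H - sb$H) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / sa$N + vb^2 / sb$N)
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  structure(list(
    statistic = c(t = t_stat),
    parameter = c(df = df),
    p.value = p,
    estimate = c(`H of a` = sa$H, `H of b` = sb$H),
    method = "Hutcheson's t-test for Shannon diversity",
    alternative = "two.sided",
    data.name = paste(deparse1(substitute(a)), "and",
                      deparse1(substitute(b)))),
    class = "htest")
}
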