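#' Tally abundance and family richness by trophic guild
#'
#' Sums individuals per guild (herbivore, predator, scavenger) and counts,
#' per guild, the distinct families with at least one individual of that
#' guild. Guild membership is assigned at the record (species) level, so a
#' family may contribute to several guilds. Records labelled `"unknown"`
#' (undetermined taxa, juveniles) are excluded from the tally and their
#' individual count is logged in the attributes.
#'
#' @param x a [community_table()] with guild labels.
#' @return A `guild_tally`: data frame with columns `guild`, `abundance`,
#'   `family_richness` (one row per guild, fixed order), with attributes
#'   `n_unknown_individuals` and `n_unknown_records`.
#' @export
tally_guilds <- function(x) {
  stopifnot(inherits(x, "community_table"))
  known <- x$guild != "unknown"
  if (!any(known)) stop("all records have guild 'unknown'", call. = FALSE)
  g <- guild_levels()
  sub <- as.data.frame(x)[known, , drop = FALSE]
  abundance <- vapply(g, function(gg) sum(sub$count[sub$guild == gg]),
                      numeric(1))
  fam_rich <- vapply(g, function(gg) {
    length(unique(sub$family[sub$guild == gg & sub$count > 0]))
  }, integer(1))
  out <- data.frame(guild = g, abundance = as.integer(abundance),
                    family_richness = fam_rich, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            n_unknown_individuals = sum(x$count[!known]),
            n_unknown_records = sum(!known),
            class = c("guild_tally", "data.frame"))
}

#' Chi-square goodness-of-fit test
#'
#' `X^2 = sum (O - E)^2 / E` with `df = length - 1` and upper-tail p-value
#' from the chi-square distribution. At df = 2 the p-value has the closed
#' form `exp(-X^2 / 2)`, a useful analytic check.
#'
#' @param observed observed counts.
#' @param expected expected counts (all strictly positive, same length).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chisq_gof(c(10, 20, 30), c(20, 20, 20))  # X^2 = 10, p = exp(-5)
chisq_gof <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length", call. = FALSE)
  }
  if (any(is.na(expected)) || any(expected <= 0)) {
    stop("expected counts must all be positive", call. = FALSE)
  }
  x2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = x2, df = df,
       p.value = pchisq(x2, df = df, lower.tail = FALSE))
}

#' Guild homogeneity tests with Bonferroni-corrected pairwise comparisons
#'
#' Runs, separately for guild abundances and for guild family richness, an
#' omnibus chi-square test of the three tallies against equal expected
#' counts (df = 2) and the three pairwise tests of two tallies against an
#' equal split (df = 1). Pairwise significance is judged against the
#' Bonferroni-corrected level `alpha' = alpha / 3`. Equal expected counts
#' are an explicit, overridable assumption of the null (no a priori reason
#' for one guild to dominate).
#'
#' A pairwise test involving a zero tally is flagged invalid (its p-value
#' is still computed when the pair total is positive); the other tests
#' proceed.
#'
#' @param tally a `guild_tally` from [tally_guilds()].
#' @param alpha family-wise significance level (default 0.05).
#' @return A `guild_test_report`: list with components `abundance` and
#'   `family_richness` (each holding `omnibus` and a `pairwise` data
#'   frame), plus `alpha`, `alpha_corrected` and the logged unknown count.
#' @export
guild_tests <- function(tally, alpha = 0.05) {
  stopifnot(inherits(tally, "guild_tally"), nrow(tally) == 3L,
            is.numeric(alpha), alpha > 0, alpha < 1)
  n_tests <- 3L
  alpha_c <- alpha / n_tests

  battery <- function(v) {
    names(v) <- tally$guild
    total <- sum(v)
    omni <- if (total > 0) {
      chisq_gof(v, rep(total / length(v), length(v)))
    } else {
      list(statistic = NA_real_, df = length(v) - 1L, p.value = NA_real_)
    }
    pairs <- utils::combn(tally$guild, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      tot <- v[g1] + v[g2]
      valid <- v[g1] > 0 && v[g2] > 0
      if (tot > 0) {
        ct <- chisq_gof(c(v[g1], v[g2]), c(tot / 2, tot / 2))
      } else {
        ct <- list(statistic = NA_real_, df = 1L, p.value = NA_real_)
      }
      data.frame(pair = paste(g1, "vs", g2),
                 statistic = ct$statistic, df = ct$df, p.value = ct$p.value,
                 significant = valid && !is.na(ct$p.value) &&
                   ct$p.value < alpha_c,
                 valid = valid, stringsAsFactors = FALSE)
    }))
    rownames(pw) <- NULL
    list(omnibus = omni, pairwise = pw)
  }

  structure(list(
    abundance = battery(tally$abundance),
    family_richness = battery(tally$family_richness),
    alpha = alpha, alpha_corrected = alpha_c,
    n_unknown_individuals = attr(tally, "n_unknown_individuals")),
    class = "guild_test_report")
}

#' @export
print.guild_test_report <- function(x, ...) {
  cat(sprintf("Guild chi-square tests (alpha = %.3g, Bonferroni alpha' = %.4f)\n",
              x$alpha, x$alpha_corrected))
  for (part in c("abundance", "family_richness")) {
    o <- x[[part]]$omnibus
    cat(sprintf("%s: omnibus X^2 = %.4g, df = %d, p = %.4g\n",
                part, o$statistic, o$df, o$p.value))
    print.data.frame(x[[part]]$pairwise, digits = 4)
  }
  if (isTRUE(x$n_unknown_individuals > 0)) {
    cat(sprintf("(%d individuals with guild 'unknown' excluded)\n",
                x$n_unknown_individuals))
  }
  invisible(x)
}
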