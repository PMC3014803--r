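#' Species-abundance-distribution model specifications
#'
#' The four models compared are, in increasing order of evenness:
#' dominance pre-emption (geometric series, one parameter `k`), the Fisher
#' log-series (one parameter `x`), the Poisson-lognormal (two parameters
#' `mu`, `sigma`), and MacArthur's broken stick (no free parameters).
#' Free-parameter counts enter the AIC; richness S and total abundance N
#' are conditioned on, as is conventional.
#'
#' @param name one of `"preemption"`, `"logseries"`, `"lognormal"`,
#'   `"brokenstick"`.
#' @return A list with elements `name`, `n_free_params`, `param_names`.
#' @export
sad_model_spec <- function(name = c("preemption", "logseries", "lognormal",
                                    "brokenstick")) {
  name <- match.arg(name)
  spec <- switch(name,
    preemption  = list(n_free_params = 1L, param_names = "k"),
    logseries   = list(n_free_params = 1L, param_names = "x"),
    lognormal   = list(n_free_params = 2L, param_names = c("mu", "sigma")),
    brokenstick = list(n_free_params = 0L, param_names = character()))
  structure(c(list(name = name), spec), class = "sad_model_spec")
}

#' Log-series log-probability mass
#'
#' The zero-truncated Fisher log-series assigns a species with parameter
#' `x` in (0,1) the probability `P(n) = -x^n / (n * log(1 - x))` of being
#' represented by `n >= 1` individuals. Its mean is
#' `-x / ((1 - x) * log(1 - x))`, which is the basis of the ML estimator in
#' [fit_logseries()].
#'
#' @param n positive integer count(s).
#' @param x log-series parameter, strictly inside (0, 1).
#' @return `log P(n)`, vectorized over `n`.
#' @export
#' @examples
#' exp(logseries_logpmf(1, 0.5))  # 0.5 / log(2)
logseries_logpmf <- function(n, x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop("x must be a scalar strictly inside (0, 1)", call. = FALSE)
  }
  if (any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    stop("n must be positive integer(s)", call. = FALSE)
  }
  n * log(x) - log(n) - log(-log1p(-x))
}

# mean of the zero-truncated log-series pmf
logseries_mean <- function(x) -x / ((1 - x) * log1p(-x))

# invert the mean relation; m must exceed 1
logseries_x_for_mean <- function(m) {
  stopifnot(m > 1)
  uniroot(function(x) logseries_mean(x) - m,
          lower = 1e-12, upper = 1 - 1e-14,
          tol = .Machine$double.eps^0.75)$root
}

#' Rank-abundance profile of the dominance pre-emption model
#'
#' Each species pre-empts a fraction `k` of the niche space left by its
#' predecessors, giving geometric rank proportions
#' `p_i = k (1-k)^(i-1) / (1 - (1-k)^S)` for ranks `i = 1..S`.
#'
#' @param S number of species (ranks).
#' @param k pre-emption fraction, strictly inside (0, 1).
#' @return A `rank_profile`: list with `S` and `props` (positive,
#'   non-increasing, summing to one).
#' @export
preemption_props <- function(S, k) {
  if (!is.numeric(S) || length(S) != 1L || S < 1 || S != round(S)) {
    stop("S must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0 || k >= 1) {
    stop("k must be a scalar strictly inside (0, 1)", call. = FALSE)
  }
  i <- seq_len(S)
  # log-space form survives extreme (S, k) where (1-k)^(i-1) underflows
  lp <- log(k) + (i - 1) * log1p(-k) - log(-expm1(S * log1p(-k)))
  rank_profile(S, exp(lp))
}

#' Rank-abundance profile of MacArthur's broken stick model
#'
#' Random simultaneous partition of a unit resource among S species gives
#' expected rank proportions `p_i = (1/S) * sum_{j=i}^{S} 1/j` — the most
#' even of the four models.
#'
#' @param S number of species.
#' @return A `rank_profile`.
#' @export
brokenstick_props <- function(S) {
  if (!is.numeric(S) || length(S) != 1L || S < 1 || S != round(S)) {
    stop("S must be a positive integer", call. = FALSE)
  }
  p <- rev(cumsum(1 / (S:1))) / S
  rank_profile(S, p)
}

rank_profile <- function(S, props) {
  stopifnot(length(props) == S, all(props >= 0),
            all(diff(props) <= 1e-15),
            abs(sum(props) - 1) < 1e-12)
  structure(list(S = as.integer(S), props = as.numeric(props)),
            class = "rank_profile")
}

#' Multinomial log-likelihood of ranked counts against a rank profile
#'
#' The pre-emption and broken-stick models predict expected proportions per
#' rank rather than a count distribution, so their likelihood is the
#' multinomial probability (including the multinomial coefficient) of the
#' observed ranked counts with cell probabilities given by the profile.
#' This is the likelihood bridge that makes the four models comparable by
#' AIC.
#'
#' @param counts an [abundance_vector()] or positive numeric counts; length
#'   must equal `profile$S`. Counts are ranked before matching.
#' @param profile a `rank_profile` from [preemption_props()] or
#'   [brokenstick_props()].
#' @return The multinomial log-likelihood in nats.
#' @export
multinomial_rank_loglik <- function(counts, profile) {
  stopifnot(inherits(profile, "rank_profile"))
  av <- as_abundance(counts)
  if (length(av$counts) != profile$S) {
    stop("counts length (", length(av$counts),
         ") does not match profile S (", profile$S, ")", call. = FALSE)
  }
  dmultinom(av$counts, prob = profile$props, log = TRUE)
}

# ---- Poisson-lognormal ------------------------------------------------------

gauss_hermite_nodes <- function(n = 64L) {
  key <- paste0("gh", n)
  if (is.null(.commstruct_cache[[key]])) {
    .commstruct_cache[[key]] <- pracma::gaussHermite(n)
  }
  .commstruct_cache[[key]]
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Zero-truncated Poisson-lognormal log-probability mass
#'
#' Count-level realization of the lognormal SAD: a species' mean abundance
#' is lognormal(`mu`, `sigma`) and its observed count Poisson around that
#' mean; unobserved species (n = 0) are truncated away. The mixing integral
#' `P(n) = int Poisson(n; e^z) Normal(z; mu, sigma^2) dz` is evaluated by
#' fixed 64-node Gauss-Hermite quadrature with log-sum-exp accumulation.
#' The quadrature is re-centred for every `n` at the mode of the log
#' integrand with its Laplace width (the integrand narrows like
#' `n^(-1/2)`, so a fixed centring loses accuracy at large counts); the
#' adapted rule is deterministic and accurate to better than 1e-8 over the
#' ranges arising in practice.
#'
#' @param n positive integer count(s).
#' @param mu lognormal location (log scale).
#' @param sigma lognormal scale, > 0.
#' @param nodes number of quadrature nodes.
#' @return `log P(n)` under the zero-truncated mixture, vectorized over `n`.
#' @export
poisson_lognormal_logpmf <- function(n, mu, sigma, nodes = 64L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  if (any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    stop("n must be positive integer(s)", call. = FALSE)
  }
  lp <- pln_log_integral(n, mu, sigma, nodes)
  l0 <- pln_log_integral(0, mu, sigma, nodes)
  lp - log1p(-exp(l0))
}

# log of int Poisson(n; e^z) N(z; mu, sigma^2) dz by mode-adapted
# Gauss-Hermite quadrature; vectorized over n (n = 0 allowed)
pln_log_integral <- function(n, mu, sigma, nodes = 64L) {
  gh <- gauss_hermite_nodes(nodes)
  isig2 <- 1 / sigma^2
  # Newton iterations for the mode of n*z - e^z - (z - mu)^2 / (2 sigma^2)
  z <- ifelse(n > 0, log(n + 0.5), mu)
  for (it in 1:100) {
    ez <- exp(pmin(z, 700))
    step <- (n - ez - (z - mu) * isig2) / (-ez - isig2)
    z <- z - step
    if (max(abs(step)) < 1e-12) break
  }
  s <- 1 / sqrt(exp(pmin(z, 700)) + isig2)      # Laplace width at the mode
  # z_j = mode + sqrt(2) s x_j; int g(z) dz = sqrt(2) s sum w_j e^{x_j^2} g(z_j)
  lt <- vapply(seq_along(gh$x), function(j) {
    zj <- z + sqrt(2) * s * gh$x[j]
    log(gh$w[j]) + gh$x[j]^2 + dpois(n, pmin(exp(zj), 1e300), log = TRUE) +
      dnorm(zj, mu, sigma, log = TRUE)
  }, numeric(length(n)))
  if (length(n) == 1L) lt <- matrix(lt, nrow = 1L)
  log(sqrt(2) * s) + logsumexp_rows(lt)
}

# ---- fit objects ------------------------------------------------------------

#' Construct a fitted SAD model object
#'
#' Normally produced by the `fit_*` functions; the constructor is exported
#' so that externally published fits (e.g. AIC values from the literature)
#' can enter [select_sad_models()]. The invariant
#' `aic = 2 * n_free_params - 2 * logLik` always holds.
#'
#' @param model model name or [sad_model_spec()].
#' @param params named numeric vector of estimates.
#' @param logLik maximized log-likelihood in nats.
#' @param n_obs number of ranked groups the model was fitted to (used to
#'   verify that competing fits describe the same data).
#' @param converged logical.
#' @param diagnostic scalar convergence diagnostic (MCMC split-half R-hat,
#'   optimizer code), `NA` when not applicable.
#' @param derived named numeric vector of derived quantities (e.g. Fisher's
#'   alpha for the log-series).
#' @param posterior optional matrix of MCMC draws (one column per free
#'   parameter plus `logL`).
#' @param settings list of fitting settings (seed, chain lengths, ...).
#' @return An object of class `sad_fit`.
#' @export
sad_fit <- function(model, params = numeric(), logLik, n_obs = NA_integer_,
                    converged = TRUE, diagnostic = NA_real_,
                    derived = numeric(), posterior = NULL, settings = list()) {
  if (!inherits(model, "sad_model_spec")) model <- sad_model_spec(model)
  stopifnot(is.numeric(logLik), length(logLik) == 1L)
  fit <- list(model = model, params = params, logLik = as.numeric(logLik),
              aic = aic(logLik, model$n_free_params),
              n_obs = as.integer(n_obs), converged = isTRUE(converged),
              diagnostic = diagnostic, derived = derived,
              posterior = posterior, settings = settings)
  class(fit) <- "sad_fit"
  fit
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("SAD fit: %s (%d free parameter%s)\n", x$model$name,
              x$model$n_free_params,
              if (x$model$n_free_params == 1L) "" else "s"))
  if (length(x$params)) {
    cat("  params:",
        paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "),
        "\n")
  }
  if (length(x$derived)) {
    cat("  derived:",
        paste(sprintf("%s = %.6g", names(x$derived), x$derived), collapse = ", "),
        "\n")
  }
  cat(sprintf("  logLik = %.4f, AIC = %.4f, converged = %s\n",
              x$logLik, x$aic, x$converged))
  if (!is.null(x$posterior)) {
    cat(sprintf("  posterior: %d draws\n", nrow(x$posterior)))
  }
  invisible(x)
}

#' Akaike Information Criterion
#'
#' @param logLik maximized log-likelihood.
#' @param n_free_params number of freely estimated parameters.
#' @return `2 * n_free_params - 2 * logLik`.
#' @export
aic <- function(logLik, n_free_params) {
  stopifnot(n_free_params >= 0)
  2 * n_free_params - 2 * logLik
}

# ---- maximum-likelihood fitting --------------------------------------------

#' Fit the Fisher log-series by maximum likelihood
#'
#' The ML estimate of `x` solves the mean-matching equation
#' `N/S = -x / ((1-x) log(1-x))` by bracketed root-finding (this is exactly
#' the score equation of the zero-truncated log-series likelihood).
#' Fisher's alpha is reported as the derived quantity
#' `alpha = -S / log(1 - x)`.
#'
#' @param counts an [abundance_vector()] or positive integer counts, S >= 2.
#' @return A [sad_fit()].
#' @export
fit_logseries <- function(counts) {
  av <- as_abundance(counts)
  n <- av$counts
  S <- length(n)
  if (S < 2L) stop("log-series fit needs at least 2 groups", call. = FALSE)
  mbar <- mean(n)
  if (mbar <= 1 + 1e-12) {
    warning("all counts are 1: log-series x at its lower boundary",
            call. = FALSE)
    x_hat <- 1e-10
  } else {
    x_hat <- logseries_x_for_mean(mbar)
  }
  ll <- sum(logseries_logpmf(n, x_hat))
  sad_fit("logseries", params = c(x = x_hat), logLik = ll, n_obs = S,
          derived = c(alpha = -S / log1p(-x_hat)))
}

#' Fit the dominance pre-emption model by maximum likelihood
#'
#' Maximizes the multinomial rank log-likelihood over the pre-emption
#' fraction `k` in (0, 1) by bounded scalar optimization.
#'
#' @param counts an [abundance_vector()] or positive integer counts, S >= 2.
#' @return A [sad_fit()].
#' @export
fit_preemption <- function(counts) {
  av <- as_abundance(counts)
  S <- length(av$counts)
  if (S < 2L) stop("pre-emption fit needs at least 2 groups", call. = FALSE)
  obj <- function(k) multinomial_rank_loglik(av, preemption_props(S, k))
  opt <- optimize(obj, interval = c(1e-9, 1 - 1e-9), maximum = TRUE,
                  tol = 1e-10)
  sad_fit("preemption", params = c(k = opt$maximum), logLik = opt$objective,
          n_obs = S)
}

#' Fit MacArthur's broken stick model
#'
#' The broken stick has no free parameters: the log-likelihood is the
#' multinomial rank log-likelihood against the fixed broken-stick profile
#' and `AIC = -2 logLik`.
#'
#' @param counts an [abundance_vector()] or positive integer counts.
#' @return A [sad_fit()].
#' @export
fit_brokenstick <- function(counts) {
  av <- as_abundance(counts)
  S <- length(av$counts)
  ll <- multinomial_rank_loglik(av, brokenstick_props(S))
  sad_fit("brokenstick", logLik = ll, n_obs = S)
}

#' Fit the zero-truncated Poisson-lognormal by maximum likelihood
#'
#' Maximizes the summed [poisson_lognormal_logpmf()] over `(mu, sigma)`
#' with Nelder-Mead on `(mu, log sigma)` from five deterministic starts
#' (method-of-moments on log counts, plus fixed perturbations); the
#' likelihood can be multimodal for small S, so the best of the five is
#' kept and polished.
#'
#' @param counts an [abundance_vector()] or positive integer counts, S >= 3.
#' @return A [sad_fit()].
#' @export
fit_lognormal <- function(counts) {
  av <- as_abundance(counts)
  n <- av$counts
  S <- length(n)
  if (S < 3L) {
    stop("Poisson-lognormal fit needs at least 3 groups (2 parameters)",
         call. = FALSE)
  }
  u <- sort(unique(n))
  w <- as.numeric(table(factor(n, levels = u)))
  if (length(u) == 1L) {
    warning("all counts equal: sigma at its lower bound", call. = FALSE)
    sig0 <- 1e-4
    opt <- optimize(function(mu) S * poisson_lognormal_logpmf(u, mu, sig0),
                    interval = log(u) + c(-3, 3), maximum = TRUE, tol = 1e-9)
    return(sad_fit("lognormal", params = c(mu = opt$maximum, sigma = sig0),
                   logLik = opt$objective, n_obs = S))
  }
  nll <- function(p) {
    sig <- exp(p[2L])
    if (!is.finite(sig) || sig > 50 || abs(p[1L]) > 700) return(1e10)
    v <- -sum(w * poisson_lognormal_logpmf(u, p[1L], sig))
    if (is.finite(v)) v else 1e10
  }
  mu0 <- mean(log(n))
  ls0 <- log(max(sd(log(n)), 0.2))
  starts <- list(c(mu0, ls0), c(mu0 - 1, ls0), c(mu0 + 1, ls0),
                 c(mu0, ls0 + log(2)), c(mu0, ls0 - log(2)))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(optim(st, nll, method = "Nelder-Mead",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(sad_fit("lognormal", params = c(mu = NA_real_, sigma = NA_real_),
                   logLik = -Inf, n_obs = S, converged = FALSE))
  }
  polish <- tryCatch(optim(best$par, nll, method = "BFGS",
                           control = list(maxit = 200)),
                     error = function(e) best)
  if (polish$value <= best$value) best <- polish
  sad_fit("lognormal",
          params = c(mu = best$par[1L], sigma = exp(best$par[2L])),
          logLik = -best$value, n_obs = S,
          converged = best$convergence == 0,
          diagnostic = best$convergence)
}

#' Fit one SAD model by maximum likelihood
#'
#' Dispatcher over [fit_logseries()], [fit_preemption()],
#' [fit_brokenstick()], [fit_lognormal()].
#'
#' @param counts an [abundance_vector()] or positive integer counts.
#' @param model model name.
#' @return A [sad_fit()].
#' @export
fit_sad <- function(counts, model = c("logseries", "preemption",
                                      "brokenstick", "lognormal")) {
  model <- match.arg(model)
  switch(model,
         logseries   = fit_logseries(counts),
         preemption  = fit_preemption(counts),
         brokenstick = fit_brokenstick(counts),
         lognormal   = fit_lognormal(counts))
}

# ---- model selection --------------------------------------------------------

#' Rank SAD fits by AIC with a delta-AIC equivalence rule
#'
#' Fits are sorted by ascending AIC (ties keep input order); every fit
#' within `delta_threshold` of the minimum is flagged equivalent to the
#' best — models whose AICs differ by less than about 2 describe the data
#' equally well.
#'
#' @param fits list of [sad_fit()] objects for the same data.
#' @param delta_threshold delta-AIC below which fits are considered
#'   equivalent (default 2).
#' @return A `sad_selection`: a data frame with columns `model`,
#'   `n_params`, `logLik`, `AIC`, `delta_AIC`, `equivalent`, sorted by AIC,
#'   with the best model name in attribute `best`.
#' @export
select_sad_models <- function(fits, delta_threshold = 2) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "sad_fit")))
  n_obs <- vapply(fits, function(f) f$n_obs, integer(1))
  known <- n_obs[!is.na(n_obs)]
  if (length(unique(known)) > 1L) {
    stop("fits describe data of differing lengths: ",
         paste(unique(known), collapse = ", "), call. = FALSE)
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aics)  # stable for ties
  delta <- aics - min(aics)
  out <- data.frame(
    model = vapply(fits, function(f) f$model$name, character(1)),
    n_params = vapply(fits, function(f) f$model$n_free_params, integer(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AIC = aics,
    delta_AIC = delta,
    equivalent = delta < delta_threshold,
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, best = out$model[1L], delta_threshold = delta_threshold,
            class = c("sad_selection", "data.frame"))
}

#' @export
print.sad_selection <- function(x, ...) {
  cat(sprintf("SAD model selection (delta-AIC threshold %.3g): best = %s\n",
              attr(x, "delta_threshold"), attr(x, "best")))
  print.data.frame(x, digits = 6)
  invisible(x)
}
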