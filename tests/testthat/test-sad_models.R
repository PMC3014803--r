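test_that("log-series pmf has the closed form, normalizes, and has the stated mean", {
  expect_equal(logseries_logpmf(1, 0.5), log(0.5 / log(2)), tolerance = 1e-12)
  expect_error(logseries_logpmf(1, 1), "inside")
  expect_error(logseries_logpmf(0, 0.5), "positive integer")

  expect_lt(abs(sum(exp(logseries_logpmf(1:1e6, 0.9))) - 1), 1e-9)

  # brute-force mean vs -x / ((1-x) log(1-x)) at x = 0.8
  n <- 1:1e5
  mean_bf <- sum(n * exp(logseries_logpmf(n, 0.8)))
  expect_equal(mean_bf, -0.8 / (0.2 * log(0.2)), tolerance = 1e-10)
})

test_that("pre-emption profile matches its closed form and is a valid profile", {
  p <- preemption_props(2, 0.5)
  expect_equal(p$props, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(preemption_props(1, 0.7)$props, 1.0)
  expect_error(preemption_props(5, 1.2), "inside")

  for (S in round(seq(2, 200, length.out = 50))) {
    for (k in seq(0.02, 0.98, length.out = 50)) {
      pr <- preemption_props(S, k)$props
      expect_true(all(diff(pr) <= 1e-15))
      expect_lt(abs(sum(pr) - 1), 1e-12)
    }
  }
})

test_that("broken-stick profile telescopes to one and matches hand values", {
  expect_equal(brokenstick_props(1)$props, 1.0)
  expect_equal(brokenstick_props(2)$props, c(0.75, 0.25), tolerance = 1e-12)
  expect_error(brokenstick_props(0), "positive integer")
  for (S in 1:500) {
    expect_lt(abs(sum(brokenstick_props(S)$props) - 1), 1e-12)
  }
})

test_that("multinomial rank log-likelihood matches hand computation", {
  prof2 <- brokenstick_props(2)  # (0.75, 0.25)
  expect_equal(multinomial_rank_loglik(c(3, 1), prof2),
               log(4 * 0.75^3 * 0.25), tolerance = 1e-12)
  expect_equal(multinomial_rank_loglik(5, brokenstick_props(1)), 0)
  expect_error(multinomial_rank_loglik(c(3, 1, 1), prof2), "match")

  # independent lgamma-based oracle on random fixtures
  for (seed in 1:20) {
    n <- random_counts(seed)
    S <- length(n)
    pr <- preemption_props(S, 0.3)
    oracle <- lgamma(sum(n) + 1) - sum(lgamma(n + 1)) + sum(n * log(pr$props))
    expect_equal(multinomial_rank_loglik(n, pr), oracle, tolerance = 1e-9)
  }
})

test_that("Poisson-lognormal pmf matches truncated Poisson limit, normalizes, and agrees with adaptive integration", {
  # sigma -> 0 limit: zero-truncated Poisson(5)
  n <- 1:20
  lim <- poisson_lognormal_logpmf(n, log(5), 1e-4)
  ztp <- dpois(n, 5) / (1 - dpois(0, 5))
  expect_true(all(abs(exp(lim) - ztp) < 1e-4))

  expect_lt(abs(sum(exp(poisson_lognormal_logpmf(1:2000, 1, 1))) - 1), 1e-6)

  # adaptive-quadrature oracle at (n = 3, mu = 0.5, sigma = 0.8)
  num <- integrate(function(z) dpois(3, exp(z)) * dnorm(z, 0.5, 0.8),
                   -Inf, Inf, rel.tol = 1e-12)$value
  p0 <- integrate(function(z) dpois(0, exp(z)) * dnorm(z, 0.5, 0.8),
                  -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(exp(poisson_lognormal_logpmf(3, 0.5, 0.8)), num / (1 - p0),
               tolerance = 1e-8)
  expect_error(poisson_lognormal_logpmf(3, 0, -1), "positive")
})

test_that("ML optima dominate dense parameter grids", {
  set.seed(31)
  for (seed in 1:5) {
    n <- random_counts(seed, S = 30, max_count = 120)

    fl <- fit_logseries(n)
    for (x in runif(100, 0.01, 0.999)) {
      expect_gte(fl$logLik, sum(logseries_logpmf(n, x)))
    }

    fp <- fit_preemption(n)
    kgrid <- seq(0.001, 0.999, length.out = 1000)
    ll_grid <- vapply(kgrid, function(k)
      multinomial_rank_loglik(n, preemption_props(length(n), k)), numeric(1))
    expect_gte(fp$logLik, max(ll_grid))

    fn <- fit_lognormal(n)
    for (mu in seq(fn$params["mu"] - 1, fn$params["mu"] + 1, length.out = 8)) {
      for (sg in seq(max(fn$params["sigma"] / 2, 0.05),
                     fn$params["sigma"] * 2, length.out = 8)) {
        expect_gte(fn$logLik + 1e-6,
                   sum(poisson_lognormal_logpmf(n, mu, sg)))
      }
    }
  }
})

test_that("log-series fit recovers the generating parameter and Fisher's alpha", {
  set.seed(99)
  n <- oracle_rlogseries(200, 0.97)
  fit <- fit_logseries(n)
  expect_gt(fit$params["x"], 0.96)
  expect_lt(fit$params["x"], 0.98)

  # cross-check Fisher's alpha against vegan's independent estimator
  alpha_vegan <- vegan::fisherfit(n)$estimate
  expect_equal(unname(fit$derived["alpha"]), unname(alpha_vegan),
               tolerance = 1e-4)
})

test_that("degenerate inputs hit documented boundaries with warnings", {
  expect_warning(fit <- fit_logseries(c(1, 1, 1, 1)), "boundary")
  expect_lt(fit$params["x"], 1e-6)

  expect_warning(fln <- fit_lognormal(c(7, 7, 7, 7)), "lower bound")
  expect_equal(unname(fln$params["sigma"]), 1e-4)
  expect_error(fit_lognormal(c(3, 2)), "at least 3")
})

test_that("pre-emption fit recovers k from multinomial draws and exact geometry", {
  set.seed(12)
  n <- as.numeric(rmultinom(1, 1e4, preemption_props(20, 0.3)$props))
  n <- sort(n[n > 0], decreasing = TRUE)
  fp <- fit_preemption(n)
  expect_gt(fp$params["k"], 0.28)
  expect_lt(fp$params["k"], 0.32)

  geo <- c(64, 32, 16, 8, 4, 2, 1)
  expect_equal(unname(fit_preemption(geo)$params["k"]), 0.5,
               tolerance = 1e-4)
})

test_that("broken stick is parameter-free and wins on its own data", {
  f1 <- fit_brokenstick(9)
  expect_equal(f1$logLik, 0)
  expect_equal(f1$aic, 0)

  # counts exactly proportional to the S = 4 broken-stick profile
  n4 <- round(brokenstick_props(4)$props * 4800)
  sel <- select_sad_models(list(fit_preemption(n4), fit_brokenstick(n4)))
  expect_equal(attr(sel, "best"), "brokenstick")

  # AIC ordering vs pre-emption is preserved under 10x scaling
  set.seed(5)
  n <- as.numeric(rmultinom(1, 500, brokenstick_props(12)$props))
  n <- sort(n[n > 0], decreasing = TRUE)
  rank1 <- function(m) attr(select_sad_models(
    list(fit_preemption(m), fit_brokenstick(m))), "best")
  expect_equal(rank1(n), rank1(n * 10))
})

test_that("AIC arithmetic and monotonicity", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-65, 2), 134)
  expect_lt(aic(-10, 1), aic(-10, 2))
  f <- fit_logseries(c(20, 10, 5, 2, 1, 1))
  expect_equal(f$aic, 2 * 1 - 2 * f$logLik, tolerance = 1e-9)
})

test_that("delta-AIC selection flags equivalence and orders fits", {
  # published AIC pair: log series 41.318 vs log normal 39.72
  fls <- sad_fit("logseries", params = c(x = 0.9), n_obs = 30L,
                 logLik = (2 * 1 - 41.318) / 2)
  fln <- sad_fit("lognormal", params = c(mu = 1, sigma = 1), n_obs = 30L,
                 logLik = (2 * 2 - 39.72) / 2)
  expect_equal(fls$aic, 41.318, tolerance = 1e-12)
  expect_equal(fln$aic, 39.72, tolerance = 1e-12)
  sel <- select_sad_models(list(fls, fln), delta_threshold = 2)
  expect_equal(attr(sel, "best"), "lognormal")
  expect_true(all(sel$equivalent))

  # clear winner among synthetic competitors
  mk <- function(model, a, np) sad_fit(model, n_obs = 52L,
                                       logLik = (2 * np - a) / 2)
  sel2 <- select_sad_models(list(mk("logseries", 202.231, 1),
                                 mk("lognormal", 250, 2),
                                 mk("preemption", 300, 1),
                                 mk("brokenstick", 310, 0)))
  expect_equal(attr(sel2, "best"), "logseries")
  expect_equal(sum(sel2$equivalent), 1L)

  # exact tie: both equivalent, input order preserved
  tie <- select_sad_models(list(mk("preemption", 100, 1),
                                mk("brokenstick", 100, 0)))
  expect_true(all(tie$equivalent))
  expect_equal(tie$model, c("preemption", "brokenstick"))

  # differing data lengths are rejected
  bad <- sad_fit("logseries", n_obs = 10L, logLik = -5)
  expect_error(select_sad_models(list(fls, bad)), "differing")
})
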