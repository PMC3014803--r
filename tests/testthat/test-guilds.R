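test_that("guild tallies sum abundance and count distinct families", {
  tab <- community_table(data.frame(
    taxon_id = c("a", "b", "c"),
    species = c("s1", "s2", "s3"),
    family = c("f1", "f2", "f3"), order = "o1",
    guild = c("herbivore", "predator", "scavenger"),
    count = c(1L, 2L, 3L)))
  t1 <- tally_guilds(tab)
  expect_equal(t1$abundance, c(1L, 2L, 3L))
  expect_equal(t1$family_richness, c(1L, 1L, 1L))

  # two predator species in one family count that family once
  tab2 <- community_table(data.frame(
    taxon_id = c("a", "b"), species = c("s1", "s2"),
    family = "f1", order = "o1", guild = "predator", count = c(4L, 6L)))
  t2 <- tally_guilds(tab2)
  expect_equal(t2$family_richness[t2$guild == "predator"], 1L)

  expect_error(tally_guilds(community_table(data.frame(
    taxon_id = "a", species = "s", family = "f", order = "o",
    guild = "unknown", count = 3L))), "unknown")
})

test_that("guild abundances plus unknowns conserve the table total", {
  for (seed in 1:100) {
    tab <- random_table(seed)
    if (all(tab$guild == "unknown")) next
    tl <- tally_guilds(tab)
    expect_identical(sum(tl$abundance) +
                       attr(tl, "n_unknown_individuals"),
                     sum(tab$count))
  }
})

test_that("chi-square goodness of fit matches closed forms and stats::chisq.test", {
  z <- chisq_gof(c(20, 20, 20), c(20, 20, 20))
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)

  g <- chisq_gof(c(10, 20, 30), c(20, 20, 20))
  expect_equal(g$statistic, 10)
  expect_equal(g$df, 2L)
  expect_equal(g$p.value, exp(-5), tolerance = 1e-12)

  # df = 2 closed form p = exp(-X^2/2)
  for (x2 in c(0.1, 1, 5.81, 20)) {
    obs <- c(100 + sqrt(50 * x2), 100 - sqrt(50 * x2), 100)
    out <- chisq_gof(obs, c(100, 100, 100))
    expect_equal(out$statistic, x2, tolerance = 1e-12)
    expect_lt(abs(out$p.value - exp(-x2 / 2)), 1e-10)
  }

  # independent cross-check against stats::chisq.test
  o <- c(35, 21, 44)
  ct <- suppressWarnings(chisq.test(o, p = rep(1 / 3, 3)))
  mine <- chisq_gof(o, rep(sum(o) / 3, 3))
  expect_equal(mine$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, ct$p.value, tolerance = 1e-12)

  expect_error(chisq_gof(c(1, 2), c(1, 0)), "positive")
  expect_error(chisq_gof(c(1, 2), c(1, 1, 1)), "length")
})

test_that("guild battery: Bonferroni level, equal-split nulls, hand-checked X^2", {
  mk_tally <- function(ab) {
    tab <- community_table(data.frame(
      taxon_id = paste0("t", 1:3), species = paste0("s", 1:3),
      family = paste0("f", 1:3), order = "o",
      guild = c("herbivore", "predator", "scavenger"),
      count = as.integer(ab)))
    tally_guilds(tab)
  }
  rep0 <- guild_tests(mk_tally(c(100, 100, 100)), alpha = 0.05)
  expect_equal(rep0$alpha_corrected, 0.05 / 3, tolerance = 1e-15)
  expect_equal(round(rep0$alpha_corrected, 4), 0.0167)
  expect_equal(rep0$abundance$omnibus$statistic, 0)
  expect_false(any(rep0$abundance$pairwise$significant))

  # arithmetic oracle on (300, 100, 50)
  rep1 <- guild_tests(mk_tally(c(300, 100, 50)), alpha = 0.05)
  ab <- c(herbivore = 300, predator = 100, scavenger = 50)
  E <- sum(ab) / 3
  expect_equal(rep1$abundance$omnibus$statistic,
               sum((ab - E)^2 / E), tolerance = 1e-12)
  expect_equal(rep1$abundance$omnibus$df, 2L)
  pw <- rep1$abundance$pairwise
  hand <- function(a, b) (a - (a + b) / 2)^2 / ((a + b) / 2) * 2
  expect_equal(pw$statistic[pw$pair == "herbivore vs predator"],
               hand(300, 100), tolerance = 1e-12)
  expect_equal(pw$statistic[pw$pair == "predator vs scavenger"],
               hand(100, 50), tolerance = 1e-12)
  expect_true(all(pw$df == 1L))

  # omnibus X^2 invariant under permutation of guild order
  rep2 <- guild_tests(mk_tally(c(50, 300, 100)))
  expect_equal(rep2$abundance$omnibus$statistic,
               rep1$abundance$omnibus$statistic, tolerance = 1e-12)

  # a zero-abundance guild invalidates its pairwise tests only
  rep3 <- guild_tests(mk_tally(c(0, 80, 40)))
  pw3 <- rep3$abundance$pairwise
  expect_equal(pw3$valid, c(FALSE, FALSE, TRUE))
  expect_true(all(!pw3$significant[!pw3$valid]))
})
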