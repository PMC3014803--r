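test_that("CSV round-trip preserves counts, labels and totals", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_community_table(demo_table(), path)
  back <- read_community_table(path)
  expect_equal(back$count, demo_records()$count)
  expect_equal(back$taxon_id, demo_records()$taxon_id)
  expect_equal(sum(back$count), 20L)
  expect_equal(nrow(back), 4L)

  # single-record file
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon_id,species,family,order,guild,count",
               "a1,sp1,fam1,ord1,predator,7"), p1)
  one <- read_community_table(p1)
  expect_equal(nrow(one), 1L)
  expect_equal(sum(one$count), 7L)
})

test_that("malformed input is rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon_id,species,family,order,guild,count",
               "a1,sp1,fam1,ord1,predator,7",
               "a1,sp2,fam1,ord1,predator,3"), p)
  expect_error(read_community_table(p), "duplicate taxon_id")

  writeLines(c("taxon_id,species,family,order,count",
               "a1,sp1,fam1,ord1,7"), p)
  expect_error(read_community_table(p), "guild")

  writeLines(c("taxon_id,species,family,order,guild,count",
               "a1,sp1,fam1,ord1,predator,-2"), p)
  expect_error(read_community_table(p), "row\\(s\\): 1")

  writeLines(c("taxon_id,species,family,order,guild,count",
               "a1,sp1,fam1,ord1,predator,2.5"), p)
  expect_error(read_community_table(p), "non-integer")

  expect_error(read_community_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("zero-count records are retained in the table, dropped from vectors", {
  rec <- demo_records()
  rec$count[2L] <- 0L
  tab <- community_table(rec)
  expect_equal(nrow(tab), 4L)
  av <- aggregate_abundance(tab, "species")
  expect_equal(length(av$counts), 3L)
  expect_false("spB" %in% av$labels)
})

test_that("aggregation sums within labels and breaks ties by input order", {
  tab <- community_table(data.frame(
    taxon_id = c("x1", "x2", "x3"),
    species = c("a", "b", "c"),
    family = c("f1", "f1", "f2"),
    order = c("o1", "o1", "o1"),
    guild = "predator",
    count = c(3L, 4L, 5L)))
  fam <- aggregate_abundance(tab, "family")
  expect_equal(fam$counts, c(7, 5))
  expect_equal(fam$labels, c("f1", "f2"))

  tie <- community_table(data.frame(
    taxon_id = c("x1", "x2", "x3"),
    species = c("a", "b", "c"), family = "f", order = "o",
    guild = "unknown", count = c(10L, 5L, 5L)))
  sp <- aggregate_abundance(tie, "species")
  expect_equal(sp$counts, c(10, 5, 5))
  expect_equal(sp$labels, c("a", "b", "c"))  # b before c: input order
})

test_that("total abundance is conserved across aggregation levels", {
  for (seed in 1:200) {
    tab <- random_table(seed)
    if (sum(tab$count) == 0) next
    n_sp <- sum(aggregate_abundance(tab, "species")$counts)
    expect_identical(n_sp, sum(aggregate_abundance(tab, "family")$counts))
    expect_identical(n_sp, sum(aggregate_abundance(tab, "order")$counts))
    expect_identical(n_sp, sum(as.numeric(tab$count)))
  }
})

test_that("taxon exclusion filters records and records provenance", {
  tab <- community_table(data.frame(
    taxon_id = c("a", "b"), species = c("ant", "beetle"),
    family = c("Formicidae", "Tenebrionidae"), order = "x",
    guild = "predator", count = c(80L, 20L)))
  out <- exclude_taxa(tab, "family", "Formicidae")
  expect_equal(sum(out$count), 20L)
  expect_match(attr(out, "metadata"), "Formicidae", all = FALSE)

  expect_warning(same <- exclude_taxa(tab, "family", "Carabidae"),
                 "unchanged")
  expect_identical(as.data.frame(same), as.data.frame(tab))
})

test_that("exclude-then-aggregate commutes with aggregate-then-drop", {
  for (seed in 1:1000) {
    tab <- random_table(seed)
    fams <- unique(tab$family)
    victim <- fams[1L + seed %% length(fams)]
    left <- suppressWarnings(exclude_taxa(tab, "family", victim))
    if (sum(left$count) == 0) next
    a <- aggregate_abundance(left, "family")
    full <- aggregate_abundance(tab, "family")
    keep <- full$labels != victim
    expect_equal(a$counts, full$counts[keep])
    expect_equal(a$labels, full$labels[keep])
  }
})

test_that("relative abundances are proportions that sum to one", {
  expect_equal(relative_abundance(5), 1.0)
  expect_equal(relative_abundance(c(3, 1)), c(0.75, 0.25))
  expect_equal(relative_abundance(c(10, 5, 3, 2)), c(0.5, 0.25, 0.15, 0.1))
  expect_error(abundance_vector(numeric(0)), "empty")
  for (seed in 1:25) {
    p <- relative_abundance(random_counts(seed))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})
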