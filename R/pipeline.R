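#' Run the full community-structure analysis pipeline
#'
#' One-command reproduction of the whole workflow on a taxon-by-count
#' table: for each requested taxonomic level and each stratum (the full
#' table, and the table minus each configured exclusion), fits the
#' requested SAD models, ranks them by AIC with the delta-AIC equivalence
#' rule, and summarizes diversity; runs Hutcheson comparisons between each
#' full/excluded stratum pair and between any user-defined groups; and
#' runs the trophic-guild chi-square battery on the full table. Any stage
#' failure is recorded in the bundle and the remaining stages proceed.
#'
#' @param input path to a community CSV (see [read_community_table()]) or a
#'   [community_table()].
#' @param levels taxonomic levels to analyze.
#' @param exclusions character vector of `"level=label"` filters, e.g.
#'   `"family=Formicidae"`; each defines an extra stratum per level.
#' @param models SAD models to fit.
#' @param delta_threshold delta-AIC equivalence threshold (default 2).
#' @param comparisons list of user-defined diversity comparisons; each
#'   element is a list/vector with members `a` and `b`, each a
#'   `"level=label"` group selector (the matching records are analyzed at
#'   species level), e.g.
#'   `list(c(a = "family=Formicidae", b = "family=Tenebrionidae"))`.
#' @param alpha family-wise level for the guild tests.
#' @param mcmc if `TRUE`, additionally run [mcmc_fit()] for every fitted
#'   model with free parameters.
#' @param mcmc_draws,mcmc_burnin chain settings passed to [mcmc_fit()].
#' @param seed integer seed; required when `mcmc = TRUE` and used to derive
#'   per-stratum chain seeds.
#' @param out_dir if non-`NULL`, the JSON summary, per-stage CSVs, the
#'   plain-text report and a run log are written there.
#' @param quiet suppress progress messages.
#' @return A `pipeline_bundle`: list with `config`, `strata` (fits,
#'   selection, diversity per stratum), `comparisons`, `guilds`,
#'   `failures` and `summary` (best model per stratum).
#' @export
run_pipeline <- function(input,
                         levels = c("species", "family"),
                         exclusions = character(),
                         models = c("logseries", "preemption",
                                    "brokenstick", "lognormal"),
                         delta_threshold = 2,
                         comparisons = list(),
                         alpha = 0.05,
                         mcmc = FALSE,
                         mcmc_draws = 10000L,
                         mcmc_burnin = 1000L,
                         seed = 1L,
                         out_dir = NULL,
                         quiet = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  levels <- match.arg(levels, c("species", "family", "order"),
                      several.ok = TRUE)
  if (mcmc && missing(seed)) {
    stop("a seed is required when MCMC is enabled", call. = FALSE)
  }
  seed <- as.integer(seed)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  tab <- if (inherits(input, "community_table")) input
         else read_community_table(input)
  input_name <- if (is.character(input)) input else "<in-memory table>"
  say("input: %s (%d taxa, N = %d)", input_name, nrow(tab), sum(tab$count))
  say("seed: %d; models: %s; delta-AIC threshold: %g",
      seed, paste(models, collapse = ", "), delta_threshold)

  parse_filter <- function(f) {
    parts <- strsplit(f, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("exclusion must be 'level=label': ", f, call. = FALSE)
    }
    list(level = parts[1L], label = parts[2L])
  }

  failures <- character()
  fail <- function(stage, err) {
    failures <<- c(failures, sprintf("%s: %s", stage, conditionMessage(err)))
    say("FAILED %s: %s", stage, conditionMessage(err))
    NULL
  }

  # strata: per level, the full table and each exclusion applied
  variants <- c(list(full = NULL),
                setNames(lapply(exclusions, parse_filter),
                         sprintf("excl_%s", exclusions)))
  strata <- list()
  stratum_i <- 0L
  for (lev in levels) {
    for (vn in names(variants)) {
      stratum_i <- stratum_i + 1L
      key <- paste0(lev, "/", vn)
      stage <- paste0("sad+diversity[", key, "]")
      strata[[key]] <- tryCatch({
        tb <- tab
        filt <- variants[[vn]]
        if (!is.null(filt)) tb <- exclude_taxa(tb, filt$level, filt$label)
        av <- aggregate_abundance(tb, lev)
        say("stratum %s: S = %d, N = %d", key, length(av$counts),
            sum(av$counts))
        fits <- setNames(lapply(models, function(m) {
          tryCatch(fit_sad(av, m), error = function(e) fail(
            paste0("fit[", key, ", ", m, "]"), e))
        }), models)
        fits <- Filter(Negate(is.null), fits)
        mcmc_fits <- NULL
        if (mcmc) {
          mcmc_models <- intersect(models,
                                   c("logseries", "preemption", "lognormal"))
          mcmc_fits <- setNames(lapply(seq_along(mcmc_models), function(j) {
            tryCatch(mcmc_fit(av, mcmc_models[j], draws = mcmc_draws,
                              burnin = mcmc_burnin,
                              seed = seed + 1000L * stratum_i + j),
                     error = function(e) fail(
                       paste0("mcmc[", key, ", ", mcmc_models[j], "]"), e))
          }), mcmc_models)
          mcmc_fits <- Filter(Negate(is.null), mcmc_fits)
        }
        selection <- if (length(fits) >= 2L) {
          select_sad_models(fits, delta_threshold)
        } else NULL
        if (!is.null(selection)) {
          say("stratum %s: best model = %s (AIC %.3f)", key,
              attr(selection, "best"), selection$AIC[1L])
        }
        list(level = lev, variant = vn, S = length(av$counts),
             N = sum(av$counts), fits = fits, mcmc_fits = mcmc_fits,
             selection = selection, diversity = shannon(av))
      }, error = function(e) fail(stage, e))
    }
  }
  strata <- Filter(Negate(is.null), strata)

  # Hutcheson comparisons: full vs each excluded stratum, plus user pairs
  comp_rows <- list()
  for (lev in levels) {
    full_key <- paste0(lev, "/full")
    for (vn in setdiff(names(variants), "full")) {
      key <- paste0(lev, "/", vn)
      if (is.null(strata[[full_key]]) || is.null(strata[[key]])) next
      comp_rows[[length(comp_rows) + 1L]] <- tryCatch({
        tb <- tab
        filt <- variants[[vn]]
        tb2 <- suppressWarnings(exclude_taxa(tb, filt$level, filt$label))
        ht <- hutcheson_test(aggregate_abundance(tb, lev),
                             aggregate_abundance(tb2, lev))
        comparison_row(paste0(full_key, " vs ", key), ht)
      }, error = function(e) fail(paste0("hutcheson[", lev, ", ", vn, "]"), e))
    }
  }
  subset_group <- function(sel) {
    filt <- parse_filter(sel)
    keep <- tab[[filt$level]] == filt$label
    if (!any(keep)) stop("group selector matches nothing: ", sel,
                         call. = FALSE)
    community_table(as.data.frame(tab)[keep, , drop = FALSE],
                    metadata = sprintf("subset %s", sel))
  }
  for (cmp in comparisons) {
    cmp <- as.list(cmp)
    comp_rows[[length(comp_rows) + 1L]] <- tryCatch({
      ht <- hutcheson_test(
        aggregate_abundance(subset_group(cmp$a), "species"),
        aggregate_abundance(subset_group(cmp$b), "species"))
      comparison_row(paste0(cmp$a, " vs ", cmp$b), ht)
    }, error = function(e) fail(paste0("hutcheson[", cmp$a, " vs ", cmp$b, "]"),
                                e))
  }
  comp_df <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL

  guilds <- tryCatch(guild_tests(tally_guilds(tab), alpha = alpha),
                     error = function(e) fail("guilds", e))

  summary <- list(
    input = input_name, seed = seed,
    exclusions = as.list(exclusions),
    delta_threshold = delta_threshold,
    best_model = lapply(strata, function(s) {
      if (is.null(s$selection)) NA_character_ else attr(s$selection, "best")
    }),
    equivalent_models = lapply(strata, function(s) {
      if (is.null(s$selection)) character()
      else s$selection$model[s$selection$equivalent]
    }),
    diversity = lapply(strata, function(s) {
      list(H = s$diversity$H, varH = s$diversity$varH, S = s$diversity$S,
           N = s$diversity$N, J = s$diversity$J)
    }),
    n_failures = length(failures))

  bundle <- structure(list(config = list(
    input = input_name, levels = levels, exclusions = exclusions,
    models = models, delta_threshold = delta_threshold, alpha = alpha,
    mcmc = mcmc, mcmc_draws = mcmc_draws, mcmc_burnin = mcmc_burnin,
    seed = seed),
    strata = strata, comparisons = comp_df, guilds = guilds,
    failures = failures, summary = summary, log = log_lines),
    class = "pipeline_bundle")

  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

comparison_row <- function(label, ht) {
  data.frame(comparison = label,
             H_a = unname(ht$estimate[1L]), H_b = unname(ht$estimate[2L]),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p.value = ht$p.value, stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sel_rows <- do.call(rbind, lapply(names(bundle$strata), function(k) {
    s <- bundle$strata[[k]]
    if (is.null(s$selection)) return(NULL)
    cbind(stratum = k, as.data.frame(s$selection))
  }))
  if (!is.null(sel_rows)) {
    write.csv(sel_rows, file.path(out_dir, "sad_selection.csv"),
              row.names = FALSE)
  }
  div_rows <- do.call(rbind, lapply(names(bundle$strata), function(k) {
    d <- bundle$strata[[k]]$diversity
    data.frame(stratum = k, H = d$H, varH = d$varH, S = d$S, N = d$N,
               J = d$J)
  }))
  write.csv(div_rows, file.path(out_dir, "diversity.csv"), row.names = FALSE)
  if (!is.null(bundle$comparisons)) {
    write.csv(bundle$comparisons, file.path(out_dir, "hutcheson.csv"),
              row.names = FALSE)
  }
  writeLines(render_report(bundle), file.path(out_dir, "report.txt"))
  writeLines(c("# resolved configuration",
               paste0(names(bundle$config), ": ",
                      vapply(bundle$config, function(v)
                        paste(format(v), collapse = " "), character(1))),
               "# run log", bundle$log),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Render a pipeline bundle as a plain-text report
#'
#' Tabulates, per stratum, the AIC ranking with delta-AIC equivalences;
#' the diversity summaries (H, varH, S, N, J); the Hutcheson comparisons
#' (t, df, p); and the guild chi-square battery with Bonferroni-corrected
#' decisions. Failed stages are listed at the end.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @return A character vector of report lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  out <- c("Community structure analysis report",
           "===================================", "")
  for (k in names(bundle$strata)) {
    s <- bundle$strata[[k]]
    out <- c(out, sprintf("Stratum %s (S = %d, N = %d)", k, s$S, s$N))
    if (!is.null(s$selection)) {
      sel <- s$selection
      out <- c(out, sprintf("  best model: %s", attr(sel, "best")),
               sprintf("  %-12s %4s %12s %12s %10s %s", "model", "k",
                       "logLik", "AIC", "dAIC", "equivalent"),
               sprintf("  %-12s %4d %12.3f %12.3f %10.3f %s",
                       sel$model, sel$n_params, sel$logLik, sel$AIC,
                       sel$delta_AIC,
                       ifelse(sel$equivalent, "yes", "no")))
    }
    d <- s$diversity
    out <- c(out, sprintf(
      "  diversity: H = %.4f (var %.3g), J = %s", d$H, d$varH,
      if (is.na(d$J)) "undefined" else sprintf("%.4f", d$J)), "")
  }
  if (!is.null(bundle$comparisons)) {
    cmp <- bundle$comparisons
    out <- c(out, "Hutcheson diversity comparisons",
             sprintf("  %-45s %10s %10s %10s", "comparison", "t", "df", "p"),
             sprintf("  %-45s %10.3f %10.1f %10.4g", cmp$comparison, cmp$t,
                     cmp$df, cmp$p.value), "")
  }
  if (!is.null(bundle$guilds)) {
    g <- bundle$guilds
    out <- c(out, sprintf(
      "Trophic guilds (alpha = %.3g, Bonferroni alpha' = %.4f)",
      g$alpha, g$alpha_corrected))
    for (part in c("abundance", "family_richness")) {
      o <- g[[part]]$omnibus
      pw <- g[[part]]$pairwise
      out <- c(out, sprintf("  %s omnibus: X^2 = %.4g, df = %d, p = %.4g",
                            part, o$statistic, o$df, o$p.value),
               sprintf("    %-28s X^2 = %9.4g  p = %.4g  %s%s", pw$pair,
                       pw$statistic, pw$p.value,
                       ifelse(pw$significant, "significant",
                              "not significant"),
                       ifelse(pw$valid, "", " [invalid: zero tally]")))
    }
    out <- c(out, "")
  }
  if (length(bundle$failures)) {
    out <- c(out, "FAILED stages:", paste0("  ", bundle$failures))
  } else {
    out <- c(out, "All stages completed.")
  }
  out
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
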