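#' Community tables
#'
#' A community table is a data frame with one row per lowest-level taxon and
#' six columns: `taxon_id`, `species`, `family`, `order`, `guild`, `count`.
#' Counts are non-negative integers (individuals pooled over traps);
#' `guild` is one of `"herbivore"`, `"predator"`, `"scavenger"` or
#' `"unknown"`. Zero-count rows are retained in the table (they record taxa
#' known from the survey but absent from a filtered subset) and are dropped
#' only when an abundance vector is formed.
#'
#' @param records data frame holding the six required columns.
#' @param metadata character vector of provenance notes (source file,
#'   filters applied); carried along by [exclude_taxa()] and written back as
#'   `# filters:` comment lines by [write_community_table()].
#'
#' @return An object of class `community_table` (a data frame).
#' @seealso [read_community_table()], [aggregate_abundance()],
#'   [exclude_taxa()]
#' @export
#' @examples
#' tab <- community_table(data.frame(
#'   taxon_id = c("t1", "t2"), species = c("sp1", "sp2"),
#'   family = c("famA", "famA"), order = c("ordX", "ordX"),
#'   guild = c("predator", "herbivore"), count = c(10L, 3L)))
#' sum(tab$count)
community_table <- function(records, metadata = character()) {
  required <- c("taxon_id", "species", "family", "order", "guild", "count")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$taxon_id <- as.character(records$taxon_id)
  for (col in c("species", "family", "order")) {
    records[[col]] <- as.character(records[[col]])
    bad <- is.na(records[[col]]) | !nzchar(records[[col]])
    if (any(bad)) {
      stop(sprintf("empty %s label at row(s): %s", col,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  records$guild <- as.character(records$guild)
  records$guild[is.na(records$guild) | !nzchar(records$guild)] <- "unknown"
  bad_guild <- !records$guild %in% guild_levels(unknown = TRUE)
  if (any(bad_guild)) {
    stop("invalid guild label(s): ",
         paste(unique(records$guild[bad_guild]), collapse = ", "),
         " (allowed: herbivore, predator, scavenger, unknown)",
         call. = FALSE)
  }
  cnt <- records$count
  bad_cnt <- is.na(cnt) | !is.numeric(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad_cnt)) {
    stop("negative or non-integer count at row(s): ",
         paste(which(bad_cnt), collapse = ", "), call. = FALSE)
  }
  records$count <- as.integer(round(cnt))
  dup <- duplicated(records$taxon_id)
  if (any(dup)) {
    stop("duplicate taxon_id: ",
         paste(unique(records$taxon_id[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records, metadata = as.character(metadata),
            class = c("community_table", "data.frame"))
}

guild_levels <- function(unknown = FALSE) {
  g <- c("herbivore", "predator", "scavenger")
  if (unknown) c(g, "unknown") else g
}

rank_levels <- function() c("species", "family", "order")

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa, N = %d individuals\n",
              nrow(x), sum(x$count)))
  md <- attr(x, "metadata")
  if (length(md)) cat(paste0("  ", md, collapse = "\n"), "\n")
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a community table from CSV
#'
#' Expects a comma-separated UTF-8 file with a mandatory header naming the
#' six fields `taxon_id,species,family,order,guild,count`. Lines starting
#' with `#` are treated as provenance comments and stored in the table's
#' metadata. Zero-count rows are retained and their number is noted in the
#' metadata.
#'
#' @param path path to a CSV file.
#' @return A [community_table()].
#' @export
read_community_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])
  body <- lines[!is_comment & nzchar(lines)]
  if (length(body) < 1L) stop("no header row in ", path, call. = FALSE)
  df <- read.csv(text = paste(body, collapse = "\n"),
                 colClasses = "character", check.names = FALSE)
  required <- c("taxon_id", "species", "family", "order", "guild", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad)) {
    stop("negative or non-integer count at row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  df$count <- as.integer(round(cnt))
  meta <- c(sprintf("source: %s", path), comments)
  nzero <- sum(df$count == 0L)
  if (nzero > 0L) meta <- c(meta, sprintf("%d zero-count record(s) retained", nzero))
  community_table(df, metadata = meta)
}

#' Write a community table to CSV
#'
#' Writes the same dialect [read_community_table()] reads; metadata entries
#' recording filters are emitted as `# filters:` comment lines so a filtered
#' table documents its own provenance.
#'
#' @param x a [community_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(x, path) {
  stopifnot(inherits(x, "community_table"))
  md <- attr(x, "metadata")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(md)) writeLines(paste0("# filters: ", md), con)
  write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ranked abundance vectors
#'
#' An abundance vector holds the strictly positive counts at one taxonomic
#' level, sorted in non-increasing order (ties keep their input order, so
#' rank-abundance profiles are deterministic). It is the input expected by
#' all SAD fitting and diversity functions.
#'
#' @param counts positive integer counts.
#' @param labels optional parallel labels (species/family/order names).
#' @param level taxonomic level the counts describe.
#' @return An object of class `abundance_vector` with elements `level`,
#'   `counts` and `labels`.
#' @export
#' @examples
#' abundance_vector(c(5, 12, 3), labels = c("a", "b", "c"))
abundance_vector <- function(counts, labels = NULL,
                             level = c("species", "family", "order")) {
  level <- match.arg(level)
  if (length(counts) == 0L) stop("empty abundance vector", call. = FALSE)
  if (any(is.na(counts)) || any(counts <= 0) || any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (is.null(labels)) labels <- as.character(seq_along(counts))
  if (length(labels) != length(counts)) {
    stop("labels must parallel counts", call. = FALSE)
  }
  ord <- order(-counts)  # stable: ties keep input order
  structure(list(level = level, counts = counts[ord],
                 labels = as.character(labels)[ord]),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("abundance_vector (%s level): S = %d, N = %d\n",
              x$level, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
length.abundance_vector <- function(x) length(x$counts)

# coerce numeric vectors (tests, quick interactive use) to abundance_vector
as_abundance <- function(x, level = "species") {
  if (inherits(x, "abundance_vector")) return(x)
  abundance_vector(x, level = level)
}

#' Aggregate a community table to one taxonomic level
#'
#' Sums counts within each distinct label at the requested level, drops
#' groups whose total is zero, and returns the ranked abundance vector.
#' Total abundance is conserved: `sum` of the result equals the table's N
#' at every level.
#'
#' @param x a [community_table()].
#' @param level `"species"`, `"family"` or `"order"`.
#' @return An [abundance_vector()].
#' @export
aggregate_abundance <- function(x, level = c("species", "family", "order")) {
  stopifnot(inherits(x, "community_table"))
  level <- match.arg(level)
  labs <- x[[level]]
  f <- factor(labs, levels = unique(labs))  # first-appearance order
  tot <- rowsum(as.numeric(x$count), f)[, 1L]
  keep <- tot > 0
  if (!any(keep)) stop("no positive counts at level ", level, call. = FALSE)
  abundance_vector(tot[keep], labels = names(tot)[keep], level = level)
}

#' Exclude taxa matching a label at a taxonomic level
#'
#' Returns a new table without the records whose `level` label equals
#' `label`; the filter is recorded in the metadata and the original table is
#' unchanged. The canonical use is removing a hyper-dominant colonial taxon
#' (e.g. `family = "Formicidae"`) whose trap-by-trap recruitment swamps the
#' abundance structure of the rest of the community.
#'
#' @param x a [community_table()].
#' @param level `"species"`, `"family"` or `"order"`.
#' @param label label to remove at that level.
#' @return A filtered [community_table()]. If nothing matches, the input is
#'   returned unchanged with a warning.
#' @export
exclude_taxa <- function(x, level = c("species", "family", "order"), label) {
  stopifnot(inherits(x, "community_table"))
  level <- match.arg(level)
  stopifnot(is.character(label), length(label) == 1L)
  hit <- x[[level]] == label
  if (!any(hit)) {
    warning(sprintf("no records match %s = '%s'; table unchanged", level, label),
            call. = FALSE)
    return(x)
  }
  md <- c(attr(x, "metadata"),
          sprintf("exclude %s=%s (%d records, %d individuals removed)",
                  level, label, sum(hit), sum(x$count[hit])))
  community_table(as.data.frame(x)[!hit, , drop = FALSE], metadata = md)
}

#' Relative abundances
#'
#' @param x an [abundance_vector()] (or positive numeric counts).
#' @return Proportions `n_i / N`, summing to one.
#' @export
relative_abundance <- function(x) {
  x <- as_abundance(x)
  x$counts / sum(x$counts)
}
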