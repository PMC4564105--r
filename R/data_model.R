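# Core record types and the tab-separated count-table interchange format.
#
# A cohort table is a data.frame with one row per sequencing measurement of
# one individual at one culture passage.  Extra columns are carried along
# untouched so round-trips are lossless.

.required_columns <- c(
  "sample_id", "individual_id", "family_id", "cohort", "disease",
  "component", "passage", "replicate", "total_reads", "alt_reads"
)

.cohort_levels    <- c("WM_FAMILY", "MM_FAMILY", "REFERENCE")
.disease_levels   <- c("WM", "MGUS", "MM", "OTHER")
.component_levels <- c("IgM", "IgG", "IgA", "NONE")

#' Construct and validate a cohort count table
#'
#' A cohort table holds one row per deep-amplicon measurement: the sequenced
#' individual, its cohort and disease labels, the culture passage number
#' (0 = uncultured blood), a replicate index, and the total / mutant-allele
#' read counts at the assayed locus.
#'
#' @param x A data.frame containing at least the columns `sample_id`,
#'   `individual_id`, `family_id`, `cohort` (one of `WM_FAMILY`,
#'   `MM_FAMILY`, `REFERENCE`), `disease` (`WM`, `MGUS`, `MM`, `OTHER`),
#'   `component` (`IgM`, `IgG`, `IgA`, `NONE`), `passage`, `replicate`,
#'   `total_reads`, `alt_reads`.  Additional columns are preserved verbatim.
#' @param provenance Free-text note on where the counts came from.
#' @return An object of class `cohort_table` (a validated data.frame).
#' @examples
#' tab <- cohort_table(data.frame(
#'   sample_id = "s1", individual_id = "i1", family_id = "",
#'   cohort = "REFERENCE", disease = "OTHER", component = "NONE",
#'   passage = 0L, replicate = 1L, total_reads = 10000L, alt_reads = 12L))
#' nrow(tab)
#' @export
cohort_table <- function(x, provenance = "") {
  stopifnot(is.data.frame(x))
  missing <- setdiff(.required_columns, names(x))
  if (length(missing) > 0L) {
    stop("count table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("sample_id", "individual_id", "family_id", "cohort",
                "disease", "component")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$family_id[is.na(x$family_id)] <- ""
  for (col in c("passage", "replicate", "total_reads", "alt_reads")) {
    v <- x[[col]]
    iv <- suppressWarnings(as.integer(v))
    if (anyNA(iv) || any(abs(as.numeric(v) - iv) > 0, na.rm = TRUE)) {
      stop("column '", col, "' must be integer-valued", call. = FALSE)
    }
    x[[col]] <- iv
  }
  validate_cohort_table(x)
  # required columns first, annotations after, input row order preserved
  extra <- setdiff(names(x), .required_columns)
  x <- x[, c(.required_columns, extra), drop = FALSE]
  rownames(x) <- NULL
  attr(x, "provenance") <- provenance
  class(x) <- c("cohort_table", "data.frame")
  x
}

validate_cohort_table <- function(x) {
  bad <- which(x$alt_reads > x$total_reads)
  if (length(bad) > 0L) {
    stop("alt_reads exceeds total_reads in row ", bad[1L],
         " (sample_id '", x$sample_id[bad[1L]], "')", call. = FALSE)
  }
  if (any(x$total_reads < 0L) || any(x$alt_reads < 0L)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(x$passage < 0L)) stop("passage must be >= 0", call. = FALSE)
  if (any(x$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  for (col in c("cohort", "disease", "component")) {
    lv <- switch(col, cohort = .cohort_levels, disease = .disease_levels,
                 component = .component_levels)
    bad <- setdiff(unique(x[[col]]), lv)
    if (length(bad) > 0L) {
      stop("column '", col, "' contains unknown level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(x$individual_id, x$passage, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (individual_id, passage, replicate) combination: ",
         gsub("\r", "/", d), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort table: %d samples, %d individuals\n",
              nrow(x), length(unique(x$individual_id))))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("provenance:", prov, "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a cohort count table from a tab-separated file
#'
#' The dialect is tab-separated, UTF-8, `.` decimal separator, no quoting,
#' with a mandatory header row naming all required columns (see
#' [cohort_table()]).  Unknown extra columns are preserved as opaque
#' annotations.
#'
#' @param path Path to a TSV file.
#' @param provenance Provenance note attached to the result; defaults to
#'   the file path.
#' @return A `cohort_table`.
#' @export
read_count_table <- function(path, provenance = path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), fileEncoding = "UTF-8")
  dup <- names(raw)[duplicated(names(raw))]
  if (length(dup) > 0L) {
    stop("duplicate column(s) in header: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.required_columns, names(raw))
  if (length(missing) > 0L) {
    stop("count table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("passage", "replicate", "total_reads", "alt_reads")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(v) && !anyNA(raw[[col]])) {
      stop("column '", col, "' is not integer-valued", call. = FALSE)
    }
    raw[[col]] <- v
  }
  # numeric- and logical-looking annotation columns are converted back
  extra <- setdiff(names(raw), .required_columns)
  for (col in extra) {
    if (all(raw[[col]] %in% c("TRUE", "FALSE"))) {
      raw[[col]] <- as.logical(raw[[col]])
      next
    }
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (!anyNA(v)) raw[[col]] <- v
  }
  cohort_table(raw, provenance = provenance)
}

#' Write a cohort count table to a tab-separated file
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(t))`
#' reproduces `t` field for field, including annotation columns.
#'
#' @param table A `cohort_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  ok <- tryCatch({
    write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write count table to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Load the bundled 19-individual passage-series count table
#'
#' The package ships, as a plain-text fixture, the published count table of
#' 19 mutation-positive individuals (15 from Waldenstrom-family kindreds, 4
#' from multiple-myeloma-family kindreds) measured at passages 0 (uncultured
#' blood), 4 and 9 after EBV immortalization: 57 samples in all.  The
#' annotation column `af_printed_pct` carries the allele fraction (percent,
#' 2 decimals) as printed in the source table, for cross-checking.
#'
#' @return A `cohort_table` with 57 rows.
#' @examples
#' tab <- load_table1_fixture()
#' subset(tab, individual_id == "34" & passage == 9)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_myd88_l265p.tsv",
                      package = "ampliclone", mustWork = TRUE)
  read_count_table(path, provenance = "bundled published count table (19 individuals x 3 passages)")
}
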