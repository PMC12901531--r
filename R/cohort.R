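#' @title Segment-level cohort data model
#' @description A cohort is a data frame of myocardial segments, one row per
#'   segment, clustered within subjects. Ordinal viability scores follow the
#'   AHA 17-segment convention: FDG uptake, LGE scar transmurality and
#'   wall-motion abnormality (WMA) are each scored 0-4; recovery is the binary
#'   indicator of wall-motion improvement between baseline and follow-up.
#' @name cohort
NULL

COHORT_COLUMNS <- c(
  "subject_id", "segment_id", "fdg", "lge", "wma_baseline",
  "wma_followup", "recovery", "in_cto_territory", "sim_perfect", "sim_flawed"
)
MANDATORY_COLUMNS <- c(
  "subject_id", "segment_id", "fdg", "lge", "wma_baseline",
  "recovery", "in_cto_territory"
)
SCORE_COLUMNS <- c("fdg", "lge", "wma_baseline", "wma_followup")
BINARY_COLUMNS <- c("recovery", "sim_perfect", "sim_flawed")

#' Construct and validate a cohort
#'
#' @param records data frame with at least the mandatory columns
#'   `subject_id`, `segment_id`, `fdg`, `lge`, `wma_baseline`, `recovery`,
#'   `in_cto_territory`; optionally `wma_followup`, `sim_perfect`,
#'   `sim_flawed`.
#' @param provenance free-text metadata recording where the records came from.
#' @param require_both_classes if `TRUE` (default) validation demands at least
#'   2 subjects and both recovery classes, the preconditions of every
#'   analysis entry point.
#' @return the validated records as a `cohort` object (a data frame).
#' @export
as_cohort <- function(records, provenance = "unspecified",
                      require_both_classes = TRUE) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    stop("cohort has no records", call. = FALSE)
  }
  records$subject_id <- as.character(records$subject_id)
  records$in_cto_territory <- as.logical(records$in_cto_territory)

  check_int_range <- function(col, lo, hi, allow_na = FALSE) {
    x <- records[[col]]
    if (is.null(x)) return(invisible())
    bad <- !is.na(x) & (x %% 1 != 0 | x < lo | x > hi)
    if (!allow_na && anyNA(x)) {
      stop("column '", col, "' has missing values on row(s) ",
           paste(utils::head(which(is.na(x)), 5), collapse = ", "),
           call. = FALSE)
    }
    if (any(bad)) {
      stop("column '", col, "' outside {", lo, ",...,", hi, "} on row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
    records[[col]] <<- as.integer(x)
  }
  check_int_range("segment_id", 1L, 17L)
  for (col in intersect(SCORE_COLUMNS, names(records))) {
    check_int_range(col, 0L, 4L, allow_na = col == "wma_followup")
  }
  for (col in intersect(BINARY_COLUMNS, names(records))) {
    check_int_range(col, 0L, 1L)
  }
  dup <- duplicated(records[c("subject_id", "segment_id")])
  if (any(dup)) {
    d <- records[which(dup)[1], ]
    stop("duplicated (subject, segment) pair ('", d$subject_id, "', ",
         d$segment_id, ") on row ", which(dup)[1], call. = FALSE)
  }
  if ("wma_followup" %in% names(records) && !anyNA(records$wma_followup)) {
    implied <- as.integer(records$wma_followup < records$wma_baseline)
    if (any(implied != records$recovery)) {
      stop("recovery inconsistent with wall-motion improvement ",
           "(followup < baseline) on row(s) ",
           paste(utils::head(which(implied != records$recovery), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (require_both_classes) {
    if (length(unique(records$subject_id)) < 2) {
      stop("cohort must contain at least 2 subjects", call. = FALSE)
    }
    if (length(unique(records$recovery)) < 2) {
      stop("cohort must contain both recovery classes", call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("cohort", "data.frame"))
}

#' Read a cohort from CSV
#'
#' Columns are lower-snake-case; `subject_id, segment_id, fdg, lge,
#' wma_baseline, recovery, in_cto_territory` are mandatory,
#' `wma_followup, sim_perfect, sim_flawed` optional.
#'
#' @param path CSV file path.
#' @param format only `"csv"` is supported.
#' @param ... passed to [as_cohort()].
#' @return a validated [cohort].
#' @export
load_cohort <- function(path, format = "csv", ...) {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(records, provenance = path, ...)
}

#' Write a cohort to CSV
#'
#' The written file round-trips through [load_cohort()] to an identical
#' record collection (columns in the documented fixed order).
#'
#' @param cohort a validated [cohort].
#' @param path output CSV path.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  cols <- intersect(COHORT_COLUMNS, names(cohort))
  utils::write.csv(as.data.frame(cohort)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Apply the study's segment inclusion filter
#'
#' Retains the segments with baseline wall-motion abnormality (`wma_baseline
#' > 0`) lying in the territory of the occluded coronary artery
#' (`in_cto_territory`); subjects left without qualifying segments drop out
#' entirely. The filter is idempotent.
#'
#' @param cohort a validated [cohort].
#' @return the filtered [cohort].
#' @export
apply_inclusion_filter <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- cohort$wma_baseline > 0 & cohort$in_cto_territory
  kept <- as.data.frame(cohort)[keep, , drop = FALSE]
  if (nrow(kept) == 0 || length(unique(kept$recovery)) < 2 ||
      length(unique(kept$subject_id)) < 2) {
    stop("inclusion filter left an unanalyzable cohort ",
         "(empty, single-class or single-subject)", call. = FALSE)
  }
  as_cohort(kept, provenance = attr(cohort, "provenance"))
}

#' Derive the binary recovery outcome from paired wall-motion scores
#'
#' Recovery is 1 when the follow-up WMA score improved (strictly decreased by
#' at least one point, the minimal resolvable change on the 5-point scale)
#' relative to baseline; unchanged or worsened segments are class 0.
#'
#' @param cohort a [cohort] whose records all carry `wma_followup`.
#' @return the cohort with `recovery` recomputed.
#' @export
derive_recovery <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$wma_followup) || anyNA(cohort$wma_followup)) {
    stop("derive_recovery requires wma_followup on every record",
         call. = FALSE)
  }
  out <- as.data.frame(cohort)
  out$recovery <- as.integer(out$wma_followup < out$wma_baseline)
  as_cohort(out, provenance = attr(cohort, "provenance"),
            require_both_classes = FALSE)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x), " segments, ",
      length(unique(x$subject_id)), " subjects, ",
      sum(x$recovery), ":", sum(x$recovery == 0),
      " recovered:unrecovered\n", sep = "")
  NextMethod()
}
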