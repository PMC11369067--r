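#' Construct an abundance table
#'
#' An abundance table is a numeric matrix with samples as rows and species as
#' columns, holding relative abundances (unitless fractions). This constructor
#' validates the matrix and attaches the `abundance_table` class; most
#' functions in the package also accept a plain validated matrix.
#'
#' @param values numeric matrix, samples x species, all entries >= 0.
#' @return the validated matrix with class `abundance_table`.
#' @export
abundance_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("abundance table must be a numeric matrix (samples x species)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance table requires sample row names and species column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate species identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric value at sample '%s', species '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', species '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  class(values) <- c("abundance_table", class(values))
  values
}

#' Read a wide-format taxonomic abundance table
#'
#' Expects one row per sample and one column per species (use
#' `transpose = TRUE` for species-as-rows exports), with the first column
#' holding the row identifiers.
#'
#' @param path file path of a TSV or CSV table.
#' @param dialect `"tsv"` or `"csv"`.
#' @param transpose logical; set `TRUE` if rows are species and columns samples.
#' @return an [abundance_table()] matrix.
#' @export
read_abundance_table <- function(path, dialect = c("tsv", "csv"), transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"", comment.char = "")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & body[[j]] != "NA")
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1]], colnames(body)[j], body[[j]][bad[1]]))
    m[, j] <- v
  }
  if (transpose) m <- t(m)
  abundance_table(m)
}

#' Write an abundance table
#'
#' @param x abundance matrix (samples x species).
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an abundance table to relative abundances
#'
#' Each sample (row) is divided by its total so rows sum to one; proportions
#' within a sample are preserved. Already-relative rows are unchanged.
#'
#' @param x abundance matrix (samples x species), counts or fractions.
#' @return matrix of the same shape with unit row sums.
#' @export
to_relative <- function(x) {
  rs <- rowSums(x)
  if (any(rs <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(rownames(x)[rs <= 0], collapse = ", "))
  out <- x / rs
  class(out) <- class(x)
  out
}

#' Apply a relative-abundance detection threshold
#'
#' Entries below the detection limit `tau` are set to zero and treated as
#' absent everywhere downstream. Sub-threshold mass is discarded, not
#' redistributed, so each row afterwards sums to at most one; the retained
#' fraction per sample is recorded in the `"retained"` attribute. Set
#' `renormalize = TRUE` to re-close rows to unit sum for sensitivity analyses.
#'
#' @param x relative abundance matrix (samples x species).
#' @param tau detection limit as a relative-abundance fraction, default 0.001
#'   (i.e. 0.1%).
#' @param renormalize logical; re-close rows after thresholding (default FALSE).
#' @return thresholded matrix with attribute `retained` (named per-sample
#'   fraction of abundance kept, before any renormalisation).
#' @export
apply_detection_threshold <- function(x, tau = 0.001, renormalize = FALSE) {
  stopifnot(tau >= 0, tau < 1)
  before <- rowSums(x)
  out <- x
  out[out < tau] <- 0
  retained <- ifelse(before > 0, rowSums(out) / before, 0)
  if (renormalize) {
    nz <- rowSums(out) > 0
    out[nz, ] <- out[nz, , drop = FALSE] / rowSums(out[nz, , drop = FALSE])
  }
  attr(out, "retained") <- stats::setNames(as.numeric(retained), rownames(x))
  out
}

#' Retained abundance fraction after thresholding
#'
#' @param x result of [apply_detection_threshold()].
#' @return named numeric vector of per-sample retained fractions.
#' @export
retained_fraction <- function(x) {
  r <- attr(x, "retained")
  if (is.null(r)) stop("no retained-fraction attribute; threshold the table first")
  r
}

#' Study time windows for engraftment assessment
#'
#' Defaults follow the trial layout: FMT infusions are given weekly from week
#' 3 to 6, the acute window covers the samples taken one week after each
#' infusion (weeks 4-7), the durable window the samples from two weeks after
#' the final infusion onwards (weeks 8-14), and overall spans both.
#'
#' @param acute,durable,overall inclusive integer week ranges `c(lo, hi)`.
#' @return named list of integer ranges.
#' @export
window_specs <- function(acute = c(4L, 7L), durable = c(8L, 14L),
                         overall = c(4L, 14L)) {
  w <- list(acute = acute, durable = durable, overall = overall)
  for (nm in names(w)) {
    r <- w[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("malformed window range: ", nm)
  }
  w
}

#' Assign a study week to its windows
#'
#' @param week integer study week.
#' @param windows window list from [window_specs()].
#' @return character vector of window names whose inclusive range contains
#'   `week` (possibly empty, e.g. for pre-FMT weeks).
#' @export
assign_window <- function(week, windows = window_specs()) {
  names(windows)[vapply(windows, function(r) week >= r[1] && week <= r[2],
                        logical(1))]
}

#' Read a cohort metadata table
#'
#' @param path TSV/CSV with required columns `sample_id`, `subject_id`,
#'   `role` (donor|recipient), `donor_id`, `week`, `arm`; extra columns pass
#'   through.
#' @param dialect `"tsv"` or `"csv"`.
#' @return data.frame of per-sample metadata.
#' @export
read_cohort_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  meta$week <- as.integer(meta$week)
  meta
}

#' Validate cohort metadata against an abundance table
#'
#' Checks required columns, role values, week uniqueness per subject, that
#' every recipient has at least one pre-FMT sample and a donor with samples,
#' and (when `profiles` is supplied) that sample identifiers match.
#'
#' @param meta metadata data.frame (see [read_cohort_metadata()]).
#' @param profiles optional abundance matrix whose row names must equal
#'   `meta$sample_id`.
#' @param first_post_fmt_week first study week considered post-FMT; samples
#'   with `week` strictly below it are pre-FMT baseline (default 4).
#' @return `meta`, invisibly, on success; errors otherwise.
#' @export
validate_cohort_metadata <- function(meta, profiles = NULL,
                                     first_post_fmt_week = 4L) {
  req <- c("sample_id", "subject_id", "role", "donor_id", "week", "arm")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$role %in% c("donor", "recipient")))
    stop("role must be 'donor' or 'recipient'")
  dup <- stats::aggregate(week ~ subject_id, meta, function(w) anyDuplicated(w) > 0)
  if (any(dup$week))
    stop("duplicated weeks for subject(s): ",
         paste(dup$subject_id[dup$week], collapse = ", "))
  donors <- unique(meta$subject_id[meta$role == "donor"])
  rec <- meta[meta$role == "recipient", , drop = FALSE]
  for (s in unique(rec$subject_id)) {
    rows <- rec[rec$subject_id == s, , drop = FALSE]
    if (!any(rows$week < first_post_fmt_week))
      stop("recipient ", s, " has no pre-FMT sample (week < ",
           first_post_fmt_week, ")")
    d <- unique(rows$donor_id)
    if (length(d) != 1) stop("recipient ", s, " has inconsistent donor_id")
    if (!d %in% donors)
      stop("recipient ", s, " assigned donor ", d, " with no samples")
  }
  if (!is.null(profiles)) {
    if (!setequal(rownames(profiles), meta$sample_id))
      stop("sample_id mismatch between profiles and metadata")
  }
  invisible(meta)
}
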