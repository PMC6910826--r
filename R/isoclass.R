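#' Isoform annotation records
#'
#' Validates a transcript annotation table: one row per transcript with
#' its gene, LIM-domain count and ZM/PDZ presence. The LIM-domain count
#' is the sole determinant of the growing/blocking classification; the
#' other fields document the architecture.
#'
#' @param transcript_id Character vector of unique transcript ids.
#' @param gene Gene symbol per transcript (`Zasp52`, `Zasp66`,
#'   `Zasp67`, or other).
#' @param n_lim Non-negative integer LIM-domain count per transcript.
#' @param has_zm,has_pdz Logical flags for the ZM and PDZ domains.
#' @return A validated data.frame of class `isoform_records`.
#' @export
isoform_records <- function(transcript_id, gene, n_lim,
                            has_zm = TRUE, has_pdz = TRUE) {
  if (anyDuplicated(transcript_id))
    stop("`transcript_id` must be unique")
  if (any(n_lim < 0) || any(n_lim != round(n_lim)))
    stop("`n_lim` must be non-negative integers")
  out <- data.frame(transcript_id = as.character(transcript_id),
                    gene = as.character(gene),
                    n_lim = as.integer(n_lim),
                    has_zm = rep_len(as.logical(has_zm),
                                     length(transcript_id)),
                    has_pdz = rep_len(as.logical(has_pdz),
                                      length(transcript_id)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("isoform_records", "data.frame"))
}

#' Isoform expression set
#'
#' A transcript x timepoint TPM matrix joined one-to-one to its
#' annotation records, the container for class-wise developmental
#' time-course summaries.
#'
#' @param tpm Numeric matrix, transcripts in rows (rownames =
#'   transcript ids), timepoints in columns; all values >= 0.
#' @param timepoints_h Strictly increasing hours APF, one per column.
#' @param records An [isoform_records()] table (or coercible
#'   data.frame) covering exactly the row ids of `tpm`.
#' @return An object of class `isoform_expression_set`.
#' @export
isoform_expression_set <- function(tpm, timepoints_h, records) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0) || anyNA(tpm)) stop("TPM values must be >= 0")
  if (length(timepoints_h) != ncol(tpm))
    stop("one timepoint per TPM column required")
  if (any(diff(timepoints_h) <= 0))
    stop("`timepoints_h` must be strictly increasing")
  if (!inherits(records, "isoform_records"))
    records <- isoform_records(records$transcript_id, records$gene,
                               records$n_lim,
                               records$has_zm %||% TRUE,
                               records$has_pdz %||% TRUE)
  if (is.null(rownames(tpm))) rownames(tpm) <- records$transcript_id
  if (!identical(sort(rownames(tpm)), sort(records$transcript_id)))
    stop("TPM row ids and annotation records must match one-to-one")
  records <- records[match(rownames(tpm), records$transcript_id), ]
  rownames(records) <- NULL
  structure(list(tpm = tpm, timepoints_h = as.numeric(timepoints_h),
                 records = records),
            class = "isoform_expression_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.isoform_expression_set <- function(x, ...) {
  cat(sprintf(
    "isoform_expression_set: %d transcripts x %d timepoints (%g-%g h APF)\n",
    nrow(x$tpm), ncol(x$tpm), min(x$timepoints_h), max(x$timepoints_h)))
  print(table(classify_isoform(x$records)))
  invisible(x)
}

#' Classify isoforms as growing or blocking
#'
#' A Zasp isoform is a growing isoform when it carries two or more LIM
#' domains (multivalent: it can recruit further Zasp molecules via
#' LIM-ZM binding and enlarge the Z-disc) and a blocking isoform when it
#' carries 0 or 1 LIM domain (it terminates recruitment). The
#' classification is a total deterministic function of the LIM-domain
#' count.
#'
#' @param records An [isoform_records()] table, or a numeric vector of
#'   LIM-domain counts.
#' @return Character vector `"growing"` / `"blocking"`, one per record.
#' @export
classify_isoform <- function(records) {
  n_lim <- if (is.numeric(records)) records else {
    stopifnot(is.data.frame(records), "n_lim" %in% names(records))
    records$n_lim
  }
  if (any(n_lim < 0)) stop("`n_lim` must be >= 0")
  ifelse(n_lim >= 2, "growing", "blocking")
}

#' Class-wise expression time-course
#'
#' Groups transcripts by [classify_isoform()] (optionally further by
#' gene) and reports the per-class mean TPM at each timepoint, both raw
#' and as `log10(TPM + 1)` for display. Classes with zero members are
#' omitted with a warning.
#'
#' @param expr An [isoform_expression_set()].
#' @param by `"class"` (default) or `"gene_class"` for a finer grouping
#'   by (gene, class).
#' @return A data.frame of class `class_timecourse`: columns `class`,
#'   `timepoint_h`, `mean_tpm`, `mean_log_tpm`, `n_isoforms`.
#' @export
class_timecourse <- function(expr, by = c("class", "gene_class")) {
  stopifnot(inherits(expr, "isoform_expression_set"))
  by <- match.arg(by)
  cls <- classify_isoform(expr$records)
  grp <- if (by == "class") cls else paste(expr$records$gene, cls, sep = ":")
  for (want in c("growing", "blocking"))
    if (by == "class" && !want %in% grp)
      warning("class '", want, "' has zero members and is omitted")
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    rows <- grp == g
    m <- colMeans(expr$tpm[rows, , drop = FALSE])
    data.frame(class = g, timepoint_h = expr$timepoints_h,
               mean_tpm = as.numeric(m),
               mean_log_tpm = log10(m + 1),
               n_isoforms = sum(rows), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("class_timecourse", "data.frame"), by = by)
}

#' Onset time of a class time-course
#'
#' Operationalises "switched on by hour t" as the linearly interpolated
#' time at which a class's mean expression first crosses a fraction
#' (default one half) of its plateau (maximum mean). Growing isoforms
#' are already strongly expressed around 24 h APF whereas blocking
#' isoforms rise only around 60 h APF, so recovered onsets order
#' growing < blocking.
#'
#' @param tc A `class_timecourse` (possibly filtered to one class), or
#'   any data.frame with `class`, `timepoint_h` and `mean_tpm` columns.
#' @param fraction_of_plateau Crossing level as a fraction of the
#'   maximum mean (default 0.5).
#' @return Named numeric vector of onset hours APF, one per class;
#'   `NA` (with a message) for a flat or zero time-course.
#' @export
onset_time <- function(tc, fraction_of_plateau = 0.5) {
  stopifnot(is.data.frame(tc),
            all(c("class", "timepoint_h", "mean_tpm") %in% names(tc)))
  stopifnot(fraction_of_plateau > 0, fraction_of_plateau < 1)
  vapply(split(tc, tc$class), function(d) {
    d <- d[order(d$timepoint_h), ]
    y <- d$mean_tpm; t <- d$timepoint_h
    plateau <- max(y)
    if (plateau <= 0 || diff(range(y)) == 0) {
      message("flat time-course for class '", d$class[1],
              "': onset undefined")
      return(NA_real_)
    }
    if (any(diff(y) < -0.25 * plateau))
      warning("time-course for class '", d$class[1],
              "' is far from non-decreasing; onset may be unreliable")
    lev <- fraction_of_plateau * plateau
    i <- which(y >= lev)[1]
    if (i == 1L) return(t[1])
    t[i - 1] + (lev - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }, numeric(1))
}

#' Read an isoform TPM table with annotations
#'
#' Loads an externally quantified TPM table (CSV/TSV; transcripts in
#' rows, a header row of hours APF over the value columns) and a
#' matching annotation table (`transcript_id`, `gene`, `n_lim`,
#' optional `has_zm`, `has_pdz`), and returns a validated
#' [isoform_expression_set()]. Quantification itself (e.g. Salmon over
#' an SRA project) is outside this package's scope.
#'
#' @param tpm_path Path to the TPM table; first column transcript id,
#'   remaining column names coercible to hours APF.
#' @param annotation_path Path to the annotation CSV.
#' @param sep Field separator (default `,`; use `"\t"` for TSV).
#' @return An [isoform_expression_set()].
#' @export
read_isoform_tpm <- function(tpm_path, annotation_path, sep = ",") {
  tab <- utils::read.table(tpm_path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  ann <- utils::read.table(annotation_path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  ids <- tab[[1]]
  tpm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(tpm) <- ids
  tp <- suppressWarnings(as.numeric(colnames(tpm)))
  if (anyNA(tp))
    stop("TPM column names must be hours APF; got: ",
         paste(colnames(tpm), collapse = ", "))
  rec <- isoform_records(ann$transcript_id, ann$gene, ann$n_lim,
                         ann$has_zm %||% TRUE, ann$has_pdz %||% TRUE)
  isoform_expression_set(tpm, tp, rec)
}
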