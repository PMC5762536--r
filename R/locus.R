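#' Parse a locus string into internal coordinates
#'
#' @param x Locus as `"chrom:start-end"`.
#' @param one_based Interpret the coordinates as 1-based inclusive (the
#'   usual browser convention; default) and convert to the internal
#'   0-based half-open form.  With `FALSE` the coordinates are taken as
#'   already 0-based half-open.
#' @return A list with `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_locus <- function(x, one_based = TRUE) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop_ln("locus must be 'chrom:start-end', got '", x, "'")
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (one_based) start <- start - 1
  if (!(start < end)) stop_ln("locus start must be before end")
  list(chrom = m[2], start = start, end = end)
}

#' Classify the miRNAs of a genomic locus by the two-fold rule
#'
#' A miRNA belongs to the locus when its interval intersects the locus
#' interval.  Members are called `up` or `down` when their fold-change
#' magnitude is at least `fc_threshold` (inclusive, so fc = 2.0 counts) in
#' the corresponding direction, and `unchanged` otherwise.  By design the
#' rule uses the fold change alone; supply `p_threshold` to additionally
#' require a t-test p value below it.
#'
#' @param mirna_de Differential-expression table for the miRNA matrix.
#' @param locus List with `chrom`, `start`, `end` (0-based half-open; see
#'   [parse_locus()]).
#' @param annotation Annotation table containing the miRNA coordinates.
#' @param fc_threshold Fold-change cut-off (default 2).
#' @param p_threshold Optional raw-p gate (default `NULL`, none).
#' @return Named character vector `mirna_id -> up/down/unchanged`.
#' @export
classify_locus_mirnas <- function(mirna_de, locus, annotation,
                                  fc_threshold = 2, p_threshold = NULL) {
  mir <- annotation[annotation$biotype == "miRNA", , drop = FALSE]
  inside <- mir$chrom == locus$chrom & mir$start < locus$end &
    locus$start < mir$end
  members <- mir$feature_id[inside]
  if (!length(members))
    stop_ln("locus ", locus$chrom, ":", locus$start, "-", locus$end,
            " contains no annotated miRNAs")
  miss <- setdiff(members, mirna_de$feature_id)
  if (length(miss))
    stop_ln("locus miRNA(s) absent from the DE table: ",
            paste(miss, collapse = ", "))
  rec <- mirna_de[match(members, mirna_de$feature_id), , drop = FALSE]
  changed <- rec$fc >= fc_threshold
  if (!is.null(p_threshold)) changed <- changed & rec$p < p_threshold
  status <- ifelse(changed, rec$direction, "unchanged")
  setNames(status, members)
}

#' Summarise up/down/unchanged counts for a locus
#'
#' Percentages are rounded half-up to 2 decimals (e.g. 30 of 49 down gives
#' 61.22).
#'
#' @param statuses Named status vector from [classify_locus_mirnas()], or
#'   any character vector over `up`, `down`, `unchanged`.
#' @return One-row `data.frame`: `n_total`, `n_up`, `n_down`,
#'   `n_unchanged`, `pct_up`, `pct_down`, `pct_unchanged`.
#' @export
locus_summary <- function(statuses) {
  if (!length(statuses)) stop_ln("empty status vector")
  bad <- setdiff(unique(statuses), c("up", "down", "unchanged"))
  if (length(bad))
    stop_ln("unknown status value(s): ", paste(bad, collapse = ", "))
  n <- length(statuses)
  n_up <- sum(statuses == "up")
  n_down <- sum(statuses == "down")
  n_unch <- n - n_up - n_down
  data.frame(n_total = n, n_up = n_up, n_down = n_down,
             n_unchanged = n_unch,
             pct_up = round_half_up(100 * n_up / n, 2),
             pct_down = round_half_up(100 * n_down / n, 2),
             pct_unchanged = round_half_up(100 * n_unch / n, 2))
}
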