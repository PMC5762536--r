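#' Select the most dysregulated lncRNAs
#'
#' Takes the `n` significant records with the largest fold-change magnitude
#' regardless of direction.  Ties are broken by smaller p value, then by
#' lexicographic feature id.  When fewer than `n` records are significant,
#' all of them are returned with a note.
#'
#' @param records Differential-expression table for the lncRNA class.
#' @param n Number of lncRNAs to select (default 200).
#' @return Character vector of selected feature ids.
#' @export
select_top_lncrnas <- function(records, n = 200) {
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) < n)
    ln_note("only ", nrow(sig), " significant lncRNAs available (asked for ",
            n, ")")
  ord <- order(-sig$fc, sig$p, sig$feature_id)
  head(sig$feature_id[ord], n)
}

#' Genomic-window cis-regulation pairing
#'
#' For each selected lncRNA, coding genes on the same chromosome whose
#' interval lies within `window` bp of the lncRNA interval (gap between
#' closest edges, boundary inclusive; overlap counts as distance 0) are
#' candidate cis partners.  A candidate pair is kept when the two-sided
#' Pearson correlation p value of the expression profiles (log2) is below
#' `p_max`.  The `relation` names the side of the mRNA relative to the
#' lncRNA on the lncRNA's strand.
#'
#' @param lnc_ids Selected lncRNA feature ids (see [select_top_lncrnas()]).
#' @param annotation Annotation covering all ids involved.
#' @param lnc_em,mrna_em Expression matrices sharing the same samples.
#' @param coding_ids Candidate coding feature ids (normally the significant
#'   coding features).
#' @param window Window size in bp (default 300000).
#' @param p_max Correlation p cut-off (default 0.05).
#' @return A `data.frame` sorted by `lncrna_id`, `mrna_id` with columns
#'   `lncrna_id`, `mrna_id`, `r`, `p`, `q` (BH over tested candidates),
#'   `sign`, `distance_bp`, `relation`.
#' @export
find_cis_pairs <- function(lnc_ids, annotation, lnc_em, mrna_em,
                           coding_ids, window = 300000, p_max = 0.05) {
  if (!identical(sample_ids(lnc_em), sample_ids(mrna_em)))
    stop_ln("matrices must share the same samples in the same order")
  miss <- setdiff(c(lnc_ids, coding_ids), annotation$feature_id)
  if (length(miss))
    stop_ln("unannotated feature id(s): ", paste(miss, collapse = ", "))
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      r = numeric(), p = numeric(), q = numeric(),
                      sign = character(), distance_bp = integer(),
                      relation = character(), stringsAsFactors = FALSE)
  if (!length(lnc_ids) || !length(coding_ids)) return(empty)
  al <- annotation[match(lnc_ids, annotation$feature_id), , drop = FALSE]
  ac <- annotation[match(coding_ids, annotation$feature_id), , drop = FALSE]
  gl <- ann_granges(al); gc <- ann_granges(ac)
  hits <- GenomicRanges::findOverlaps(gl, gc, maxgap = window,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(empty)
  d <- GenomicRanges::distance(gl[qh], gc[sh], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= window
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  if (!length(qh)) return(empty)

  L <- em_log2(lnc_em); M <- em_log2(mrna_em)
  rp <- vapply(seq_along(qh), function(k) {
    x <- L[al$feature_id[qh[k]], ]
    y <- M[ac$feature_id[sh[k]], ]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    out <- pearson_with_p(x, y)
    c(out$r, out$p)
  }, numeric(2))
  r <- rp[1, ]; p <- rp[2, ]
  if (anyNA(r)) {
    ln_note(sum(is.na(r)), " candidate pair(s) skipped (zero variance)")
  }
  q <- p.adjust(p, method = "BH")

  ovl <- al$start[qh] < ac$end[sh] & ac$start[sh] < al$end[qh]
  mrna_left <- ac$end[sh] <= al$start[qh]
  relation <- ifelse(ovl, "overlapping",
                     ifelse(mrna_left == (al$strand[qh] == "+"),
                            "upstream", "downstream"))
  sel <- !is.na(p) & p < p_max
  pairs <- data.frame(lncrna_id = al$feature_id[qh][sel],
                      mrna_id = ac$feature_id[sh][sel],
                      r = r[sel], p = p[sel], q = q[sel],
                      sign = ifelse(r[sel] >= 0, "positive", "negative"),
                      distance_bp = as.integer(d[sel]),
                      relation = relation[sel],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$lncrna_id, pairs$mrna_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Number of selected lncRNAs that found at least one cis partner
#'
#' @param lnc_ids Selected lncRNA feature ids.
#' @param pairs Cis pair table from [find_cis_pairs()].
#' @return Integer count of `lnc_ids` participating in >= 1 pair.
#' @export
count_localized <- function(lnc_ids, pairs) {
  length(intersect(lnc_ids, unique(pairs$lncrna_id)))
}
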