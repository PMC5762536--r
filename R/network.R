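#' Pearson correlation with a t-distribution p value
#'
#' The two-sided p value comes from the exact null transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Perfectly collinear vectors return `p = 0`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A list with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_ln("x and y must have equal length")
  if (length(x) < 3) stop_ln("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_ln("values must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop_ln("zero variance: correlation undefined")
  r <- min(1, max(-1, cor(x, y)))
  n <- length(x)
  p <- if (1 - r^2 <= 0) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(r = r, p = p)
}

# vectorized r/p over a lnc x mrna grid of log2 profiles
cor_grid <- function(L, M) {
  n <- ncol(L)
  r <- cor(t(L), t(M))
  r[r > 1] <- 1; r[r < -1] <- -1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tt), n - 2)
  p[1 - r^2 <= 0] <- 0
  list(r = r, p = p)
}

#' Build the lncRNA-mRNA co-expression edge list
#'
#' Scores every differentially expressed lncRNA against every
#' differentially expressed mRNA with Pearson correlation on log2 values
#' across the shared samples, adjusts the p values with Benjamini-Hochberg
#' over all scored pairs, and keeps an edge when `|r| >= r_min` and the
#' adjusted `q < q_max` (set `use_q = FALSE` to gate on the raw p instead).
#' Features with zero variance cannot be scored and are skipped with a
#' note.
#'
#' @param lnc_em,mrna_em [expression_matrix()] objects sharing the same
#'   samples in the same order (any scale; log2 is taken internally).
#' @param de_lnc_ids,de_mrna_ids Feature ids to score (normally the
#'   significant features of each class).
#' @param r_min Minimum absolute correlation (default 0.90).
#' @param q_max Significance cut-off (default 0.01).
#' @param use_q Gate on BH-adjusted q (default) or on raw p.
#' @return A `data.frame` of edges sorted by `lncrna_id`, `mrna_id`:
#'   columns `lncrna_id`, `mrna_id`, `r`, `p`, `q`, `sign`.
#' @export
build_edges <- function(lnc_em, mrna_em, de_lnc_ids, de_mrna_ids,
                        r_min = 0.90, q_max = 0.01, use_q = TRUE) {
  if (!identical(sample_ids(lnc_em), sample_ids(mrna_em)))
    stop_ln("matrices must share the same samples in the same order")
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      r = numeric(), p = numeric(), q = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (!length(de_lnc_ids) || !length(de_mrna_ids)) return(empty)
  L <- em_log2(lnc_em)[de_lnc_ids, , drop = FALSE]
  M <- em_log2(mrna_em)[de_mrna_ids, , drop = FALSE]
  varL <- apply(L, 1, sd) > 0
  varM <- apply(M, 1, sd) > 0
  if (!all(varL) || !all(varM))
    ln_note(sum(!varL) + sum(!varM),
            " zero-variance feature(s) skipped in correlation scoring")
  L <- L[varL, , drop = FALSE]; M <- M[varM, , drop = FALSE]
  if (!nrow(L) || !nrow(M)) return(empty)
  g <- cor_grid(L, M)
  q <- matrix(p.adjust(as.vector(g$p), method = "BH"), nrow = nrow(g$p))
  crit <- if (use_q) q < q_max else g$p < q_max
  keep <- which(abs(g$r) >= r_min & crit, arr.ind = TRUE)
  edges <- data.frame(
    lncrna_id = rownames(L)[keep[, 1]],
    mrna_id = rownames(M)[keep[, 2]],
    r = g$r[keep], p = g$p[keep], q = q[keep],
    sign = ifelse(g$r[keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges[order(edges$lncrna_id, edges$mrna_id), , drop = FALSE]
}

#' Edges incident to one coding gene, grouped by lncRNA gene of origin
#'
#' Extracts the network neighborhood of a coding gene (all lncRNA partners
#' of any of its transcripts) and annotates each edge with the lncRNA gene
#' its transcript belongs to, so multi-transcript lncRNA genes are visible
#' as groups.
#'
#' @param edges Edge list from [build_edges()].
#' @param gene_id Coding gene of interest.
#' @param annotation Annotation table mapping transcript `feature_id` to
#'   `gene_id`.
#' @return Edges incident to `gene_id`, with an extra `lncrna_gene` column,
#'   sorted by `lncrna_gene`, `lncrna_id`, `mrna_id`.  Unknown or
#'   unconnected genes yield an empty table (with a note).
#' @export
gene_neighborhood <- function(edges, gene_id, annotation) {
  tx2gene <- setNames(annotation$gene_id, annotation$feature_id)
  mg <- tx2gene[edges$mrna_id]
  mg[is.na(mg)] <- edges$mrna_id[is.na(mg)]
  sel <- edges[mg == gene_id | edges$mrna_id == gene_id, , drop = FALSE]
  if (!nrow(sel))
    ln_note("gene '", gene_id, "' has no incident edges")
  lg <- tx2gene[sel$lncrna_id]
  sel$lncrna_gene <- ifelse(is.na(lg), sel$lncrna_id, lg)
  sel <- sel[order(sel$lncrna_gene, sel$lncrna_id, sel$mrna_id), ,
             drop = FALSE]
  rownames(sel) <- NULL
  sel
}
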