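LNC_CLASSES <- c("sense", "antisense", "bidirectional", "intergenic",
                 "intronic")

#' Positional classification of lncRNAs against the coding annotation
#'
#' Each lncRNA is assigned exactly one label by a strand-aware decision
#' cascade, checked in this order:
#'
#' 1. `intronic` — wholly contained in a same-strand coding gene and
#'    overlapping none of that gene's exons (requires `exons`);
#' 2. `sense` — overlapping a coding exon on the same strand (without an
#'    exon model, any same-strand overlap with a coding gene counts, i.e.
#'    intronic collapses into sense);
#' 3. `antisense` — overlapping a coding gene on the opposite strand;
#' 4. `bidirectional` — not overlapping any coding gene, but head-to-head
#'    with an opposite-strand gene: the two 5' starts lie within
#'    `bidir_window` bp;
#' 5. `intergenic` — everything else.
#'
#' @param lnc Annotation rows of biotype `lncRNA` (must be stranded).
#' @param coding Annotation rows of biotype `coding`.
#' @param exons Optional exon model: `data.frame` with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @param bidir_window Promoter-sharing window for the bidirectional class,
#'   in bp (default 1000).
#' @return A `data.frame`: `lncrna_id`, `class`, `nearest_coding_gene`,
#'   `distance_bp` (gap to the nearest coding gene; 0 when overlapping,
#'   `NA` when no coding gene shares the chromosome).
#' @export
classify_lncrnas <- function(lnc, coding, exons = NULL,
                             bidir_window = 1000) {
  if (!nrow(lnc)) {
    return(data.frame(lncrna_id = character(), class = character(),
                      nearest_coding_gene = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  if (!all(lnc$strand %in% c("+", "-")))
    stop_ln("all lncRNAs must have a defined strand")
  if (!all(coding$strand %in% c("+", "-")))
    stop_ln("all coding genes must have a defined strand")
  gl <- ann_granges(lnc)
  gc <- ann_granges(coding)
  ov <- GenomicRanges::findOverlaps(gl, gc, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  same <- lnc$strand[qh] == coding$strand[sh]

  n <- nrow(lnc)
  is_sense <- logical(n); is_intronic <- logical(n)
  is_antisense <- logical(n)
  overlaps_any <- logical(n)
  overlaps_any[unique(qh)] <- TRUE
  is_antisense[unique(qh[!same])] <- TRUE

  if (is.null(exons)) {
    is_sense[unique(qh[same])] <- TRUE
  } else {
    ge <- GenomicRanges::GRanges(
      exons$chrom,
      IRanges::IRanges(exons$start + 1L, exons$end))
    ove <- GenomicRanges::findOverlaps(gl, ge, ignore.strand = TRUE)
    eqh <- S4Vectors::queryHits(ove); esh <- S4Vectors::subjectHits(ove)
    esame <- lnc$strand[eqh] == exons$strand[esh]
    is_sense[unique(eqh[esame])] <- TRUE
    # intronic: same-strand gene hit, lncRNA within the gene body, and no
    # overlap with any exon of that gene
    for (k in which(same)) {
      i <- qh[k]; j <- sh[k]
      within <- lnc$start[i] >= coding$start[j] &&
        lnc$end[i] <= coding$end[j]
      if (!within) next
      gene_ex <- which(exons$gene_id == coding$gene_id[j])
      hit_ex <- any(exons$start[gene_ex] < lnc$end[i] &
                      lnc$start[i] < exons$end[gene_ex])
      if (!hit_ex) is_intronic[i] <- TRUE
    }
  }

  # bidirectional: no gene overlap; 5' start within bidir_window of an
  # opposite-strand gene's 5' start (0-based: + strand 5' = start,
  # - strand 5' = end)
  tss_l <- ifelse(lnc$strand == "+", lnc$start, lnc$end)
  tss_c <- ifelse(coding$strand == "+", coding$start, coding$end)
  is_bidir <- vapply(seq_len(n), function(i) {
    if (overlaps_any[i]) return(FALSE)
    j <- which(coding$chrom == lnc$chrom[i] &
                 coding$strand != lnc$strand[i])
    any(abs(tss_c[j] - tss_l[i]) <= bidir_window)
  }, logical(1))

  cls <- rep("intergenic", n)
  cls[is_bidir] <- "bidirectional"
  cls[is_antisense] <- "antisense"
  cls[is_sense] <- "sense"
  cls[is_intronic] <- "intronic"

  nearest <- GenomicRanges::distanceToNearest(gl, gc, ignore.strand = TRUE)
  ng <- rep(NA_character_, n); nd <- rep(NA_integer_, n)
  ng[S4Vectors::queryHits(nearest)] <-
    coding$gene_id[S4Vectors::subjectHits(nearest)]
  nd[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  data.frame(lncrna_id = lnc$feature_id, class = cls,
             nearest_coding_gene = ng, distance_bp = nd,
             stringsAsFactors = FALSE)
}

#' Count differentially expressed lncRNAs per positional class
#'
#' @param de_lncrnas Differential-expression table for the lncRNA matrix;
#'   only rows flagged significant are tabulated.
#' @param classifications Output of [classify_lncrnas()] covering every
#'   significant lncRNA.
#' @return A 5-row `data.frame` (`class`, `n_up`, `n_down`) whose counts sum
#'   to the number of significant lncRNAs.
#' @export
subgroup_counts <- function(de_lncrnas, classifications) {
  sig <- de_lncrnas[de_lncrnas$significant, , drop = FALSE]
  miss <- setdiff(sig$feature_id, classifications$lncrna_id)
  if (length(miss))
    stop_ln("unclassified DE lncRNA(s): ", paste(miss, collapse = ", "))
  cls <- classifications$class[match(sig$feature_id,
                                     classifications$lncrna_id)]
  tab <- table(factor(cls, LNC_CLASSES),
               factor(sig$direction, c("up", "down")))
  data.frame(class = LNC_CLASSES,
             n_up = as.integer(tab[, "up"]),
             n_down = as.integer(tab[, "down"]),
             stringsAsFactors = FALSE)
}
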