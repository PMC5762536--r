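# shared fixtures and independent brute-force oracles

make_em <- function(values, n_case = 3, n_control = 3,
                    scale = "linear") {
  samples <- c(sprintf("case_%d", seq_len(n_case)),
               sprintf("control_%d", seq_len(n_control)))
  colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(n_case, n_control)), samples)
  expression_matrix(values, groups, scale)
}

random_em <- function(nf = 20, n_case = 3, n_control = 3, seed = 1,
                      base = 8, sd = 1) {
  set.seed(seed)
  make_em(matrix(2^rnorm(nf * (n_case + n_control), base, sd), nf),
          n_case, n_control)
}

small_annotation <- function() {
  data.frame(
    feature_id = c("G1", "G2", "L1", "L2", "M1"),
    gene_id = c("G1", "G2", "LG1", "LG2", "M1"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(1000L, 800000L, 5000L, 100L, 2000L),
    end = c(21000L, 820000L, 7000L, 300L, 2080L),
    strand = c("+", "-", "+", "-", "+"),
    biotype = c("coding", "coding", "lncRNA", "lncRNA", "miRNA"),
    stringsAsFactors = FALSE)
}

# brute-force window pairing on 0-based half-open coordinates
bf_window_pairs <- function(lnc_ann, cod_ann, window) {
  out <- list()
  for (i in seq_len(nrow(lnc_ann))) for (j in seq_len(nrow(cod_ann))) {
    if (lnc_ann$chrom[i] != cod_ann$chrom[j]) next
    ovl <- lnc_ann$start[i] < cod_ann$end[j] &&
      cod_ann$start[j] < lnc_ann$end[i]
    gap <- if (ovl) 0 else max(lnc_ann$start[i] - cod_ann$end[j],
                               cod_ann$start[j] - lnc_ann$end[i])
    if (gap <= window)
      out[[length(out) + 1]] <- data.frame(
        lncrna_id = lnc_ann$feature_id[i],
        mrna_id = cod_ann$feature_id[j], distance_bp = gap,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      distance_bp = integer()))
  df <- do.call(rbind, out)
  df[order(df$lncrna_id, df$mrna_id), , drop = FALSE]
}

# brute-force positional classifier (same definitions, plain arithmetic)
bf_classify <- function(lnc, coding, exons = NULL, bidir_window = 1000) {
  vapply(seq_len(nrow(lnc)), function(i) {
    l <- lnc[i, ]
    ov <- which(coding$chrom == l$chrom & coding$start < l$end &
                  l$start < coding$end)
    same <- ov[coding$strand[ov] == l$strand]
    opp <- ov[coding$strand[ov] != l$strand]
    if (!is.null(exons)) {
      for (j in same) {
        within <- l$start >= coding$start[j] && l$end <= coding$end[j]
        ex <- which(exons$gene_id == coding$gene_id[j])
        hit <- any(exons$chrom[ex] == l$chrom & exons$start[ex] < l$end &
                     l$start < exons$end[ex])
        if (within && !hit) return("intronic")
      }
      exs <- which(exons$chrom == l$chrom & exons$strand == l$strand &
                     exons$start < l$end & l$start < exons$end)
      if (length(exs)) return("sense")
    } else if (length(same)) return("sense")
    if (length(opp)) return("antisense")
    if (!length(ov)) {
      tss_l <- if (l$strand == "+") l$start else l$end
      cand <- which(coding$chrom == l$chrom & coding$strand != l$strand)
      tss_c <- ifelse(coding$strand[cand] == "+", coding$start[cand],
                      coding$end[cand])
      if (any(abs(tss_c - tss_l) <= bidir_window)) return("bidirectional")
    }
    "intergenic"
  }, "")
}

# exact hypergeometric upper tail by direct summation
bf_hyper_upper <- function(k, m, N, n) {
  kk <- k:min(m, n)
  sum(choose(m, kk) * choose(N - m, n - kk)) / choose(N, n)
}
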