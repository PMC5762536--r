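#' Quantile normalization of an expression matrix
#'
#' Classic quantile normalization: every column is ranked, and the value at
#' rank k in each column is replaced by the mean of the k-th order
#' statistics across all columns.  Tied values within a column receive the
#' mean of the reference values their ranks span.  Afterwards all columns
#' share exactly the same empirical distribution, and a second application
#' is a no-op.
#'
#' @param em A linear-scale [expression_matrix()] with at least 2 samples.
#' @return A normalized `ExpressionMatrix` (linear scale).
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale != "linear")
    stop_ln("quantile_normalize expects a linear-scale matrix")
  v <- em$values
  if (ncol(v) < 2) stop_ln("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(v, 2, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    if (all(lo == hi)) {
      out[, j] <- ref[lo]
    } else {
      out[, j] <- vapply(seq_along(x),
                         function(i) mean(ref[lo[i]:hi[i]]), 0)
    }
  }
  expression_matrix(out, em$groups, "linear")
}

#' Fold-change / t-test differential expression screen
#'
#' For every feature the group means are computed on the linear scale, the
#' fold change is the larger mean over the smaller one (so always >= 1, with
#' a `direction`), and a two-sided two-sample t-test (Student,
#' equal-variance, by default) is run on log2-transformed values.  Raw p
#' values are adjusted with Benjamini-Hochberg (`q`), and a feature is
#' flagged significant when `fc >= fc_threshold` and raw `p < p_threshold`.
#'
#' If a group mean is exactly zero the fold change is computed after
#' flooring the means at `eps` (default: half the smallest positive value
#' in the matrix).  Features that are constant across all samples get
#' `p = 1` by convention.
#'
#' @param em A (typically quantile-normalized) linear-scale
#'   [expression_matrix()] with >= 2 samples per group.
#' @param fc_threshold Fold-change cut-off (must exceed 1); default 2.
#' @param p_threshold Raw-p cut-off; default 0.05.
#' @param var_equal Use the pooled-variance Student t-test (default).
#'   `FALSE` switches to Welch.
#' @param eps Optional floor for zero group means.
#' @return A `data.frame` with one row per feature: `feature_id`,
#'   `mean_case`, `mean_control`, `fc`, `direction`, `t`, `p`, `q`,
#'   `significant`.
#' @export
differential_expression <- function(em, fc_threshold = 2,
                                    p_threshold = 0.05,
                                    var_equal = TRUE, eps = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (fc_threshold <= 1) stop_ln("fc_threshold must exceed 1")
  v <- if (em$scale == "linear") em$values else 2^em$values
  cs <- case_ids(em); ct <- control_ids(em)
  mc <- rowMeans(v[, cs, drop = FALSE])
  m0 <- rowMeans(v[, ct, drop = FALSE])
  if (is.null(eps)) {
    pos <- v[v > 0]
    eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  }
  nz <- sum(mc == 0 | m0 == 0)
  if (nz > 0)
    ln_note(nz, " feature(s) had a zero group mean; fold change used floor ",
            signif(eps, 4))
  fc <- pmax(pmax(mc, eps), pmax(m0, eps)) / pmin(pmax(mc, eps),
                                                  pmax(m0, eps))
  direction <- ifelse(mc > m0, "up", "down")
  lv <- log2(pmax(v, eps))
  x <- lv[, cs, drop = FALSE]; y <- lv[, ct, drop = FALSE]
  n1 <- length(cs); n2 <- length(ct)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * pt(-abs(tt), df)
  degen <- se == 0
  if (any(degen)) {
    same <- degen & abs(m1 - m2) < .Machine$double.eps^0.5
    p[same] <- 1; tt[same] <- 0
    p[degen & !same] <- .Machine$double.xmin
    tt[degen & !same] <- sign(m1 - m2)[degen & !same] * Inf
  }
  p <- pmax(p, .Machine$double.xmin)
  q <- p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(v), mean_case = mc, mean_control = m0,
             fc = fc, direction = direction, t = tt, p = p, q = q,
             significant = fc >= fc_threshold & p < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count significant features by direction
#'
#' @param records A differential-expression table from
#'   [differential_expression()].
#' @return A list with `n_up`, `n_down` and `n_total` (their sum) over the
#'   significant records.
#' @export
de_counts <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  n_up <- sum(sig$direction == "up")
  n_down <- sum(sig$direction == "down")
  list(n_up = n_up, n_down = n_down, n_total = n_up + n_down)
}

FC_BIN_BREAKS <- c(2, 5, 10, 50, 100, Inf)
FC_BIN_LABELS <- c("[2,5)", "[5,10)", "[10,50)", "[50,100)", "[100,Inf)")

#' Tabulate significant features into fold-change magnitude bins
#'
#' Bins are closed on the left and open on the right:
#' `[2,5) [5,10) [10,50) [50,100) [100,Inf)`, counted separately for up- and
#' down-regulated features.
#'
#' @param records Differential-expression table; only rows flagged
#'   significant (which implies `fc >= 2` under the default screen) are
#'   binned.
#' @return A `data.frame` with columns `bin`, `n_up`, `n_down`.
#' @export
bin_fold_changes <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  bin <- cut(sig$fc, breaks = FC_BIN_BREAKS, labels = FC_BIN_LABELS,
             right = FALSE)
  tab <- table(bin, factor(sig$direction, c("up", "down")))
  data.frame(bin = FC_BIN_LABELS,
             n_up = as.integer(tab[, "up"]),
             n_down = as.integer(tab[, "down"]),
             stringsAsFactors = FALSE)
}

#' Volcano-plot coordinates for a differential-expression table
#'
#' @param records Differential-expression table.
#' @return A `data.frame` with `feature_id`, `log2_fc` (signed:
#'   `+log2(fc)` for up, `-log2(fc)` for down), `neg_log10_p`, and the
#'   `significant` flag carried over.
#' @export
volcano_table <- function(records) {
  p <- records$p
  if (any(p == 0)) {
    ln_note(sum(p == 0), " zero p value(s) clipped for -log10")
    p <- pmax(p, .Machine$double.xmin)
  }
  data.frame(feature_id = records$feature_id,
             log2_fc = ifelse(records$direction == "up", 1, -1) *
               log2(records$fc),
             neg_log10_p = -log10(p),
             significant = records$significant,
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of samples or features
#'
#' Agglomerative clustering on log2 values with distance
#' `1 - Pearson correlation` and average linkage (both configurable).
#' Pairs involving a constant item, whose correlation is undefined, are
#' assigned distance 1.
#'
#' @param em An [expression_matrix()].
#' @param axis Cluster `"samples"` (columns) or `"features"` (rows).
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An `hclust` object (subclass `LinkageResult`) with attributes
#'   `metric` and `linkage`; compatible with [stats::cutree()].
#' @export
hierarchical_cluster <- function(em, axis = c("samples", "features"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  m <- em_log2(em)
  if (axis == "features") m <- t(m)
  if (ncol(m) < 3) stop_ln("need at least 3 items to cluster")
  const <- apply(m, 2, sd) == 0
  cc <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    ln_note(sum(const), " constant item(s); undefined correlations set to 0",
            " (distance 1)")
  }
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = linkage)
  attr(hc, "metric") <- "1-pearson"
  attr(hc, "linkage") <- linkage
  class(hc) <- c("LinkageResult", "hclust")
  hc
}
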