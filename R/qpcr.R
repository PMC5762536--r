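#' Relative quantification by the 2^-ddCt method
#'
#' Per group, `dCt = mean(Ct_target) - mean(Ct_reference)` (arithmetic
#' mean over replicates); `ddCt = dCt_case - dCt_control`; the relative
#' expression is `2^-ddCt`, reported as a magnitude >= 1 plus a direction
#' (`up` when `2^-ddCt > 1`).  Amplification efficiency is fixed at 2, the
#' assumption of the ddCt model.
#'
#' @param ct_target_case,ct_ref_case Ct replicate values for the target
#'   and the reference gene (e.g. GAPDH) in the case group.
#' @param ct_target_control,ct_ref_control Same for the control group.
#' @return A list: `fold_change` (magnitude >= 1), `direction`
#'   (`up`/`down`; an exact 1.0 reports `up` by convention), `ratio`
#'   (`2^-ddCt` itself) and `ddct`.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control) {
  arms <- list(ct_target_case, ct_ref_case, ct_target_control,
               ct_ref_control)
  if (any(vapply(arms, length, 0L) == 0))
    stop_ln("every replicate list needs at least one Ct value")
  if (!all(vapply(arms, function(a) all(is.finite(a)), TRUE)))
    stop_ln("Ct values must be finite")
  dct_case <- mean(ct_target_case) - mean(ct_ref_case)
  dct_ctrl <- mean(ct_target_control) - mean(ct_ref_control)
  ddct <- dct_case - dct_ctrl
  ratio <- 2^(-ddct)
  list(fold_change = max(ratio, 1 / ratio),
       direction = if (ratio >= 1) "up" else "down",
       ratio = ratio, ddct = ddct)
}

#' Apply the ddCt calculation to a long-format Ct table
#'
#' @param ct A `data.frame` with columns `feature_id`, `sample_id`,
#'   `group` (`case`/`control`), `target_ct`, `ref_ct` — one row per
#'   sample replicate.
#' @return A `data.frame` with one row per feature: `feature_id`,
#'   `fold_change`, `direction`, `ddct`.
#' @export
ddct_table <- function(ct) {
  need <- c("feature_id", "sample_id", "group", "target_ct", "ref_ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop_ln("Ct table missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(split(ct, ct$feature_id), function(d) {
    cs <- d$group == "case"
    res <- ddct_fold_change(d$target_ct[cs], d$ref_ct[cs],
                            d$target_ct[!cs], d$ref_ct[!cs])
    data.frame(feature_id = d$feature_id[1],
               fold_change = res$fold_change,
               direction = res$direction, ddct = res$ddct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction concordance between qPCR and microarray calls
#'
#' @param qpcr_results Output of [ddct_table()] (needs `feature_id` and
#'   `direction`).
#' @param de_records Differential-expression table for the same features.
#' @return A list: `table` (per-feature `feature_id`, `qpcr_direction`,
#'   `array_direction`, `agree`) and `fraction_concordant`.
#' @export
concordance <- function(qpcr_results, de_records) {
  shared <- intersect(qpcr_results$feature_id, de_records$feature_id)
  if (!length(shared)) stop_ln("no shared feature ids")
  qd <- qpcr_results$direction[match(shared, qpcr_results$feature_id)]
  ad <- de_records$direction[match(shared, de_records$feature_id)]
  tab <- data.frame(feature_id = shared, qpcr_direction = qd,
                    array_direction = ad, agree = qd == ad,
                    stringsAsFactors = FALSE)
  list(table = tab, fraction_concordant = mean(tab$agree))
}
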