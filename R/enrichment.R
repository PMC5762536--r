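#' Fisher's-exact over-representation analysis of a gene list
#'
#' For every gene set the 2x2 table (in set / not in set, against in query
#' / not in query, within the background universe) is tested one-sided for
#' over-representation; the p value is the hypergeometric upper tail
#' `P(X >= k)`.  BH-adjusted FDR values are computed across all tested
#' sets.  Sets with no member inside the background are skipped with a
#' note.
#'
#' @param query Gene ids of interest; must be a subset of `background`.
#' @param sets Gene-set collection from [read_gene_sets()] (a named list of
#'   character vectors).
#' @param background Universe of gene ids (e.g. every coding gene on the
#'   platform).
#' @param p_max Screening cut-off on the raw p value (default 0.05).
#' @return A `data.frame` sorted by `p`: `set_id`, `name`, `k` (overlap),
#'   `m` (set size in background), `n` (query size), `N` (background
#'   size), `p`, `fdr`, `significant`.
#' @export
fisher_enrichment <- function(query, sets, background, p_max = 0.05) {
  query <- unique(query); background <- unique(background)
  if (!length(background)) stop_ln("empty background")
  if (!length(query)) stop_ln("empty query")
  out <- setdiff(query, background)
  if (length(out))
    stop_ln("query gene(s) outside the background: ",
            paste(out, collapse = ", "))
  descs <- attr(sets, "description") %||% setNames(names(sets), names(sets))
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    m <- length(members)
    if (m == 0) {
      ln_note("set '", id, "' has no members in the background; skipped")
      return(NULL)
    }
    k <- length(intersect(members, query))
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set_id = id, name = unname(descs[id]), k = k, m = m,
               n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(set_id = character(), name = character(),
                      k = integer(), m = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  rows$fdr <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$p < p_max
  rows <- rows[order(rows$p, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Coding genes correlated with the transcripts of named lncRNA genes
#'
#' Collects the unique coding genes that share a (network or cis) edge
#' with any transcript of the given lncRNA genes — the query list for a
#' downstream enrichment analysis.
#'
#' @param edges Edge or cis-pair table with `lncrna_id` and `mrna_id`
#'   columns.
#' @param lnc_gene_ids lncRNA gene ids of interest.
#' @param annotation Annotation mapping transcript ids to gene ids.
#' @return Sorted character vector of coding gene ids (deduplicated);
#'   empty when the genes have no edges.
#' @export
genes_correlated_with <- function(edges, lnc_gene_ids, annotation) {
  tx2gene <- setNames(annotation$gene_id, annotation$feature_id)
  lg <- tx2gene[edges$lncrna_id]
  lg[is.na(lg)] <- edges$lncrna_id[is.na(lg)]
  hits <- edges$mrna_id[lg %in% lnc_gene_ids]
  mg <- tx2gene[hits]
  mg[is.na(mg)] <- hits[is.na(mg)]
  sort(unique(unname(mg)))
}
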