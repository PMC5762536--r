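PIPELINE_DEFAULTS <- list(fc = 2.0, p = 0.05, r_min = 0.90, edge_q = 0.01,
                          cis_window = 300000, cis_p = 0.05, top_n = 200,
                          bidir_window = 1000, mirna_fc = 2.0, seed = 1)

#' Run the full integrative analysis pipeline
#'
#' Chains every stage on files named in a config (YAML path or list):
#' quantile normalization and differential screening of the three
#' matrices, positional classification of the significant lncRNAs,
#' lncRNA-mRNA co-expression network construction, cis-regulation pairing
#' of the most dysregulated lncRNAs, the locus miRNA silencing summary,
#' and gene-set enrichment of the coding genes correlated with lncRNAs in
#' the network.  All outputs are plain TSV/SIF, deterministically sorted;
#' a run log echoes every threshold, so re-running the same config
#' reproduces the directory byte for byte.
#'
#' Required config keys: `coding_matrix`, `lncrna_matrix`, `mirna_matrix`,
#' `groups`, `annotation`, `gene_sets`, `locus` (as `"chrom:start-end"`,
#' 1-based inclusive), `out_dir`.  Optional keys (defaults in
#' parentheses): `exons` (none), `fc` (2.0), `p` (0.05), `r_min` (0.90),
#' `edge_q` (0.01), `cis_window` (300000), `cis_p` (0.05), `top_n` (200),
#' `bidir_window` (1000), `mirna_fc` (2.0), `seed` (1).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The output directory path, invisibly; the directory contains
#'   `de_coding.tsv`, `de_lncrna.tsv`, `de_mirna.tsv`,
#'   `subgroup_counts.tsv`, `network_edges.tsv` + `network.sif`,
#'   `cis_pairs.tsv`, `locus_summary.tsv` (+ per-miRNA statuses),
#'   `enrichment.tsv` and `run_log.txt`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("coding_matrix", "lncrna_matrix", "mirna_matrix",
                "groups", "annotation", "gene_sets", "locus", "out_dir")
  for (key in required)
    if (is.null(config[[key]]))
      stop_ln("missing config key: '", key, "'")
  for (key in names(PIPELINE_DEFAULTS))
    config[[key]] <- config[[key]] %||% PIPELINE_DEFAULTS[[key]]
  if (config$fc <= 1) stop_ln("config key 'fc' must exceed 1")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  log_lines <- c("locusnet pipeline run",
                 sprintf("threshold %s = %s",
                         c("fc", "p", "r_min", "edge_q", "cis_window",
                           "cis_p", "top_n", "bidir_window", "mirna_fc",
                           "seed"),
                         vapply(c("fc", "p", "r_min", "edge_q",
                                  "cis_window", "cis_p", "top_n",
                                  "bidir_window", "mirna_fc", "seed"),
                                function(k) format(config[[k]]), "")))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  wtab <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)

  ann <- read_annotation(config$annotation)
  sets <- read_gene_sets(config$gene_sets)
  exons <- NULL
  if (!is.null(config$exons)) {
    ex <- read_annotation(config$exons)
    exons <- data.frame(gene_id = ex$gene_id, chrom = ex$chrom,
                        start = ex$start, end = ex$end,
                        strand = ex$strand, stringsAsFactors = FALSE)
  }

  de <- list()
  for (cls in c("coding", "lncrna", "mirna")) {
    em <- read_expression_matrix(config[[paste0(cls, "_matrix")]],
                                 config$groups, scale = "linear")
    note(sprintf("%s: %d features x %d samples (%d rows dropped)", cls,
                 nrow(em$values), ncol(em$values),
                 attr(em, "n_dropped") %||% 0L))
    em <- quantile_normalize(em)
    de[[cls]] <- differential_expression(em, fc_threshold = config$fc,
                                         p_threshold = config$p)
    wtab(de[[cls]], sprintf("de_%s.tsv", cls))
    note(sprintf("%s: %d significant (up %d / down %d)", cls,
                 de_counts(de[[cls]])$n_total, de_counts(de[[cls]])$n_up,
                 de_counts(de[[cls]])$n_down))
    assign(paste0("em_", cls), em)
  }

  sig_ids <- function(cls)
    de[[cls]]$feature_id[de[[cls]]$significant]

  lnc_ann <- ann[ann$biotype == "lncRNA" &
                   ann$feature_id %in% sig_ids("lncrna"), , drop = FALSE]
  cod_ann <- ann[ann$biotype == "coding", , drop = FALSE]
  classes <- classify_lncrnas(lnc_ann, cod_ann, exons = exons,
                              bidir_window = config$bidir_window)
  wtab(classes, "lncrna_classes.tsv")
  wtab(subgroup_counts(de$lncrna, classes), "subgroup_counts.tsv")

  edges <- build_edges(get("em_lncrna"), get("em_coding"),
                       sig_ids("lncrna"), sig_ids("coding"),
                       r_min = config$r_min, q_max = config$edge_q)
  wtab(edges, "network_edges.tsv")
  write_network(edges, file.path(out, "network.sif"), "sif")
  note(sprintf("network: %d edges", nrow(edges)))

  top <- select_top_lncrnas(de$lncrna, n = config$top_n)
  cis <- find_cis_pairs(top, ann, get("em_lncrna"), get("em_coding"),
                        intersect(sig_ids("coding"), ann$feature_id),
                        window = config$cis_window, p_max = config$cis_p)
  wtab(cis, "cis_pairs.tsv")
  note(sprintf("cis: %d of %d selected lncRNAs localized",
               count_localized(top, cis), length(top)))

  locus <- parse_locus(config$locus, one_based = TRUE)
  statuses <- classify_locus_mirnas(de$mirna, locus, ann,
                                    fc_threshold = config$mirna_fc)
  wtab(data.frame(mirna_id = names(statuses),
                  status = unname(statuses)), "locus_mirna_status.tsv")
  ls <- locus_summary(statuses)
  wtab(ls, "locus_summary.tsv")
  note(sprintf("locus: %d miRNAs, %.2f%% down / %.2f%% up", ls$n_total,
               ls$pct_down, ls$pct_up))

  lnc_genes <- unique(ann$gene_id[match(edges$lncrna_id,
                                        ann$feature_id)])
  lnc_genes <- lnc_genes[!is.na(lnc_genes)]
  background <- unique(cod_ann$gene_id)
  query <- genes_correlated_with(edges, lnc_genes, ann)
  enr <- if (length(query))
    fisher_enrichment(query, sets, background, p_max = config$p)
  else data.frame(set_id = character(), name = character(),
                  k = integer(), m = integer(), n = integer(),
                  N = integer(), p = numeric(), fdr = numeric(),
                  significant = logical())
  wtab(enr, "enrichment.tsv")
  note(sprintf("enrichment: %d sets tested, %d significant", nrow(enr),
               sum(enr$significant)))

  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(out)
}
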