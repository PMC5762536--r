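BIOTYPES <- c("coding", "lncRNA", "miRNA")

validate_annotation <- function(ann, file = "annotation") {
  need <- c("feature_id", "gene_id", "chrom", "start", "end", "strand",
            "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_ln(file, ": missing annotation column(s): ",
            paste(miss, collapse = ", "))
  if (anyDuplicated(ann$feature_id))
    stop_ln(file, ": duplicate feature ids: ",
            paste(unique(ann$feature_id[duplicated(ann$feature_id)]),
                  collapse = ", "))
  bad <- which(!(ann$start < ann$end))
  if (length(bad))
    stop_ln(file, ": start >= end for ",
            paste(ann$feature_id[bad], collapse = ", "))
  if (any(ann$start < 0)) stop_ln(file, ": negative coordinates")
  if (!all(ann$biotype %in% BIOTYPES))
    stop_ln(file, ": unknown biotype token(s): ",
            paste(setdiff(unique(ann$biotype), BIOTYPES), collapse = ", "))
  stranded <- ann$biotype %in% c("coding", "lncRNA")
  if (!all(ann$strand[stranded] %in% c("+", "-")))
    stop_ln(file, ": coding and lncRNA records must have strand + or -")
  if (!all(ann$strand %in% c("+", "-", ".")))
    stop_ln(file, ": strand must be one of + - .")
  invisible(ann)
}

#' Read genomic feature annotation from BED6 or GFF3
#'
#' Coordinates are stored 0-based half-open internally.  BED input is taken
#' as-is; GFF3 (1-based, closed) is converted at the boundary.  In BED the
#' name column must encode `feature_id|gene_id|biotype`; in GFF3 the
#' attributes column must carry `ID=`, `gene_id=` and `biotype=` tags.
#' Recognised biotypes are `coding`, `lncRNA` and `miRNA`.
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file (format detected from
#'   the extension; anything not ending in gff/gff3 is treated as BED).
#' @return A `data.frame` with columns `feature_id`, `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `biotype`.
#' @export
read_annotation <- function(path) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop_ln(path, ": no annotation records")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (is_gff) {
    ann <- do.call(rbind, lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 9)
        stop_ln(path, ": line ", i, ": GFF3 needs 9 columns")
      attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
      kv <- strsplit(trimws(attrs), "=", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1)
      vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
      get <- function(k) {
        j <- match(k, keys)
        if (is.na(j)) stop_ln(path, ": line ", i, ": missing attribute ", k)
        vals[j]
      }
      data.frame(feature_id = get("ID"), gene_id = get("gene_id"),
                 chrom = f[1], start = as.numeric(f[4]) - 1,
                 end = as.numeric(f[5]), strand = f[7],
                 biotype = get("biotype"), stringsAsFactors = FALSE)
    }))
  } else {
    ann <- do.call(rbind, lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 6)
        stop_ln(path, ": line ", i, ": BED6 needs 6 columns")
      name <- strsplit(f[4], "|", fixed = TRUE)[[1]]
      if (length(name) != 3)
        stop_ln(path, ": line ", i,
                ": BED name must be 'feature_id|gene_id|biotype'")
      data.frame(feature_id = name[1], gene_id = name[2], chrom = f[1],
                 start = as.numeric(f[2]), end = as.numeric(f[3]),
                 strand = f[6], biotype = name[3], stringsAsFactors = FALSE)
    }))
  }
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  validate_annotation(ann, file = path)
  ann
}

#' Write annotation records as BED6
#'
#' The name column packs `feature_id|gene_id|biotype` so that
#' [read_annotation()] round-trips the records exactly.
#'
#' @param ann Annotation `data.frame` (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  validate_annotation(ann)
  bed <- data.frame(ann$chrom, ann$start, ann$end,
                    paste(ann$feature_id, ann$gene_id, ann$biotype,
                          sep = "|"),
                    0L, ann$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member gene ids.  Duplicate member ids within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set), with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop_ln(path, ": empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  descs <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop_ln(path, ": line ", i, ": GMT line needs >= 3 fields")
    id <- f[1]
    if (id %in% names(sets))
      stop_ln(path, ": line ", i, ": duplicate set id '", id, "'")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop_ln(path, ": line ", i, ": set '", id, "' has no members")
    sets[[id]] <- members
    descs[id] <- f[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Export a correlation edge list for Cytoscape
#'
#' `sif` writes one line per edge, `lncrna_id <pos|neg> mrna_id`
#' (tab-separated); `tsv` writes a header plus `lncrna_id`, `sign`,
#' `mrna_id`, `r`, `p`, `q` columns.  Output is sorted by lncRNA id, then
#' mRNA id, so files are byte-identical across runs regardless of input
#' order.
#'
#' @param edges Edge `data.frame` from [build_edges()] (needs columns
#'   `lncrna_id`, `mrna_id`, `r`, `p`, `q`, `sign`).
#' @param path Output path.
#' @param format `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  edges <- edges[order(edges$lncrna_id, edges$mrna_id), , drop = FALSE]
  sig <- ifelse(edges$sign == "positive", "pos", "neg")
  if (format == "sif") {
    writeLines(if (nrow(edges))
      paste(edges$lncrna_id, sig, edges$mrna_id, sep = "\t")
      else character(), path)
  } else {
    out <- data.frame(lncrna_id = edges$lncrna_id, sign = sig,
                      mrna_id = edges$mrna_id, r = edges$r, p = edges$p,
                      q = edges$q, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# annotation -> GRanges (internal 0-based half-open to 1-based closed)
ann_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*"))
}
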