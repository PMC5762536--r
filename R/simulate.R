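#' Specification of the planted imprinted locus
#'
#' The default mirrors the topology of a silenced DLK1-MEG3-style imprinted
#' domain: one protein-coding gene, eight partner lncRNA transcripts from
#' two lncRNA genes (5 + 3), and 49 clustered miRNAs of which 30 are
#' down-regulated and 3 up-regulated at two-fold or more.  The coding gene
#' and all partner lncRNA transcripts share one (large) fold change and are
#' co-down-regulated, so their mutual correlation is driven by the shared
#' group shift.
#'
#' @param chrom Chromosome name of the locus.
#' @param start Locus start (0-based).
#' @param span Locus width in bp; all locus features are placed inside
#'   `[start, start + span)` and the partner lncRNAs within 300 kb of the
#'   coding gene.
#' @param coding_fc Shared linear fold change of the coding gene and its
#'   partner lncRNA transcripts (down-regulated).
#' @param n_lnc_a,n_lnc_b Transcript counts of the two surrogate lncRNA
#'   genes (defaults 5 and 3).
#' @param n_mirna Number of clustered miRNAs (default 49).
#' @param fraction_down,fraction_up Fractions of locus miRNAs planted down
#'   / up (rounded to counts; defaults 30/49 and 3/49).
#' @param mirna_fc Linear fold change of the planted locus miRNAs.
#' @return A list used as the `locus` field of [simulation_config()].
#' @export
locus_spec <- function(chrom = "chr14", start = 100e6, span = 1e6,
                       coding_fc = 2771.79, n_lnc_a = 5, n_lnc_b = 3,
                       n_mirna = 49, fraction_down = 30 / 49,
                       fraction_up = 3 / 49, mirna_fc = 4) {
  stopifnot(coding_fc > 1, mirna_fc > 1, n_mirna >= 1,
            fraction_down >= 0, fraction_up >= 0,
            fraction_down + fraction_up <= 1)
  list(chrom = chrom, start = start, span = span, coding_fc = coding_fc,
       n_lnc_a = n_lnc_a, n_lnc_b = n_lnc_b, n_mirna = n_mirna,
       fraction_down = fraction_down, fraction_up = fraction_up,
       mirna_fc = mirna_fc)
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults reproduce the study conditions the generator emulates: two
#' groups of 3 samples, log-normal intensity noise (Gaussian with sd 0.25
#' on the log2 scale), planted differential features at fold changes
#' {2, 5, 10, 100}, and a planted silenced imprinted locus
#' ([locus_spec()]).  Non-locus lncRNAs are placed genome-wide with a
#' configurable fraction within 300 kb of a coding gene (true cis
#' candidates) and a few deliberately planted in each positional class for
#' the classifier; the rest lie farther than 300 kb from any coding gene.
#'
#' @param n_case,n_control Samples per group (default 3 / 3).
#' @param n_coding,n_lncrna,n_mirna Feature counts per class (the locus
#'   members are included in these totals).
#' @param frac_de_coding,frac_de_lncrna,frac_de_mirna Fraction of planted
#'   differential features per class, outside the locus.  Non-locus lncRNA
#'   differential expression defaults to 0 so that the locus transcripts
#'   are the only strongly co-shifted lncRNAs and the planted network /
#'   cis topology is exactly recoverable (see the package vignette).
#' @param fc_grid Linear fold changes cycled over the planted non-locus
#'   features (all > 1).
#' @param noise_sd_log2 Per-cell Gaussian noise sd on the log2 scale.
#' @param baseline_log2_range Dynamic range of the per-feature baseline
#'   log2 intensity (drawn uniformly).  Planted features draw their
#'   baseline so that both group means stay inside the range -- a
#'   silenced feature bottoms out at the detection floor instead of
#'   falling arbitrarily far below every null intensity, mirroring how a
#'   scanner floors a lost transcript.  The range must therefore be wider
#'   than the largest planted log2 fold change.
#' @param frac_cis Fraction of ordinary (non-planted-class) non-locus
#'   lncRNAs placed within 300 kb of a coding gene.
#' @param n_subgroup_plant How many lncRNAs to plant per positional class
#'   (sense, antisense, bidirectional, intronic).
#' @param locus A [locus_spec()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @return A validated config list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_case = 3, n_control = 3,
                              n_coding = 3000, n_lncrna = 800,
                              n_mirna = 1000,
                              frac_de_coding = 0.05,
                              frac_de_lncrna = 0,
                              frac_de_mirna = 0.05,
                              fc_grid = c(2, 5, 10, 100),
                              noise_sd_log2 = 0.25,
                              baseline_log2_range = c(4, 16),
                              frac_cis = 0.3,
                              n_subgroup_plant = 2L,
                              locus = locus_spec(),
                              seed = 7) {
  cfg <- list(n_case = n_case, n_control = n_control, n_coding = n_coding,
              n_lncrna = n_lncrna, n_mirna = n_mirna,
              frac_de_coding = frac_de_coding,
              frac_de_lncrna = frac_de_lncrna,
              frac_de_mirna = frac_de_mirna, fc_grid = fc_grid,
              noise_sd_log2 = noise_sd_log2,
              baseline_log2_range = baseline_log2_range,
              frac_cis = frac_cis,
              n_subgroup_plant = as.integer(n_subgroup_plant),
              locus = locus, seed = seed)
  for (f in c("frac_de_coding", "frac_de_lncrna", "frac_de_mirna",
              "frac_cis"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_ln(f, " must lie in [0, 1]")
  if (any(fc_grid <= 1)) stop_ln("all fc_grid values must exceed 1")
  if (noise_sd_log2 < 0) stop_ln("noise_sd_log2 must be >= 0")
  if (n_case < 2 || n_control < 2) stop_ln("need >= 2 samples per group")
  n_locus_lnc <- locus$n_lnc_a + locus$n_lnc_b
  if (n_lncrna < n_locus_lnc)
    stop_ln("n_lncrna must cover the ", n_locus_lnc,
            " locus lncRNA transcripts")
  if (n_mirna < locus$n_mirna)
    stop_ln("n_mirna must cover the ", locus$n_mirna, " locus miRNAs")
  if (n_coding < 4 * cfg$n_subgroup_plant + 2)
    stop_ln("n_coding too small for the planted subgroup classes")
  # locus geometry: coding gene at +150k, lncRNA genes at +250k/+290k,
  # miRNA cluster from +300k in 8 kb steps
  mir_span <- 300000 + locus$n_mirna * 8000
  if (locus$span < max(mir_span, 320000))
    stop_ln("locus span too small to place the requested features")
  width <- diff(baseline_log2_range)
  max_shift <- max(log2(c(fc_grid, locus$coding_fc, locus$mirna_fc)))
  if (max_shift >= width)
    stop_ln("largest planted log2 fold change (", round(max_shift, 2),
            ") must fit inside the baseline dynamic range (width ",
            width, ")")
  structure(cfg, class = "SimulationConfig")
}

# deterministic placement of the locus features
place_locus <- function(locus) {
  s <- locus$start
  coding <- data.frame(feature_id = "DLK1S", gene_id = "DLK1S",
                       chrom = locus$chrom, start = s + 150000,
                       end = s + 160000, strand = "+",
                       biotype = "coding", stringsAsFactors = FALSE)
  lnc_a <- if (locus$n_lnc_a) data.frame(
    feature_id = sprintf("MEG3S_T%d", seq_len(locus$n_lnc_a)),
    gene_id = "MEG3S", chrom = locus$chrom,
    start = s + 250000 + (seq_len(locus$n_lnc_a) - 1) * 500,
    end = s + 250000 + (seq_len(locus$n_lnc_a) - 1) * 500 + 25000,
    strand = "+", biotype = "lncRNA", stringsAsFactors = FALSE)
  lnc_b <- if (locus$n_lnc_b) data.frame(
    feature_id = sprintf("MEG8S_T%d", seq_len(locus$n_lnc_b)),
    gene_id = "MEG8S", chrom = locus$chrom,
    start = s + 290000 + (seq_len(locus$n_lnc_b) - 1) * 400,
    end = s + 290000 + (seq_len(locus$n_lnc_b) - 1) * 400 + 18000,
    strand = "+", biotype = "lncRNA", stringsAsFactors = FALSE)
  mir <- data.frame(
    feature_id = sprintf("MIR14S_%02d", seq_len(locus$n_mirna)),
    gene_id = sprintf("MIR14S_%02d", seq_len(locus$n_mirna)),
    chrom = locus$chrom,
    start = s + 300000 + (seq_len(locus$n_mirna) - 1) * 8000,
    end = s + 300000 + (seq_len(locus$n_mirna) - 1) * 8000 + 80,
    strand = "+", biotype = "miRNA", stringsAsFactors = FALSE)
  list(coding = coding, lnc = rbind(lnc_a, lnc_b), mir = mir)
}

sim_matrix <- function(ids, shift, cfg) {
  n1 <- cfg$n_case; n2 <- cfg$n_control
  samples <- c(sprintf("case_%d", seq_len(n1)),
               sprintf("control_%d", seq_len(n2)))
  # both group means must sit inside the dynamic range: a down-planted
  # feature needs headroom below its baseline, an up-planted one above
  lo <- cfg$baseline_log2_range[1] + pmax(0, -shift)
  hi <- cfg$baseline_log2_range[2] - pmax(0, shift)
  base <- runif(length(ids), lo, hi)
  lv <- matrix(base, length(ids), n1 + n2,
               dimnames = list(ids, samples))
  lv[, seq_len(n1)] <- lv[, seq_len(n1)] + shift
  if (cfg$noise_sd_log2 > 0)
    lv <- lv + matrix(rnorm(length(lv), 0, cfg$noise_sd_log2),
                      nrow(lv), ncol(lv))
  groups <- setNames(rep(c("case", "control"), c(n1, n2)), samples)
  expression_matrix(2^lv, groups, "linear")
}

#' Generate a synthetic lncRNA / mRNA / miRNA dataset with ground truth
#'
#' Produces three linear-scale expression matrices (coding, lncRNA,
#' miRNA), a genomic annotation (with an exon model for the coding genes),
#' a small random gene-set collection, and ground-truth tables.  Per
#' feature a baseline log2 intensity is drawn uniformly; planted
#' differential features shift their case samples by `+/- log2(fc)`;
#' i.i.d. Gaussian noise (sd `noise_sd_log2`) is added per cell.
#'
#' @param config A [simulation_config()].
#' @return A list: `coding`, `lncrna`, `mirna` (expression matrices),
#'   `annotation`, `exons`, `gene_sets`, `truth` (a list with
#'   `de_features`, `cis_pairs`, `cis_candidates`, `locus_mirna_status`,
#'   `lncrna_class`, `locus`) and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  locus <- config$locus
  lp <- place_locus(locus)
  n_chr <- 13L
  chroms <- sprintf("chr%d", seq_len(n_chr))

  ## ---- non-locus coding genes (with a 2-exon model) ----
  ncg <- config$n_coding - 1L
  chr_i <- rep(seq_len(n_chr), length.out = ncg)
  slot <- stats::ave(seq_len(ncg), chr_i, FUN = seq_along)
  gstart <- slot * 1e6
  coding <- data.frame(
    feature_id = sprintf("GENE%04d", seq_len(ncg)),
    gene_id = sprintf("GENE%04d", seq_len(ncg)),
    chrom = chroms[chr_i], start = gstart, end = gstart + 20000,
    strand = rep(c("+", "-"), length.out = ncg),
    biotype = "coding", stringsAsFactors = FALSE)
  coding <- rbind(coding, lp$coding)
  exons <- rbind(
    data.frame(gene_id = rep(coding$gene_id[seq_len(ncg)], each = 2),
               chrom = rep(coding$chrom[seq_len(ncg)], each = 2),
               start = as.vector(rbind(gstart, gstart + 15000)),
               end = as.vector(rbind(gstart + 5000, gstart + 20000)),
               strand = rep(coding$strand[seq_len(ncg)], each = 2),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "DLK1S", chrom = locus$chrom,
               start = c(lp$coding$start, lp$coding$start + 8000),
               end = c(lp$coding$start + 2000, lp$coding$end),
               strand = "+", stringsAsFactors = FALSE))

  ## ---- non-locus lncRNAs: planted classes, cis candidates, deserts ----
  n_locus_lnc <- locus$n_lnc_a + locus$n_lnc_b
  nll <- config$n_lncrna - n_locus_lnc
  k <- config$n_subgroup_plant
  planted_cls <- rep(c("sense", "antisense", "intronic", "bidirectional"),
                     each = k)
  n_planted <- length(planted_cls)
  if (n_planted > nll) stop_ln("n_lncrna too small for planted classes")
  n_rest <- nll - n_planted
  n_cis <- round(config$frac_cis * n_rest)
  host <- seq_len(n_planted + n_cis)  # one distinct host gene each
  if (length(host) > ncg) stop_ln("n_coding too small for lncRNA placement")

  mk_lnc <- function(i, cls) {
    g <- coding[host[i], ]
    if (cls == "sense") {            # overlaps exon 1, same strand
      st <- g$start + 1000; en <- g$start + 6000; strand <- g$strand
    } else if (cls == "antisense") { # overlaps gene, opposite strand
      st <- g$start + 2000; en <- g$start + 9000
      strand <- if (g$strand == "+") "-" else "+"
    } else if (cls == "intronic") {  # inside the intron, same strand
      st <- g$start + 6000; en <- g$start + 14000; strand <- g$strand
    } else if (cls == "bidirectional") { # head-to-head within 1 kb
      if (g$strand == "+") {
        st <- g$start - 5500; en <- g$start - 500; strand <- "-"
      } else {
        st <- g$end + 500; en <- g$end + 5500; strand <- "+"
      }
    } else {                         # cis candidate: 50 kb downstream
      st <- g$end + 50000; en <- g$end + 52000; strand <- g$strand
    }
    c(chrom = g$chrom, start = st, end = en, strand = strand,
      gene = g$gene_id)
  }
  cls_all <- c(planted_cls, rep("cis", n_cis))
  near <- lapply(seq_along(cls_all), function(i) mk_lnc(i, cls_all[i]))
  # far intergenic lncRNAs: > 300 kb beyond the last gene of their chrom
  n_far <- n_rest - n_cis
  far_chr <- rep(seq_len(n_chr), length.out = n_far)
  far_slot <- if (n_far) stats::ave(seq_len(n_far), far_chr,
                                    FUN = seq_along) else integer()
  chrom_max <- vapply(seq_len(n_chr), function(c)
    max(0, coding$end[coding$chrom == chroms[c]]), 0)
  lnc_rows <- data.frame(
    feature_id = sprintf("LNC%04d", seq_len(nll)),
    gene_id = sprintf("LNCG%04d", seq_len(nll)),
    chrom = c(vapply(near, `[[`, "", "chrom"), chroms[far_chr]),
    start = c(as.numeric(vapply(near, `[[`, "", "start")),
              chrom_max[far_chr] + 400000 + (far_slot - 1) * 700000),
    end = c(as.numeric(vapply(near, `[[`, "", "end")),
            chrom_max[far_chr] + 400000 + (far_slot - 1) * 700000 + 2000),
    strand = c(vapply(near, `[[`, "", "strand"),
               rep(c("+", "-"), length.out = n_far)),
    biotype = "lncRNA", stringsAsFactors = FALSE)
  true_class <- c(cls_all, rep("intergenic", n_far))
  true_class[true_class == "cis"] <- "intergenic"
  lnc <- rbind(lnc_rows, lp$lnc)

  ## ---- non-locus miRNAs in inter-gene deserts ----
  nlm <- config$n_mirna - locus$n_mirna
  mchr <- rep(seq_len(n_chr), length.out = nlm)
  mslot <- if (nlm) stats::ave(seq_len(nlm), mchr, FUN = seq_along)
           else integer()
  mir <- rbind(
    if (nlm) data.frame(
      feature_id = sprintf("MIR%03d", seq_len(nlm)),
      gene_id = sprintf("MIR%03d", seq_len(nlm)),
      chrom = chroms[mchr], start = mslot * 1e6 + 500000,
      end = mslot * 1e6 + 500080, strand = "+",
      biotype = "miRNA", stringsAsFactors = FALSE),
    lp$mir)

  annotation <- rbind(coding, lnc, mir)
  annotation$start <- as.integer(annotation$start)
  annotation$end <- as.integer(annotation$end)
  validate_annotation(annotation)

  ## ---- planted differential expression ----
  plant <- function(ids, frac) {
    n_de <- round(frac * length(ids))
    de_ids <- if (n_de) sort(sample(ids, n_de)) else character()
    fc <- rep_len(config$fc_grid, length(de_ids))
    # balance the directions within every fold-change level so the
    # case/control intensity distributions stay comparable (a quantile
    # normalization upstream assumes mostly matched distributions)
    i <- seq_along(de_ids) - 1L
    dir <- ifelse((i + i %/% length(config$fc_grid)) %% 2 == 0,
                  "up", "down")
    data.frame(feature_id = de_ids, true_fc = fc, direction = dir,
               stringsAsFactors = FALSE)
  }
  de_cod <- plant(coding$feature_id[seq_len(ncg)], config$frac_de_coding)
  de_lnc <- plant(lnc_rows$feature_id, config$frac_de_lncrna)
  de_mir <- plant(if (nlm) mir$feature_id[seq_len(nlm)] else character(),
                  config$frac_de_mirna)

  n_down <- round(locus$fraction_down * locus$n_mirna)
  n_up <- round(locus$fraction_up * locus$n_mirna)
  mir_status <- rep("unchanged", locus$n_mirna)
  if (n_down) mir_status[seq_len(n_down)] <- "down"
  if (n_up) mir_status[n_down + seq_len(n_up)] <- "up"
  changed <- mir_status != "unchanged"
  locus_mir_de <- data.frame(
    feature_id = lp$mir$feature_id[changed],
    true_fc = rep(locus$mirna_fc, sum(changed)),
    direction = mir_status[changed],
    stringsAsFactors = FALSE)
  locus_lnc_ids <- if (NROW(lp$lnc)) lp$lnc$feature_id else character()
  locus_de <- data.frame(
    feature_id = c("DLK1S", locus_lnc_ids),
    true_fc = locus$coding_fc, direction = "down",
    stringsAsFactors = FALSE)

  add_class <- function(df, cls) {
    df$class <- rep_len(cls, nrow(df))
    df
  }
  de_features <- rbind(
    add_class(de_cod, "coding"),
    add_class(de_lnc, "lncRNA"),
    add_class(de_mir, "miRNA"),
    add_class(locus_de, c("coding", rep("lncRNA", NROW(lp$lnc)))),
    add_class(locus_mir_de, "miRNA"))

  shift_for <- function(ids) {
    s <- setNames(rep(0, length(ids)), ids)
    hit <- intersect(ids, de_features$feature_id)
    rec <- de_features[match(hit, de_features$feature_id), ]
    s[hit] <- ifelse(rec$direction == "up", 1, -1) * log2(rec$true_fc)
    s
  }

  em_cod <- sim_matrix(coding$feature_id,
                       shift_for(coding$feature_id), config)
  em_lnc <- sim_matrix(lnc$feature_id, shift_for(lnc$feature_id), config)
  em_mir <- sim_matrix(mir$feature_id, shift_for(mir$feature_id), config)

  ## ---- gene sets (plumbing for the enrichment stage) ----
  gene_sets <- lapply(seq_len(15), function(i)
    sort(sample(coding$gene_id, 30)))
  names(gene_sets) <- sprintf("SET%02d", seq_len(15))
  attr(gene_sets, "description") <-
    setNames(sprintf("synthetic pathway %02d", seq_len(15)),
             names(gene_sets))

  truth <- list(
    de_features = de_features,
    cis_pairs = data.frame(lncrna_id = locus_lnc_ids,
                           mrna_id = rep("DLK1S", length(locus_lnc_ids)),
                           stringsAsFactors = FALSE),
    cis_candidates = data.frame(
      lncrna_id = lnc_rows$feature_id[which(cls_all == "cis")],
      mrna_id = coding$gene_id[host[which(cls_all == "cis")]],
      stringsAsFactors = FALSE),
    locus_mirna_status = setNames(mir_status, lp$mir$feature_id),
    lncrna_class = data.frame(
      lncrna_id = lnc_rows$feature_id, class = true_class,
      stringsAsFactors = FALSE),
    locus = list(chrom = locus$chrom, start = locus$start,
                 end = locus$start + locus$span))
  list(coding = em_cod, lncrna = em_lnc, mirna = em_mir,
       annotation = annotation, exons = exons, gene_sets = gene_sets,
       truth = truth, config = config)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits the three matrices plus group map (TSV), the annotation and exon
#' model (BED6), the gene sets (GMT) and the truth tables (TSV) — the
#' exact inputs [run_pipeline()] consumes.
#'
#' @param ds Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_expression_matrix(ds$coding, fp("coding.tsv"), fp("groups.tsv"))
  write_expression_matrix(ds$lncrna, fp("lncrna.tsv"))
  write_expression_matrix(ds$mirna, fp("mirna.tsv"))
  write_annotation_bed(ds$annotation, fp("annotation.bed"))
  ex <- ds$exons
  write_annotation_bed(
    data.frame(feature_id = sprintf("%s_ex%d", ex$gene_id,
                                    stats::ave(seq_len(nrow(ex)),
                                               ex$gene_id, FUN = seq_along)),
               gene_id = ex$gene_id, chrom = ex$chrom, start = ex$start,
               end = ex$end, strand = ex$strand, biotype = "coding",
               stringsAsFactors = FALSE),
    fp("exons.bed"))
  gmt <- vapply(names(ds$gene_sets), function(id)
    paste(c(id, attr(ds$gene_sets, "description")[id],
            ds$gene_sets[[id]]), collapse = "\t"), "")
  writeLines(gmt, fp("gene_sets.gmt"))
  write.table(ds$truth$de_features, fp("truth_de_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$truth$cis_pairs, fp("truth_cis_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(mirna_id = names(ds$truth$locus_mirna_status),
                         status = unname(ds$truth$locus_mirna_status)),
              fp("truth_locus_mirnas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Construct a noiseless (or noisy) qPCR Ct fixture for a planted feature
#'
#' Builds a Ct table whose 2^-ddCt evaluates to the feature's true fold
#' change in its planted direction: the reference gene has constant Ct,
#' and the target Ct in case samples is offset by `-/+ log2(true fc)`
#' (Ct falls as abundance rises).  Optional Gaussian noise on every Ct
#' value emulates replicate scatter.
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param feature_id A feature present in `truth$de_features` (or any
#'   feature with `fc = 1` semantics via `allow_null = TRUE`).
#' @param n_replicates Replicates per group (default 3).
#' @param noise_sd Gaussian sd added to every Ct value (default 0).
#' @param allow_null Permit features without a planted effect (true fold
#'   change 1).
#' @return A Ct `data.frame` suitable for [ddct_table()].
#' @export
qpcr_fixture <- function(truth, feature_id, n_replicates = 3,
                         noise_sd = 0, allow_null = FALSE) {
  rec <- truth$de_features[truth$de_features$feature_id == feature_id, ]
  if (!nrow(rec)) {
    if (!allow_null)
      stop_ln("feature '", feature_id, "' has no planted effect")
    rec <- data.frame(true_fc = 1, direction = "up")
  }
  shift <- ifelse(rec$direction[1] == "up", 1, -1) * log2(rec$true_fc[1])
  group <- rep(c("case", "control"), each = n_replicates)
  ct_ref <- rep(20, 2 * n_replicates)
  ct_target <- 25 - ifelse(group == "case", shift, 0)
  if (noise_sd > 0) {
    ct_ref <- ct_ref + rnorm(length(ct_ref), 0, noise_sd)
    ct_target <- ct_target + rnorm(length(ct_target), 0, noise_sd)
  }
  data.frame(feature_id = feature_id,
             sample_id = sprintf("%s_%d", group,
                                 rep(seq_len(n_replicates), 2)),
             group = group, target_ct = ct_target, ref_ct = ct_ref,
             stringsAsFactors = FALSE)
}
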