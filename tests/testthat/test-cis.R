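test_that("top-lncRNA selection orders by |fc|, then p, then id", {
  rec <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    fc = c(100, 50, 50, 7, 3),
    direction = c("up", "down", "up", "up", "down"),
    p = c(0.01, 0.04, 0.01, 0.02, 0.03),
    q = 0.05, significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  # tie at fc=50 broken by smaller p: c (p=.01) beats b (p=.04)
  expect_identical(select_top_lncrnas(rec, 2), c("a", "c"))
  # direction is irrelevant, only magnitude counts
  expect_identical(select_top_lncrnas(rec, 3), c("a", "c", "b"))
  # fewer significant than requested: all returned, with a note
  expect_message(got <- select_top_lncrnas(rec, 200), "only 4")
  expect_identical(got, c("a", "c", "b", "d"))
})

# fixture: lncRNA at [1,000,000, 1,002,000); genes placed around it
cis_fixture <- function(gene_starts, gene_width = 10000,
                        lnc_start = 1000000, lnc_end = 1002000,
                        chrom = "chr5") {
  ann <- rbind(
    data.frame(feature_id = "L1", gene_id = "LG1", chrom = chrom,
               start = lnc_start, end = lnc_end, strand = "+",
               biotype = "lncRNA", stringsAsFactors = FALSE),
    data.frame(feature_id = sprintf("G%d", seq_along(gene_starts)),
               gene_id = sprintf("G%d", seq_along(gene_starts)),
               chrom = chrom, start = gene_starts,
               end = gene_starts + gene_width, strand = "+",
               biotype = "coding", stringsAsFactors = FALSE))
  x <- c(1, 2, 3, 4, 5, 6)
  L <- 2^rbind(10 + x); rownames(L) <- "L1"
  M <- 2^t(sapply(seq_along(gene_starts), function(i) 10 + x))
  rownames(M) <- sprintf("G%d", seq_along(gene_starts))
  list(ann = ann, lnc = make_em(L), mrna = make_em(M))
}

test_that("the 300 kb window boundary is inclusive", {
  # gene ends exactly 300,000 bp before the lncRNA start; and one 1 bp
  # farther out
  fx <- cis_fixture(gene_starts = c(1000000 - 300000 - 10000,
                                    1000000 - 300001 - 10000))
  pairs <- find_cis_pairs("L1", fx$ann, fx$lnc, fx$mrna,
                          c("G1", "G2"))
  expect_identical(pairs$mrna_id, "G1")
  expect_identical(pairs$distance_bp, 300000L)
  expect_identical(pairs$relation, "upstream")
})

test_that("overlap means distance zero and relation overlapping", {
  fx <- cis_fixture(gene_starts = 995000)
  pairs <- find_cis_pairs("L1", fx$ann, fx$lnc, fx$mrna, "G1")
  expect_identical(pairs$distance_bp, 0L)
  expect_identical(pairs$relation, "overlapping")
})

test_that("relation flips with the lncRNA strand", {
  fx <- cis_fixture(gene_starts = 1100000)  # gene right of the lncRNA
  pairs <- find_cis_pairs("L1", fx$ann, fx$lnc, fx$mrna, "G1")
  expect_identical(pairs$relation, "downstream")
  fx$ann$strand[fx$ann$feature_id == "L1"] <- "-"
  pairs2 <- find_cis_pairs("L1", fx$ann, fx$lnc, fx$mrna, "G1")
  expect_identical(pairs2$relation, "upstream")
  expect_identical(pairs$distance_bp, pairs2$distance_bp)
})

test_that("uncorrelated candidates are dropped by the p gate", {
  fx <- cis_fixture(gene_starts = c(1100000, 1150000))
  set.seed(88)
  fx$mrna$values["G2", ] <- 2^rnorm(6, 10, 1)  # no relation to L1
  pairs <- find_cis_pairs("L1", fx$ann, fx$lnc, fx$mrna, c("G1", "G2"))
  expect_identical(pairs$mrna_id, "G1")
})

test_that("unannotated ids raise an error naming them", {
  fx <- cis_fixture(gene_starts = 1100000)
  expect_error(find_cis_pairs(c("L1", "Lmissing"), fx$ann, fx$lnc,
                              fx$mrna, "G1"),
               "Lmissing")
})

test_that("interval pairing equals the brute-force all-pairs scan", {
  set.seed(303)
  n_l <- 25; n_g <- 25
  mk <- function(n, prefix, biotype) {
    starts <- sample(0:2000000, n)
    data.frame(feature_id = sprintf("%s%02d", prefix, seq_len(n)),
               gene_id = sprintf("%s%02dg", prefix, seq_len(n)),
               chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
               start = starts, end = starts + sample(1000:30000, n, TRUE),
               strand = sample(c("+", "-"), n, TRUE),
               biotype = biotype, stringsAsFactors = FALSE)
  }
  ann <- rbind(mk(n_l, "L", "lncRNA"), mk(n_g, "G", "coding"))
  # perfectly co-linear profiles so the p gate never removes a candidate
  x <- c(1, 2, 3, 4, 5, 6)
  L <- 2^(matrix(rep(10 + x, n_l), n_l, byrow = TRUE))
  M <- 2^(matrix(rep(10 + x, n_g), n_g, byrow = TRUE))
  rownames(L) <- sprintf("L%02d", seq_len(n_l))
  rownames(M) <- sprintf("G%02d", seq_len(n_g))
  got <- find_cis_pairs(rownames(L), ann, make_em(L), make_em(M),
                        rownames(M), window = 300000)
  bf <- bf_window_pairs(ann[ann$biotype == "lncRNA", ],
                        ann[ann$biotype == "coding", ], 300000)
  expect_identical(got$lncrna_id, bf$lncrna_id)
  expect_identical(got$mrna_id, bf$mrna_id)
  expect_identical(got$distance_bp, as.integer(bf$distance_bp))
})

test_that("window and p-gate monotonicity hold", {
  set.seed(404)
  n <- 15
  starts <- sample(0:1500000, n)
  ann <- rbind(
    data.frame(feature_id = sprintf("L%02d", 1:n),
               gene_id = sprintf("LG%02d", 1:n), chrom = "chrA",
               start = starts, end = starts + 2000, strand = "+",
               biotype = "lncRNA", stringsAsFactors = FALSE),
    data.frame(feature_id = sprintf("G%02d", 1:n),
               gene_id = sprintf("G%02d", 1:n), chrom = "chrA",
               start = sample(0:1500000, n), end = NA,
               strand = "-", biotype = "coding",
               stringsAsFactors = FALSE))
  ann$end[16:30] <- ann$start[16:30] + 15000
  L <- 2^matrix(rnorm(n * 6, 10, 1), n)
  M <- 2^matrix(rnorm(n * 6, 10, 1), n)
  rownames(L) <- sprintf("L%02d", 1:n); rownames(M) <- sprintf("G%02d", 1:n)
  key <- function(p) paste(p$lncrna_id, p$mrna_id)
  args <- list(rownames(L), ann, make_em(L), make_em(M), rownames(M))
  small_w <- do.call(find_cis_pairs, c(args, window = 100000, p_max = 1))
  big_w <- do.call(find_cis_pairs, c(args, window = 400000, p_max = 1))
  expect_true(all(key(small_w) %in% key(big_w)))
  strict_p <- do.call(find_cis_pairs, c(args, window = 400000,
                                        p_max = 0.05))
  expect_true(all(key(strict_p) %in% key(big_w)))
})

test_that("count_localized counts selected lncRNAs with >= 1 pair", {
  pairs <- data.frame(lncrna_id = c("a", "a", "b"),
                      mrna_id = c("g1", "g2", "g1"),
                      stringsAsFactors = FALSE)
  expect_identical(count_localized(c("a", "b", "c", "d"), pairs), 2L)
  expect_identical(count_localized(character(), pairs), 0L)
  expect_identical(count_localized(c("a", "b"), pairs[0, ]), 0L)
})

test_that("the planted locus yields exactly the true cis pairs", {
  ds <- simulate_dataset(simulation_config(
    n_coding = 400, n_lncrna = 400, n_mirna = 60,
    locus = locus_spec(n_mirna = 49), seed = 7))
  del <- differential_expression(quantile_normalize(ds$lncrna))
  dec <- differential_expression(quantile_normalize(ds$coding))
  top <- select_top_lncrnas(del, 200)
  pairs <- find_cis_pairs(top, ds$annotation,
                          quantile_normalize(ds$lncrna),
                          quantile_normalize(ds$coding),
                          dec$feature_id[dec$significant])
  expect_identical(pairs[, c("lncrna_id", "mrna_id")],
                   ds$truth$cis_pairs)
  expect_identical(count_localized(top, pairs), 8L)
})
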