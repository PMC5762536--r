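test_that("quantile normalization: fixed point, hand example, order stats", {
  # identical columns are untouched
  v <- matrix(c(1, 5, 9), 3, 4)
  em <- make_em(v, 2, 2)
  expect_equal(quantile_normalize(em)$values, em$values)

  # columns [1,2] and [3,4]: order-statistic means are (2,3)
  em2 <- make_em(cbind(c(1, 2), c(3, 4), c(1, 2), c(3, 4)), 2, 2)
  qn <- quantile_normalize(em2)
  expect_equal(unname(qn$values), matrix(c(2, 3), 2, 4))

  # defining property: all sorted columns identical; and idempotence
  em3 <- random_em(nf = 40, seed = 3)
  qn3 <- quantile_normalize(em3)
  sorted <- apply(qn3$values, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1, 1)],
               ignore_attr = TRUE)
  expect_equal(quantile_normalize(qn3)$values, qn3$values,
               tolerance = 1e-12)
})

test_that("ties receive the mean of the reference values they span", {
  # column 1 has a 2-way tie at ranks 1-2
  v <- cbind(c(1, 1, 5), c(2, 4, 6), c(2, 4, 6), c(2, 4, 6))
  qn <- quantile_normalize(make_em(v, 2, 2))
  ref <- rowMeans(apply(v, 2, sort))
  expect_equal(unname(qn$values[, 1]),
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("quantile normalization matches limma on random matrices", {
  skip_if_not_installed("limma")
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(2^rnorm(300, 8, 2), 50, 6)
    em <- make_em(v)
    expect_equal(quantile_normalize(em)$values,
                 limma::normalizeQuantiles(v, ties = TRUE),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("single-sample matrices are rejected", {
  em <- random_em(nf = 5)
  em$values <- em$values[, 1, drop = FALSE]
  em$groups <- em$groups[1]
  class(em) <- "ExpressionMatrix"
  expect_error(quantile_normalize(em), ">= 2 samples")
})

test_that("differential screen recovers a noiseless planted fold change", {
  base <- c(8, 10, 12)
  v <- 2^cbind(base + 2, base + 2, base + 2, base, base, base)
  v[2, ] <- 2^10  # constant feature
  de <- differential_expression(make_em(v))
  expect_equal(de$fc[1], 4)
  expect_identical(de$direction[1], "up")
  expect_true(de$significant[1])
  # constant in all samples: fc 1, p 1 by convention, not significant
  expect_equal(de$fc[2], 1)
  expect_equal(de$p[2], 1)
  expect_false(de$significant[2])
})

test_that("pooled t statistic matches the closed form and stats::t.test", {
  # log2 case (1,2,3) vs control (4,5,6): t = -3.674, p = 0.0214, df = 4
  v <- 2^rbind(c(1, 2, 3, 4, 5, 6))
  rownames(v) <- "f1"
  de <- differential_expression(make_em(v))
  expect_equal(de$t, -3/sqrt(2/3), tolerance = 1e-12)
  expect_equal(de$t, -3.674, tolerance = 1e-3)
  expect_equal(de$p, 0.021312, tolerance = 1e-4)

  for (seed in 1:10) {
    em <- random_em(nf = 8, seed = seed, sd = 0.6)
    de <- differential_expression(em)
    lv <- log2(em$values)
    oracle <- apply(lv, 1, function(x)
      stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$p.value)
    expect_equal(de$p, unname(oracle), tolerance = 1e-10)
  }
})

test_that("Welch option matches stats::t.test(var.equal = FALSE)", {
  em <- random_em(nf = 6, seed = 42, sd = 0.8)
  de <- differential_expression(em, var_equal = FALSE)
  lv <- log2(em$values)
  oracle <- apply(lv, 1, function(x)
    stats::t.test(x[1:3], x[4:6])$p.value)
  expect_equal(de$p, unname(oracle), tolerance = 1e-10)
})

test_that("swapping group labels flips directions, keeps fc and p", {
  em <- random_em(nf = 30, seed = 9, sd = 1)
  flipped <- expression_matrix(
    em$values,
    stats::setNames(ifelse(em$groups == "case", "control", "case"),
                    names(em$groups)))
  de1 <- differential_expression(em)
  de2 <- differential_expression(flipped)
  expect_equal(de1$fc, de2$fc, tolerance = 1e-12)
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  changed <- de1$fc > 1
  expect_true(all(de1$direction[changed] != de2$direction[changed]))
})

test_that("zero group means are floored with a note, fc threshold checked", {
  v <- rbind(c(0, 0, 0, 4, 4, 4), c(2, 2, 2, 2, 2, 2))
  expect_message(de <- differential_expression(make_em(v)),
                 "zero group mean")
  expect_identical(de$direction[1], "down")
  expect_true(de$fc[1] > 1)
  expect_error(differential_expression(make_em(v), fc_threshold = 1),
               "exceed 1")
})

test_that("fold-change bins use closed-left open-right boundaries", {
  rec <- data.frame(feature_id = c("a", "b", "c"),
                    fc = c(2.0, 4.99, 5.0), direction = "up",
                    p = 0.01, q = 0.01, significant = TRUE,
                    stringsAsFactors = FALSE)
  tab <- bin_fold_changes(rec)
  expect_identical(tab$n_up, c(2L, 1L, 0L, 0L, 0L))
  # empty input
  tab0 <- bin_fold_changes(rec[0, ])
  expect_identical(tab0$n_up, rep(0L, 5))
  expect_identical(tab0$n_down, rep(0L, 5))
})

test_that("planted fold-change grid lands in the expected bins", {
  # 10 features at each of fc 2, 5, 10, 100, noiseless (built on the
  # linear scale so the planted ratios are exact in floating point)
  base <- rep(1024, 40)
  fc <- rep(c(2, 5, 10, 100), each = 10)
  v <- cbind(base * fc, base * fc, base * fc, base, base, base)
  de <- differential_expression(make_em(v))
  tab <- bin_fold_changes(de)
  expect_identical(tab$n_up, c(10L, 10L, 10L, 0L, 10L))
})

test_that("volcano coordinates are signed log2 fc and -log10 p", {
  rec <- data.frame(feature_id = c("a", "b"), fc = c(2, 1),
                    direction = c("up", "up"), p = c(0.05, 1),
                    q = c(0.1, 1), significant = c(FALSE, FALSE),
                    stringsAsFactors = FALSE)
  vt <- volcano_table(rec)
  expect_equal(vt$log2_fc, c(1, 0))
  expect_equal(vt$neg_log10_p, c(-log10(0.05), 0))
  expect_identical(vt$significant, rec$significant)
})

test_that("sample clustering separates the groups on synthetic data", {
  ds <- simulate_dataset(simulation_config(
    n_coding = 400, n_lncrna = 50, n_mirna = 60,
    frac_de_coding = 0.2,
    locus = locus_spec(n_mirna = 49), seed = 7))
  hc <- hierarchical_cluster(quantile_normalize(ds$coding), "samples")
  k2 <- stats::cutree(hc, 2)
  expect_identical(length(unique(k2[1:3])), 1L)
  expect_identical(length(unique(k2[4:6])), 1L)
  expect_false(k2[[1]] == k2[[4]])
})

test_that("clustering merges duplicates first and does n-1 merges", {
  v <- 2^cbind(c(1, 5, 3), c(1, 5, 3), c(4, 1, 2), c(2, 6, 9),
               c(7, 1, 4), c(3, 3, 8))
  hc <- hierarchical_cluster(make_em(v), "samples")
  expect_identical(nrow(hc$merge), 5L)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(hc$merge[1, ], c(-1L, -2L))
  # 3 items -> exactly 2 merges
  em3 <- random_em(nf = 3, seed = 5)
  hc3 <- hierarchical_cluster(em3, "features")
  expect_identical(nrow(hc3$merge), 2L)
})
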