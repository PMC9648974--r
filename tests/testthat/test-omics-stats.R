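test_that("log2 normalization equalizes column moments in log2 units", {
  set.seed(8)
  x <- 2^matrix(rnorm(400, 25, 2), 100, 4)
  x[2, 3] <- NA
  tab <- tiny_abundance(x)
  norm <- log2_normalize(tab)
  mus <- colMeans(norm$values, na.rm = TRUE)
  sds <- apply(norm$values, 2, sd, na.rm = TRUE)
  expect_lt(diff(range(mus)), 1e-10)
  expect_lt(diff(range(sds)), 1e-10)
  expect_identical(norm$scale, "normalized")
  # values stay in log2-intensity units (grand mean preserved)
  expect_equal(mean(mus), mean(log2(x), na.rm = TRUE), tolerance = 0.1)
  # missing cells stay missing
  expect_true(is.na(norm$values[2, 3]))
})

test_that("log2 normalization is location-scale invariant per column", {
  set.seed(9)
  base <- 2^matrix(rnorm(300, 20, 1.5), 100, 3)
  # a column that is a constant multiple of another (a global loading
  # difference, +6 in log2) normalizes to the same values
  shifted <- cbind(base[, 1], base[, 1] * 64, base[, 3])
  colnames(shifted) <- paste0("s", 1:3)
  n <- log2_normalize(tiny_abundance(shifted))
  expect_equal(n$values[, 1], n$values[, 2], ignore_attr = TRUE,
               tolerance = 1e-10)

  two_same <- cbind(base[, 1], base[, 1])
  colnames(two_same) <- c("s1", "s2")
  n3 <- log2_normalize(tiny_abundance(two_same))
  expect_equal(n3$values[, 1], n3$values[, 2], ignore_attr = TRUE)

  bad <- base; bad[2:100, 2] <- NA
  expect_error(log2_normalize(tiny_abundance(bad)), "<2 present")
})

test_that("MNAR imputation draws from the left-shifted Gaussian", {
  # single column with known moments, many missing cells
  n_miss <- 1e5
  x <- matrix(NA_real_, n_miss + 2000, 1)
  set.seed(10)
  x[seq_len(2000), 1] <- rnorm(2000, 25, 2)
  m <- mean(x[1:2000, 1]); s <- sd(x[1:2000, 1])
  tab <- abundance_table(x, scale = "normalized")
  imp <- impute_mnar(tab, shift_sd = 2.5, width_sd = 0.3, seed = 3)
  draws <- imp$values[-(1:2000), 1]
  se <- 0.3 * s / sqrt(n_miss)
  expect_lt(abs(mean(draws) - (m - 2.5 * s)), 3 * se)
  expect_equal(sd(draws), 0.3 * s, tolerance = 0.02)
  # present values untouched, determinism, no-missing passthrough
  expect_equal(imp$values[1:2000, 1], x[1:2000, 1], ignore_attr = TRUE)
  imp2 <- impute_mnar(tab, seed = 3)
  expect_identical(imp$values, imp2$values)
  full <- abundance_table(matrix(rnorm(10), 5, 2), scale = "normalized")
  expect_identical(impute_mnar(full, seed = 1)$values, full$values)
  expect_error(impute_mnar(tab), "seed")
  allna <- abundance_table(matrix(c(1, 2, NA, NA), 2, 2),
                           scale = "normalized")
  expect_error(impute_mnar(allna, seed = 1), "fully missing")
})

test_that("adaptive test routes through the documented branches", {
  set.seed(12)
  # n = 6 vs 6 normal equal-variance data: parametric branch unless SW
  # (falsely) rejects; never Mann-Whitney when SW passes both groups
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    r <- adaptive_test(a, b)
    sw_ok <- shapiro.test(a)$p.value >= 0.05 && shapiro.test(b)$p.value >= 0.05
    if (sw_ok) expect_true(r$test_used %in% c("t_homo", "t_hetero"))
    else expect_identical(r$test_used, "mann_whitney")
  }
  # <= 4 replicates skip the normality gate entirely
  r3 <- adaptive_test(c(1.2, 0.8, 1.1), c(5.3, 4.9, 5.6))
  expect_true(r3$test_used %in% c("t_homo", "t_hetero"))
  # heavily skewed data with n > 4 triggers the nonparametric branch
  skew <- c(0.01, 0.02, 0.03, 0.04, 0.05, 50)
  expect_identical(adaptive_test(skew, rnorm(6, 10))$test_used,
                   "mann_whitney")
  # degenerate identical groups
  r_deg <- adaptive_test(rep(3, 5), rep(3, 5))
  expect_identical(r_deg$p, 1)
  expect_true(r_deg$degenerate)
  # pooled t matches stats::t.test on the homoscedastic branch
  a <- c(1.1, 2.3, 0.7, 1.9); b <- c(2.2, 3.1, 2.8, 2.4)
  r <- adaptive_test(a, b)
  ref <- t.test(a, b, var.equal = (r$test_used == "t_homo"))
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_error(adaptive_test(1, c(1, 2)), ">= 2")
})

test_that("Bonferroni adjustment is p*m, capped, monotone", {
  expect_equal(adjust_pvalues(0.01), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(adjust_pvalues(c(0.9, 0.9)), c(1, 1))
  expect_equal(adjust_pvalues(c(0.01, 0.04)), p.adjust(c(0.01, 0.04),
                                                       "bonferroni"))
  set.seed(2)
  p <- runif(50)
  adj <- adjust_pvalues(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calls use strict volcano thresholds", {
  expect_identical(call_significant(1.2, 0.01), "up")
  expect_identical(call_significant(0.9, 0.001), "ns")
  expect_identical(call_significant(-1.0, 0.04), "ns")  # boundary excluded
  expect_identical(call_significant(-1.5, 0.04), "down")
  expect_identical(call_significant(1.2, 0.05), "ns")   # p boundary excluded
  expect_identical(call_significant(c(2, -2, 0), c(0.01, 0.01, 0.01)),
                   c("up", "down", "ns"))
})

test_that("row z-scores have zero mean and unit SD; constant rows excluded", {
  x <- rbind(a = c(1, 2, 3), b = c(10, 20, 60), c = c(5, 5, 5))
  expect_warning(z <- zscore_rows(abundance_table(x, scale = "log2")),
                 "constant row")
  expect_equal(rowMeans(z), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(z, 1, sd), c(a = 1, b = 1), tolerance = 1e-10)
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_identical(attr(z, "excluded"), "c")
  expect_error(zscore_rows(matrix(c(1, NA), 1, 2)), "complete")
})

test_that("hierarchical clustering is deterministic and permutation-stable", {
  z <- rbind(r1 = c(0, 0, 0), r2 = c(0.001, 0, 0), r3 = c(9, 9, 9))
  cl <- cluster_rows(z)
  # the identical-ish pair merges first
  expect_identical(sort(cl$merge[1, ]), c(-2L, -1L))
  # permuting rows permutes labels but not topology (merge heights)
  perm <- c(3, 1, 2)
  cl2 <- cluster_rows(z[perm, ])
  expect_equal(cl$height, cl2$height)
  expect_error(cluster_rows(z[1, , drop = FALSE]), ">= 2 rows")
  zbad <- z; zbad[1, 1] <- NA
  expect_error(cluster_rows(zbad), "non-finite")
})

test_that("TIC normalization equalizes column sums and is scale-invariant", {
  set.seed(14)
  x <- matrix(rexp(60, 1e-6), 20, 3)
  tab <- tiny_abundance(x)
  norm <- tic_normalize(tab)
  sums <- colSums(norm$values)
  expect_lt(diff(range(sums)) / mean(sums), 1e-10)
  # doubling one sample's intensities changes nothing after normalization
  x2 <- x; x2[, 2] <- 2 * x[, 2]
  norm2 <- tic_normalize(tiny_abundance(x2))
  expect_equal(norm$values[, 2] / sum(norm$values[, 2]),
               norm2$values[, 2] / sum(norm2$values[, 2]), tolerance = 1e-12)
  zero <- x; zero[, 1] <- 0
  expect_error(tic_normalize(tiny_abundance(zero)), "zero total ion count")
})

test_that("redox ratio panels divide pairs and normalize to control mean", {
  x <- rbind(pyruvate = c(2, 4, 3, 6),
             lactate = c(4, 4, 6, 6),
             acetoacetate = c(1, 2, 1, 2),
             bhb = c(2, 2, 0, 4))
  colnames(x) <- paste0("s", 1:4)
  tab <- tiny_abundance(x)
  r <- redox_ratios(tab, list(c("pyruvate", "lactate"),
                              c("acetoacetate", "bhb")))
  expect_equal(r["pyruvate/lactate", ], c(s1 = 0.5, s2 = 1, s3 = 0.5, s4 = 1))
  expect_true(is.na(r["acetoacetate/bhb", "s3"]))  # zero denominator flagged

  des <- group_design(paste0("s", 1:4), c("ctrl", "ctrl", "ko", "ko"))
  rn <- redox_ratios(tab, list(c("pyruvate", "lactate")), des, "ctrl")
  expect_equal(mean(rn[1, c("s1", "s2")]), 1)
  expect_error(redox_ratios(tab, list(c("pyruvate", "citrate"))),
               "citrate")
})

test_that("mitochondrial annotation matches case-insensitively", {
  df <- data.frame(feature_id = c("Ndufa9", "NDUFA9", "ndufa9", "Gapdh"))
  out <- annotate_mito(df)
  expect_identical(out$mito, c(TRUE, TRUE, TRUE, FALSE))
  out2 <- annotate_mito(df, ann = c("GAPDH"))
  expect_identical(out2$mito, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("diff_abundance is deterministic and recovers a strong spike", {
  spiked <- stats::setNames(c(3, -3), c("feature_1", "feature_2"))
  tr <- omics_truth(n_features = 60, n_per_group = 6,
                    spiked_features = spiked, missing_rate = 0.05, seed = 41)
  d <- gen_omics_dataset(tr)
  res <- diff_abundance(d$table, d$design, seed = 42)
  res2 <- diff_abundance(d$table, d$design, seed = 42)
  expect_identical(res, res2)
  expect_identical(res$call[1], "up")
  expect_identical(res$call[2], "down")
  expect_true(all(res$p_adj >= res$p_value))
  # fold-change sign convention: second design group minus first
  expect_gt(res$log2fc[1], 1)
  ann <- annotate_mito(res)
  expect_identical(ann$mito, rep(FALSE, 60))
})
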