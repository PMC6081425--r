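make_reg <- function(n = 10000, shift_genes = NULL, shift = 0, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n))
  lfc <- rnorm(n, 0, 0.5)
  if (!is.null(shift_genes)) {
    lfc[genes %in% shift_genes] <- lfc[genes %in% shift_genes] + shift
  }
  data.frame(gene = genes, gw = lfc)
}

test_that("target-set shifts recover a planted median repression", {
  genes <- sprintf("g%05d", 1:10000)
  set_genes <- sample(genes, 1000)
  reg <- make_reg(10000, set_genes, -0.2, seed = 191)
  res <- target_set_shift(reg, set_genes, "gw")
  expect_lt(abs(res$delta_median - (-0.2)), 0.05)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$n_set, 1000)

  # null set: no material shift, non-extreme p
  null_set <- sample(genes, 1000)
  reg0 <- make_reg(10000, seed = 201)
  res0 <- target_set_shift(reg0, null_set, "gw")
  expect_lt(abs(res0$delta_median), 0.08)

  expect_error(target_set_shift(reg, character(0), "gw"), "empty target set")
  expect_error(target_set_shift(reg, genes, "gw"), "background")
})

test_that("ECDF tables are valid distribution functions", {
  reg <- make_reg(500, seed = 211)
  sets <- list(A = reg$gene[1:50], B = reg$gene[51:52])
  tab <- cdf_table(reg, sets, "gw")
  expect_setequal(unique(tab$set), c("A", "B", "Other"))
  for (nm in unique(tab$set)) {
    sub <- tab[tab$set == nm, ]
    expect_equal(max(sub$ecdf), 1)
    expect_true(all(diff(sub$ecdf) > 0))
    expect_true(all(diff(sub$log2fc) >= 0))
  }
  # single-value set is a one-step function
  one <- cdf_table(reg, list(S = reg$gene[3]), "gw", include_other = FALSE)
  expect_equal(nrow(one), 1)
  expect_equal(one$ecdf, 1)
  # planted shift moves the curve left of the background at the median
  set_genes <- reg$gene[1:100]
  reg_s <- make_reg(500, set_genes, -0.5, seed = 221)
  tab_s <- cdf_table(reg_s, list(S = set_genes), "gw")
  med_set <- tab_s$log2fc[tab_s$set == "S"][
    which.min(abs(tab_s$ecdf[tab_s$set == "S"] - 0.5))]
  med_bg <- tab_s$log2fc[tab_s$set == "Other"][
    which.min(abs(tab_s$ecdf[tab_s$set == "Other"] - 0.5))]
  expect_lt(med_set, med_bg)
})

test_that("per-miRNA summaries apply the 50-target floor exactly", {
  reg <- make_reg(2000, seed = 231)
  sets <- list(
    "miR-A" = reg$gene[1:49],          # one expressed target short
    "miR-B" = reg$gene[1:50],
    "miR-C" = reg$gene[100:400])
  out <- per_mirna_summary(reg, sets, "gw")
  expect_setequal(out$mirna, c("miR-B", "miR-C"))
  # oracle: direct median computation per set
  for (i in seq_len(nrow(out))) {
    genes <- sets[[out$mirna[i]]]
    expect_equal(out$median_log2fc[i],
                 median(reg$gw[reg$gene %in% genes]))
  }
  # planted miR-30-like repression ranks most negative
  shifted <- make_reg(2000, reg$gene[100:400], -0.3, seed = 241)
  out_s <- per_mirna_summary(shifted, sets, "gw")
  expect_equal(out_s$mirna[which.min(out_s$median_log2fc)], "miR-C")
  # all-zero table gives all-zero medians
  reg0 <- data.frame(gene = reg$gene, gw = 0)
  expect_true(all(per_mirna_summary(reg0, sets, "gw")$median_log2fc == 0))
})

test_that("per-miRNA differential tests behave like Welch's t-test", {
  m <- matrix(c(8, 8, 8, 8), 1, 4, dimnames = list("m1", NULL))
  same <- mirna_differential(m, m)
  expect_equal(same$log2fc, 0)
  expect_equal(same$p_value, 1)

  # planted two-fold increase, n = 4 vs 3 replicates with small
  # replicate-level noise around each miRNA's mean
  set.seed(251)
  n_mir <- 30
  means <- rnorm(n_mir, 7, 0.5)
  base <- matrix(2^(means + rnorm(n_mir * 4, 0, 0.1)), n_mir, 4,
                 dimnames = list(sprintf("m%02d", 1:n_mir), NULL))
  ko <- matrix(2^(means + 1 + rnorm(n_mir * 3, 0, 0.1)),
               n_mir, 3, dimnames = list(rownames(base), NULL))
  res <- mirna_differential(base, ko, pseudocount = 0)
  expect_lt(abs(mean(res$log2fc) - 1), 0.15)
  expect_true(all(res$p_value < 0.05))

  # agrees with a direct t.test on the log scale
  i <- 5
  direct <- t.test(log2(ko[i, ]), log2(base[i, ]))
  expect_equal(res$p_value[i], direct$p.value)
  expect_error(mirna_differential(base[, 1, drop = FALSE], ko), "replicates")
})

test_that("the serum DEG filter requires concordance in both clones", {
  tp <- c("0h", "8h", "12h")
  genes <- c("bothUp", "ko1Only", "discordant", "lowExpr", "flat")
  wt <- matrix(10, 5, 3, dimnames = list(genes, tp))
  ko1 <- wt
  ko2 <- wt
  ko1["bothUp", "8h"] <- 25
  ko2["bothUp", "8h"] <- 26          # |lfc| > 1 in both, same sign
  ko1["ko1Only", "8h"] <- 25         # KO1 only
  ko1["discordant", "8h"] <- 25
  ko2["discordant", "8h"] <- 4       # opposite sign
  wt["lowExpr", ] <- 0.2
  ko1["lowExpr", ] <- 0.6            # strong FC but not expressed
  ko2["lowExpr", ] <- 0.6
  degs <- serum_deg_filter(wt, ko1, ko2)
  expect_equal(degs, "bothUp")

  # monotone: raising the fold threshold never adds genes
  d1 <- serum_deg_filter(wt, ko1, ko2, lfc_min = 0.5)
  d2 <- serum_deg_filter(wt, ko1, ko2, lfc_min = 1.5)
  expect_true(all(d2 %in% d1))

  # planted DEG set recovered exactly on a synthetic table
  set.seed(261)
  n <- 400
  g <- sprintf("g%03d", 1:n)
  wt2 <- matrix(rlnorm(n * 3, 2, 1), n, 3, dimnames = list(g, tp))
  ko1b <- wt2 * matrix(2^rnorm(n * 3, 0, 0.1), n, 3)
  ko2b <- wt2 * matrix(2^rnorm(n * 3, 0, 0.1), n, 3)
  planted <- sample(g, 25)
  ko1b[planted, "8h"] <- wt2[planted, "8h"] * 2^2.5
  ko2b[planted, "8h"] <- wt2[planted, "8h"] * 2^2.5
  got <- serum_deg_filter(wt2, ko1b, ko2b)
  expect_setequal(got, planted)
})

test_that("cluster enrichment matches the closed-form chi-square", {
  # 2x2 table (30,70 / 10,90): chi2 = n(ad-bc)^2 / (row and column sums)
  genes <- sprintf("g%03d", 1:200)
  clusters <- setNames(rep(c("I", "II"), each = 100), genes)
  target_set <- c(genes[1:30], genes[101:110])   # 30 in I, 10 in II
  res <- cluster_enrichment(clusters, target_set)
  closed <- 200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160)
  expect_equal(res$chi2[res$cluster == "I"], closed, tolerance = 1e-12)
  expect_equal(res$p_value[res$cluster == "I"],
               pchisq(closed, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(res$enrichment[res$cluster == "I"], 1)

  # a cluster seeded with 3x target density is significantly enriched
  set.seed(271)
  genes2 <- sprintf("h%04d", 1:2000)
  cl <- setNames(sample(c("I", "II", "III", "IV"), 2000, replace = TRUE),
                 genes2)
  targets <- c(sample(names(cl)[cl == "I"], 150),
               sample(names(cl)[cl != "I"], 150))
  res2 <- cluster_enrichment(cl, targets)
  expect_lt(res2$p_value[res2$cluster == "I"], 1e-6)

  # degenerate margins are flagged, not mis-tested
  res3 <- cluster_enrichment(clusters, character(0))
  expect_true(all(is.na(res3$p_value)))
})

test_that("the binned sensor estimator is exact under the null and scale-free", {
  set.seed(281)
  ev <- gen_flow_events(20000, 1, noise_sigma = 0.3, seed = 291)
  res <- sensor_repression(ev$sensor, ev$control, n_bins = 100,
                           bin_size = 200)
  expect_lt(abs(res$mean_fold - 1), 0.02)

  # identical populations give fold exactly 1 in every bin
  same <- sensor_repression(ev$control, ev$control, n_bins = 100,
                            bin_size = 200)
  expect_true(all(same$per_bin$fold == 1))

  # multiplicative dGFP rescaling and monotone dNGFR rescaling cancel
  ev2 <- gen_flow_events(20000, 3, seed = 301)
  base <- sensor_repression(ev2$sensor, ev2$control, 100, 200)
  scaled <- lapply(ev2, function(p) {
    data.frame(dGFP = 10 * p$dGFP, dNGFR = p$dNGFR^1.7)
  })
  res_scaled <- sensor_repression(scaled$sensor, scaled$control, 100, 200)
  expect_equal(res_scaled$mean_fold, base$mean_fold, tolerance = 1e-12)

  # noiseless events recover the planted fold exactly
  ev0 <- gen_flow_events(5000, 4, noise_sigma = 0, seed = 311)
  res0 <- sensor_repression(ev0$sensor, ev0$control, n_bins = 50,
                            bin_size = 100)
  expect_equal(res0$mean_fold, 4, tolerance = 0.05)

  expect_error(
    sensor_repression(data.frame(dGFP = numeric(0), dNGFR = numeric(0)),
                      ev$control), "empty")
})

test_that("null type-I error stays near the nominal level", {
  # Wilcoxon target-set shift over null resamplings
  set.seed(321)
  n <- 2000
  lfc <- rnorm(n, 0, 0.4)
  reg <- data.frame(gene = sprintf("g%04d", 1:n), gw = lfc)
  p_wilcox <- replicate(1000, {
    target_set_shift(reg, sample(reg$gene, 100), "gw")$p_value
  })
  expect_lte(mean(p_wilcox < 0.05), 0.06)

  # Welch per-miRNA differential under label permutation
  vals <- matrix(2^rnorm(7000, 7, 0.5), 1000, 7)
  rownames(vals) <- sprintf("m%04d", 1:1000)
  res <- mirna_differential(vals[, 1:4], vals[, 5:7])
  expect_lte(mean(res$p_value < 0.05), 0.06)
  # and the null p-value distribution is roughly uniform
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
})
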