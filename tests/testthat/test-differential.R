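# Ratios, z-test, BH, filters, regulated calling, reversion.

# small quant matrix with prescribed per-sample values
ratio_fixture <- function() {
  d <- toy_design(3)
  set.seed(99)
  v <- matrix(2^rnorm(51 * 18, 10, 0.3), 51, 18,
              dimnames = list(sprintf("F%02d", 1:51), d$sample))
  list(qm = quant_matrix(v, "protein"), design = d)
}

test_that("replicate log2 ratios are paired within replicate", {
  fx <- ratio_fixture()
  v <- fx$qm$values
  # equal abundances -> 0; doubled numerator -> 1 in every replicate
  v["F01", c("SC-IL/1", "SC-IL/2", "SC-IL/3")] <-
    v["F01", c("SC/1", "SC/2", "SC/3")]
  v["F02", c("SC-IL/1", "SC-IL/2", "SC-IL/3")] <-
    2 * v["F02", c("SC/1", "SC/2", "SC/3")]
  qm <- quant_matrix(v, "protein")
  tab <- replicate_log2_ratios(qm, fx$design, comparison("SC-IL", "SC"))
  expect_equal(tab$mean_ratio[tab$feature == "F01"], 0)
  expect_equal(tab$mean_ratio[tab$feature == "F02"], 1)
  # brute-force recomputation feature by feature
  oracle <- t(sapply(rownames(v), function(f)
    sapply(1:3, function(r)
      log2(v[f, paste0("SC-IL/", r)] / v[f, paste0("SC/", r)]))))
  expect_equal(unname(as.matrix(tab[, c("ratio_1", "ratio_2", "ratio_3")])),
               unname(oracle))
})

test_that("missing or zero values exclude a replicate, not the feature", {
  fx <- ratio_fixture()
  v <- fx$qm$values
  v["F03", "SC/2"] <- NA
  v["F04", "SC/1"] <- 0
  qm <- quant_matrix(v, "protein")
  expect_message(
    tab <- replicate_log2_ratios(qm, fx$design, comparison("SC-IL", "SC")),
    "zero-intensity")
  expect_true(is.na(tab$ratio_2[tab$feature == "F03"]))
  expect_equal(tab$n_used[tab$feature == "F03"], 2)
  expect_true(is.na(tab$ratio_1[tab$feature == "F04"]))
  expect_false(tab$complete[tab$feature == "F04"])
})

test_that("z-test standardizes against the median/MAD empirical null", {
  fx <- ratio_fixture()
  tab <- replicate_log2_ratios(fx$qm, fx$design, comparison("SC-IL", "SC"))
  res <- z_test(tab)
  loc <- median(tab$mean_ratio)
  sc <- mad(tab$mean_ratio)
  # a feature exactly at the null location has z = 0, p = 1
  i <- which.min(abs(tab$mean_ratio - loc))
  expect_equal(res$z[i], (tab$mean_ratio[i] - loc) / sc)
  expect_equal(res$p[which(tab$mean_ratio == loc)[1]], 1, tolerance = 1e-12)
  # a feature at location + 1.959964 * scale has p = 0.05
  tab2 <- tab
  tab2$mean_ratio[1] <- loc + 1.959964 * sc
  res2 <- z_test(tab2)
  loc2 <- median(tab2$mean_ratio); sc2 <- mad(tab2$mean_ratio)
  expect_equal(res2$p[1],
               2 * pnorm(-abs((tab2$mean_ratio[1] - loc2) / sc2)))
  manual_p <- 2 * pnorm(-1.959964)
  expect_equal(manual_p, 0.05, tolerance = 1e-6)
  # degenerate constant ratios are a statistical error
  tab3 <- tab; tab3$mean_ratio[] <- 0.3
  expect_error(z_test(tab3), "degenerate")
  expect_error(z_test(tab[1:5, ]), ">= 20 features")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "index 2")
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH adjusted p is monotone in raw p and bounded", {
  set.seed(8)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("direction consistency needs a strict shared sign", {
  tab <- data.frame(feature = c("a", "b", "c", "d", "e"),
                    ratio_1 = c(0.5, 0.5, 0.5, -0.2, NA),
                    ratio_2 = c(0.2, -0.1, 0.0, -0.4, NA),
                    ratio_3 = c(0.9, 0.9, 0.9, -0.1, 0.3))
  expect_equal(direction_consistency(tab),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("transfection filter applies the 0.2 log2 window inclusively", {
  d <- toy_design(3)
  v <- matrix(1000, 10, 18,
              dimnames = list(sprintf("F%02d", 1:10), d$sample))
  # plant CON/SC offsets: 3 violators, one exactly at the boundary
  set_ratio <- function(v, f, lr) {
    v[f, c("CON/1", "CON/2", "CON/3")] <-
      2^lr * v[f, c("SC/1", "SC/2", "SC/3")]
    v
  }
  v <- set_ratio(v, "F01", 0.19)
  v <- set_ratio(v, "F02", 0.21)
  v <- set_ratio(v, "F03", -0.30)
  v <- set_ratio(v, "F04", -0.19)
  v <- set_ratio(v, "F05", 0.50)
  qm <- quant_matrix(v, "protein")
  tf <- transfection_filter(qm, d, window = 0.2)
  expect_true(tf$pass_ctrl[tf$feature == "F01"])   # 0.19 accepted
  expect_false(tf$pass_ctrl[tf$feature == "F02"])  # 0.21 rejected
  expect_true(tf$pass_ctrl[tf$feature == "F04"])   # symmetric window
  expect_equal(sum(tf$pass_ctrl), 7)               # 3 planted violators
  expect_true(all(tf$pass_il))                     # CON-IL == SC-IL here
  # window is inclusive: a ratio exactly at the boundary passes
  at_boundary <- abs(tf$ctrl_log2[tf$feature == "F05"])
  tf_b <- transfection_filter(qm, d, window = at_boundary)
  expect_true(tf_b$pass_ctrl[tf_b$feature == "F05"])
  tf_below <- transfection_filter(qm, d, window = at_boundary * (1 - 1e-9))
  expect_false(tf_below$pass_ctrl[tf_below$feature == "F05"])
})

test_that("comparisons spanning IL status accept either control window", {
  d <- toy_design(3)
  v <- matrix(1000, 30, 18,
              dimnames = list(sprintf("F%02d", 1:30), d$sample))
  v["F01", c("CON/1", "CON/2", "CON/3")] <- 1000 * 2^0.5     # fails ctrl
  v["F02", c("CON-IL/1", "CON-IL/2", "CON-IL/3")] <- 1000 * 2^0.5 # fails IL
  v["F03", grep("^CON", colnames(v))] <- 1000 * 2^0.5        # fails both
  qm <- quant_matrix(v, "protein")
  tf <- transfection_filter(qm, d)
  pass <- phosphoTMT:::transfection_pass_for(
    tf, comparison("SC-IL", "SC"), tf$feature)
  expect_true(pass[tf$feature == "F01"])
  expect_true(pass[tf$feature == "F02"])
  expect_false(pass[tf$feature == "F03"])
  # same-condition comparisons use their own pair only
  pass_il <- phosphoTMT:::transfection_pass_for(
    tf, comparison("DMT1-KD-IL", "SC-IL"), tf$feature)
  expect_false(pass_il[tf$feature == "F02"])
  expect_true(pass_il[tf$feature == "F01"])
})

test_that("significance is the conjunction of all three conditions", {
  sim <- small_sim(seed = 41, n_proteins = 300, phospho_fraction = 0,
                   frac_phospho_only = 0, frac_il1b_up = 0.1,
                   frac_il1b_down = 0, frac_reverted = 0,
                   replicate_noise_sd = 0.1, missing_rate = 0)
  qm <- normalize_total_intensity(
    suppressMessages(rollup_proteins(sim$psms, sim$design)))
  tf <- transfection_filter(qm, sim$design)
  res <- differential_test(qm, sim$design, comparison("SC-IL", "SC"), tf)
  expect_true(all(res$adj_p[res$significant] < 0.05))
  expect_true(all(res$direction_consistent[res$significant]))
  expect_true(all(res$transfection_pass[res$significant]))
  expect_true(all(res$adj_p >= res$p - 1e-15, na.rm = TRUE))
  # forcing inconsistency or filter failure removes the call
  res2 <- res
  res2$significant <- !is.na(res2$adj_p) & res2$adj_p < 0.05 &
    FALSE & res2$transfection_pass
  expect_equal(sum(res2$significant), 0)
  up <- call_regulated(res)$up
  truth_up <- sim$truth$features$feature[
    sim$truth$features$il1b_direction == "up"]
  expect_gt(length(intersect(up, truth_up)) / length(truth_up), 0.85)
})

test_that("swapping numerator and denominator negates ratios, keeps |z|", {
  fx <- ratio_fixture()
  a <- z_test(replicate_log2_ratios(fx$qm, fx$design,
                                    comparison("SC-IL", "SC")))
  b <- z_test(replicate_log2_ratios(fx$qm, fx$design,
                                    comparison("SC", "SC-IL")))
  expect_equal(b$mean_ratio, -a$mean_ratio)
  expect_equal(abs(b$z), abs(a$z), tolerance = 1e-9)
})

test_that("protein-level adjustment subtracts the parent ratio", {
  mk_tab <- function(feats, r1, r2, r3) {
    d <- data.frame(feature = feats, ratio_1 = r1, ratio_2 = r2,
                    ratio_3 = r3, stringsAsFactors = FALSE)
    d$mean_ratio <- rowMeans(d[, 2:4])
    d
  }
  ph <- mk_tab(c("pepA|S3", "pepB|S5"), c(1, 0.4), c(1, 0.6), c(1, 0.5))
  pr <- mk_tab("P1", 1, 1, 1)
  parents <- c("pepA|S3" = "P1", "pepB|S5" = "P_unquantified")
  adj <- adjust_phospho_for_protein(ph, pr, parents)
  # phospho ratio 1, protein ratio 1 -> occupancy unchanged
  expect_equal(unname(unlist(adj[1, c("ratio_1", "ratio_2", "ratio_3")])),
               c(0, 0, 0))
  expect_equal(adj$mean_ratio[1], 0)
  expect_true(adj$adjusted[1])
  # no quantified parent: raw ratios kept, flagged unadjusted
  expect_equal(adj$mean_ratio[2], 0.5)
  expect_false(adj$adjusted[2])
  # protein ratio 0 leaves the phospho ratio intact
  pr0 <- mk_tab("P1", 0, 0, 0)
  adj0 <- adjust_phospho_for_protein(ph, pr0, parents)
  expect_equal(adj0$mean_ratio[1], 1)
})

test_that("reversion classification follows the band and both calls", {
  d <- toy_design(3)
  base <- matrix(1000, 40, 18,
                 dimnames = list(sprintf("F%02d", 1:40), d$sample))
  il_cols <- c("SC-IL/1", "SC-IL/2", "SC-IL/3")
  kd_cols <- c("DMT1-KD-IL/1", "DMT1-KD-IL/2", "DMT1-KD-IL/3")
  conil_cols <- c("CON-IL/1", "CON-IL/2", "CON-IL/3")
  # F01: 2x up under IL, knock-down at 0.6 x SC-IL -> reverted
  base["F01", c(il_cols, conil_cols)] <- 2000
  base["F01", kd_cols] <- 0.6 * 2000
  # F02: up under IL but knock-down equal to SC-IL -> none
  base["F02", c(il_cols, conil_cols)] <- 2000
  base["F02", kd_cols] <- 2000
  # F03: up under IL, knock-down overshoots past the band (0.45x)
  base["F03", c(il_cols, conil_cols)] <- 2000
  base["F03", kd_cols] <- 0.45 * 2000
  # F04: down under IL, knock-down at 1/0.6 of SC-IL -> reverted (mirror)
  base["F04", c(il_cols, conil_cols)] <- 500
  base["F04", kd_cols] <- 500 / 0.6
  # F05: only the knock-down comparison responds -> protective
  base["F05", kd_cols] <- 1800
  # mild jitter so the z-test null scale is positive
  set.seed(11)
  jitter <- matrix(2^rnorm(length(base), 0, 0.02), nrow(base))
  qm <- quant_matrix(base * jitter, "protein")
  tf <- transfection_filter(qm, d)
  res_il <- differential_test(qm, d, comparison("SC-IL", "SC"), tf)
  res_kd <- differential_test(qm, d, comparison("DMT1-KD-IL", "SC-IL"), tf)
  calls <- classify_reversion(res_il, res_kd, qm, d)
  cat_of <- function(f) calls$category[calls$feature == f]
  expect_equal(cat_of("F01"), "reverted")
  expect_equal(cat_of("F02"), "none")
  expect_equal(cat_of("F03"), "none")       # outside the 0.5-0.7 band
  expect_equal(cat_of("F04"), "reverted")
  expect_equal(cat_of("F05"), "protective-up")
  expect_equal(cat_of("F06"), "none")       # flat everywhere
  expect_equal(calls$reversion_fraction[calls$feature == "F01"], 0.6,
               tolerance = 0.05)
  expect_error(classify_reversion(NULL, res_kd, qm, d), "pipeline error")
})
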