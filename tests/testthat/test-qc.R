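test_that("positive-control curve check matches a hand OLS oracle", {
  panel <- tiny_panel(n_endo = 1, n_neg = 2, n_pos = 4, n_hk = 3)
  conc <- panel$nominal_concentration[panel$probe_class == "positive"]
  # perfectly proportional counts: slope 1, r2 1 on the log-log scale
  # (+1 offsets cancel because both axes use the same construction? no --
  #  use large counts so the +1 guard is negligible, then exact via lm)
  prop <- 1000 * conc
  mk <- function(pos_counts) {
    counts <- matrix(c(50, 3, 4, pos_counts, 100, 200, 300), nrow = 1)
    colnames(counts) <- panel$probe_id
    tiny_matrix(round(counts), panel)
  }
  r <- positive_control_check(mk(prop))
  expect_equal(r$pos_control_r2, 1, tolerance = 1e-4)
  expect_equal(r$pos_control_slope, 1, tolerance = 1e-3)
  # flat response: slope exactly 0, and r2 is reported as 0
  r0 <- positive_control_check(mk(c(7, 7, 7, 7)))
  expect_equal(r0$pos_control_slope, 0)
  expect_equal(r0$pos_control_r2, 0)
  # perturbed ladder against an independent least-squares computation
  y <- log2(c(128, 32, 64, 2) + 1); x <- log2(c(128, 32, 8, 2))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rp <- positive_control_check(mk(c(128, 32, 64, 2)))
  expect_equal(rp$pos_control_slope, beta)
  expect_equal(rp$pos_control_r2, r2)
  # r2 invariant under a global scale factor on the sample's counts
  rs <- positive_control_check(mk(10 * c(128, 32, 64, 2) + 4))
  expect_equal(rs$pos_control_r2, r2, tolerance = 0.02)
  # fewer than 3 distinct concentrations is an error
  p2 <- tiny_panel(n_pos = 2)
  c2 <- matrix(rep(5, nrow(p2)), nrow = 1, dimnames = list("s", p2$probe_id))
  expect_error(positive_control_check(tiny_matrix(c2, p2)), ">= 3")
})

test_that("background statistics use the n-1 standard deviation", {
  panel <- tiny_panel(n_endo = 1, n_neg = 8, n_pos = 4, n_hk = 3)
  mk <- function(neg) {
    counts <- matrix(c(100, neg, 512, 128, 32, 8, 100, 100, 100), nrow = 1,
                     dimnames = list("s1", panel$probe_id))
    tiny_matrix(counts, panel)
  }
  b1 <- background_stats(mk(rep(4, 8)))
  expect_equal(b1$background_mean, 4)
  expect_equal(b1$background_sd, 0)
  expect_equal(b1$background_threshold, 4)
  b2 <- background_stats(mk(c(1, 3, 1, 3, 1, 3, 1, 3)))
  expect_equal(b2$background_mean, 2)
  expect_equal(b2$background_sd, sqrt(8 / 7))
  expect_equal(b2$background_threshold, 2 + 2 * sqrt(8 / 7))
  b3 <- background_stats(mk(rep(0, 8)))
  expect_equal(b3$background_threshold, 0)
  # threshold identity holds to machine precision
  expect_equal(b2$background_threshold - b2$background_mean -
                 2 * b2$background_sd, 0)
})

test_that("sample flagging applies thresholds and is monotone in r2_min", {
  pos <- data.frame(sample_id = c("a", "b", "c"),
                    pos_control_r2 = c(1.0, 0.5, 0.99),
                    pos_control_slope = c(1, 0.2, 1))
  bg <- data.frame(sample_id = c("a", "b", "c"),
                   background_mean = c(5, 6, 50),
                   background_sd = c(1, 1, 10),
                   background_threshold = c(7, 8, 70))
  fl <- flag_samples(pos, bg, r2_min = 0.95, background_max = 30)
  expect_equal(fl$flags, c("", "nonlinear_positive_controls",
                           "elevated_background"))
  # raising r2_min never unflags
  for (r2m in c(0.95, 0.97, 0.995, 1)) {
    fl2 <- flag_samples(pos, bg, r2_min = r2m, background_max = 30)
    was <- grepl("nonlinear", fl$flags)
    now <- grepl("nonlinear", fl2$flags)
    expect_true(all(now[was]))
  }
})

test_that("mean-variance screen recovers a planted variance outlier", {
  set.seed(1)
  n_genes <- 200
  mu <- exp(runif(n_genes, log(50), log(2000)))  # span the dynamic range
  counts <- matrix(rpois(30 * n_genes, rep(mu, each = 30)), nrow = 30)
  # plant one gene with 100x inflated variance at an in-range mean
  counts[, 7] <- round(pmax(0, rnorm(30, 300, 10 * sqrt(300))))
  panel <- probe_annotation(
    probe_id = c(sprintf("G%03d", seq_len(n_genes)), "N1", "N2", "P1", "P2",
                 "P3", "H1"),
    probe_class = rep(c("endogenous", "negative", "positive", "housekeeping"),
                      c(n_genes, 2, 3, 1)),
    nominal_concentration = c(rep(NA, n_genes + 2), 128, 32, 8, NA),
    reference_tier = c(rep("none", n_genes + 5), "high"))
  counts <- cbind(counts, matrix(5L, 30, 5), matrix(500L, 30, 1))
  colnames(counts) <- panel$probe_id
  scr <- mean_variance_screen(count_matrix(counts, panel), axis = "gene")
  expect_true("G007" %in% scr$outliers)
  expect_lt(length(scr$outliers), 0.1 * n_genes)
  # constant matrix: zero variance everywhere, no outliers
  cc <- matrix(7L, 30, nrow(panel), dimnames = list(NULL, panel$probe_id))
  scr0 <- mean_variance_screen(count_matrix(cc, panel), axis = "gene")
  expect_length(scr0$outliers, 0)
  # degenerate axis length is an error
  expect_error(mean_variance_screen(count_matrix(cc[1:2, , drop = FALSE],
                                                 panel), "sample"),
               ">= 3")
})

test_that("MAD outlier rule flags roughly its nominal tail under i.i.d. data", {
  # under a common law the flagged fraction stays small and stable
  frac <- vapply(seq_len(100), function(i) {
    set.seed(400 + i)
    counts <- matrix(rpois(20 * 150, 200), nrow = 20)
    panel <- probe_annotation(
      probe_id = c(sprintf("G%03d", 1:150), "N1", "N2", "H1"),
      probe_class = rep(c("endogenous", "negative", "housekeeping"),
                        c(150, 2, 1)),
      reference_tier = c(rep("none", 152), "high"))
    counts <- cbind(counts, matrix(5L, 20, 2), matrix(500L, 20, 1))
    colnames(counts) <- panel$probe_id
    scr <- mean_variance_screen(count_matrix(counts, panel), axis = "gene")
    length(scr$outliers) / 150
  }, numeric(1))
  expect_lt(mean(frac), 0.02)  # 4-MAD rule: far tail only
})

test_that("exploration summaries behave on duplicated and clustered samples", {
  set.seed(8)
  cfg <- sim_config(seed = 8, n_samples = 10, n_targets = 30)
  m <- generate_counts(cfg, generate_panel(cfg))
  m$counts[2, ] <- m$counts[1, ]  # duplicated sample
  ex <- explore_matrix(m)
  expect_equal(ex$sample_cor[1, 2], 1.0)
  expect_equal(sum(ex$pca$variance_share), 1.0)
  expect_s3_class(ex$sample_hclust, "hclust")

  # two planted sample clusters separate on PC1
  base <- matrix(rnbinom(20 * 50, mu = 200, size = 20), nrow = 20)
  base[11:20, 1:25] <- matrix(rnbinom(10 * 25, mu = 800, size = 20), nrow = 10)
  panel <- probe_annotation(
    probe_id = c(sprintf("G%02d", 1:50), "N1", "N2", "H1"),
    probe_class = rep(c("endogenous", "negative", "housekeeping"), c(50, 2, 1)),
    reference_tier = c(rep("none", 52), "high"))
  counts <- cbind(base, matrix(5L, 20, 2), matrix(500L, 20, 1))
  colnames(counts) <- panel$probe_id
  # constant control columns are excluded from correlations with a warning
  expect_warning(ex2 <- explore_matrix(count_matrix(counts, panel)),
                 "zero-variance")
  pc1 <- ex2$pca$scores[, 1]
  expect_gt(silhouette_1d(pc1, rep(c("a", "b"), each = 10)), 0.5)
})
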