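test_that("background subtraction floors at zero and preserves controls", {
  panel <- tiny_panel(n_endo = 3, n_neg = 2, n_pos = 4, n_hk = 3)
  counts <- matrix(c(100, 3, 50,   4, 4,   512, 128, 32, 8,   200, 100, 50,
                     80, 10, 40,   6, 6,   512, 128, 32, 8,   150, 90, 60),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), panel$probe_id))
  m <- tiny_matrix(counts, panel)
  sub <- technical_normalize(m, c(14, 4.138))
  expect_equal(unname(sub$counts["s1", c("G1", "G2", "G3")]), c(86, 0, 36))
  expect_equal(unname(sub$counts["s2", "G2"]), 10 - 4.138)
  # controls pass through untouched
  expect_equal(sub$counts[, panel$probe_class %in% c("negative", "positive")],
               counts[, panel$probe_class %in% c("negative", "positive")] + 0)
  # zero threshold is the identity
  expect_equal(technical_normalize(m, c(0, 0))$counts, counts + 0)
  # order preserved within a sample (monotonicity)
  expect_true(all(diff(order(sub$counts["s1", c("G2", "G3", "G1")])) ==
                    diff(order(counts["s1", c("G2", "G3", "G1")]))))
  expect_error(technical_normalize(m, 14), "length")
})

test_that("biological normalization matches the geometric-mean hand oracle", {
  # two samples with reference geomeans 100 and 400:
  # grand geomean sqrt(100*400) = 200 -> factors 2.0 and 0.5
  panel <- tiny_panel(n_endo = 2, n_neg = 2, n_pos = 4, n_hk = 3)
  counts <- matrix(c(50, 10,  4, 4,  512, 128, 32, 8,  100, 100, 100,
                     60, 20,  4, 4,  512, 128, 32, 8,  400, 400, 400),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), panel$probe_id))
  bio <- biological_normalize(count_matrix(counts, panel, raw = FALSE))
  expect_equal(unname(bio$factors), c(2.0, 0.5))
  expect_equal(unname(bio$matrix$counts["s1", "G1"]), 100)
  expect_equal(unname(bio$matrix$counts["s2", "G2"]), 10)

  # equal reference geomeans: factors 1, counts unchanged up to rounding
  counts2 <- counts; counts2["s2", c("H1", "H2", "H3")] <- 100
  bio2 <- biological_normalize(count_matrix(counts2, panel, raw = FALSE))
  expect_equal(unname(bio2$factors), c(1, 1))
  expect_equal(bio2$matrix$counts[, c("G1", "G2")], counts2[, c("G1", "G2")])

  # rounding is half away from zero, not banker's
  counts3 <- counts
  counts3["s1", "G1"] <- 1.25  # * factor 2 -> 2.5 -> 3
  bio3 <- biological_normalize(count_matrix(counts3, panel, raw = FALSE))
  expect_equal(unname(bio3$matrix$counts["s1", "G1"]), 3)
  expect_equal(round_half_away(c(2.5, 3.5, -2.5, 0.5)), c(3, 4, -3, 1))
})

test_that("reference-gene geometric means equalize across samples", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(seed = seed, n_samples = 12, n_targets = 20,
                      lane_factors = exp(stats::runif(12, -1, 1)))
    m <- generate_counts(cfg, generate_panel(cfg))
    bg <- background_stats(m)
    sub <- technical_normalize(m, bg$background_threshold)
    bio <- suppressWarnings(biological_normalize(sub))
    hk_cols <- which(m$panel$probe_class[m$panel$probe_class %in%
                                           c("endogenous", "housekeeping")] ==
                       "housekeeping")
    pre_hk <- bio$prerounded[, hk_cols, drop = FALSE]
    pre_hk[pre_hk == 0] <- 1
    gm <- apply(pre_hk, 1, function(x) exp(mean(log(x))))
    expect_equal(max(gm) - min(gm), 0, tolerance = 1e-9)
    # post-rounding within 0.5 counts per gene
    post_hk <- bio$matrix$counts[, m$panel$probe_id[m$panel$probe_class ==
                                                      "housekeeping"]]
    expect_true(all(abs(post_hk - bio$prerounded[, hk_cols]) <= 0.5))
  }
})

test_that("scaling one sample above background is removed by normalization", {
  # multiplying sample s by c rescales its factor by 1/c while the grand
  # geometric mean drifts by c^(1/n); the normalized profile is therefore
  # invariant up to that shared c^(1/n) shift (and rounding)
  cfg <- sim_config(seed = 17, n_samples = 6, n_targets = 15,
                    background_mean = 0, dispersion = 0.02)
  m <- generate_counts(cfg, generate_panel(cfg))
  norm1 <- suppressWarnings(normalize_pipeline(m))
  target <- m$panel$probe_class %in% c("endogenous", "housekeeping")
  m2_counts <- m$counts
  m2_counts[3, target] <- 3 * m$counts[3, target]
  norm2 <- suppressWarnings(normalize_pipeline(count_matrix(m2_counts,
                                                            m$panel)))
  endo <- m$panel$probe_id[m$panel$probe_class == "endogenous"]
  drift <- 3^(1 / 6)
  expect_true(all(abs(norm2$normalized$counts[3, endo] -
                        drift * norm1$normalized$counts[3, endo]) <=
                    0.5 + 0.5 * drift + 1e-6))
  # and the factor itself absorbed the scale: f2 = f1 * drift / 3
  expect_equal(unname(norm2$normalization_factors[3]),
               unname(norm1$normalization_factors[3] * drift / 3),
               tolerance = 1e-10)
})

test_that("noise-gene exclusion separates expressed from background genes", {
  panel <- tiny_panel(n_endo = 2, n_neg = 8, n_pos = 4, n_hk = 3)
  set.seed(30)
  n <- 24
  counts <- cbind(
    G1 = rpois(n, 50),          # 10x the negative-control level
    G2 = rpois(n, 5),           # background-level gene
    matrix(rpois(n * 8, 5), n, dimnames = list(NULL, sprintf("N%d", 1:8))),
    P1 = rpois(n, 1024), P2 = rpois(n, 256), P3 = rpois(n, 64),
    P4 = rpois(n, 16),
    H1 = rpois(n, 2000), H2 = rpois(n, 500), H3 = rpois(n, 125))
  m <- count_matrix(counts, panel)
  res <- exclude_noise_genes(m)
  expect_true("G1" %in% res$retained)
  expect_true("G2" %in% res$excluded)
  expect_true(res$p_values[["G1"]] < 0.05)

  # a gene identical to the negative-control level everywhere: tie rule p = 1
  cc <- counts; cc[, "G2"] <- 5L
  cc[, sprintf("N%d", 1:8)] <- 5L
  res_tie <- exclude_noise_genes(count_matrix(cc, panel))
  expect_equal(unname(res_tie$p_values["G2"]), 1)

  # alpha = 0 excludes everything; alpha = 1 retains anything above ties
  expect_length(exclude_noise_genes(m, alpha = 0)$retained, 0)
  expect_true("G1" %in% exclude_noise_genes(m, alpha = 1)$retained)
  # Wilcoxon variant agrees on this clear-cut fixture
  res_w <- exclude_noise_genes(m, test = "wilcoxon")
  expect_true("G1" %in% res_w$retained)
  expect_true("G2" %in% res_w$excluded)
})

test_that("full pipeline removes lane effects in a no-biology cohort", {
  lane_groups <- rep(c(0.5, 1, 2), each = 6)
  cfg <- sim_config(seed = 55, n_samples = 18, n_targets = 40,
                    background_mean = 0, dispersion = 0.01,
                    lane_factors = lane_groups)
  m <- generate_counts(cfg, generate_panel(cfg))
  norm <- suppressWarnings(normalize_pipeline(m))
  expr <- norm$normalized$counts[, norm$retained_genes, drop = FALSE]
  gm <- function(i) colMeans(expr[lane_groups == i, , drop = FALSE])
  ratio12 <- gm(0.5) / gm(1)
  ratio32 <- gm(2) / gm(1)
  expect_true(stats::median(abs(log2(ratio12))) < log2(1.05))
  expect_true(stats::median(abs(log2(ratio32))) < log2(1.05))
  # pipeline is approximately the identity with no background and unit lanes
  cfg0 <- sim_config(seed = 56, n_samples = 6, n_targets = 10,
                     background_mean = 0, dispersion = 0)
  m0 <- generate_counts(cfg0, generate_panel(cfg0))
  n0 <- suppressWarnings(normalize_pipeline(m0))
  endo <- m0$panel$probe_id[m0$panel$probe_class == "endogenous"]
  rel <- abs(n0$normalized$counts[, endo] - m0$counts[, endo]) /
    pmax(m0$counts[, endo], 1)
  expect_lt(stats::median(rel), 0.05)
})
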