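test_that("identical conditions produce no suprathreshold clusters", {
  set.seed(70)
  a <- array(rnorm(6 * 2 * 5), c(6, 2, 5))
  res <- cluster_perm_test(a, a, n_perm = 100)
  expect_equal(length(res$clusters), 0)
  expect_false(any(res$mask))
})

test_that("exact cluster p equals exhaustive enumeration (several datasets)", {
  set.seed(71)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    nt <- sample(4:6, 1)
    shift <- sample(c(1.5, 2, 2.5), 1)
    a <- array(rnorm(n * nt, shift), c(n, 1, nt))
    b <- array(rnorm(n * nt), c(n, 1, nt))
    res <- cluster_perm_test(a, b, exact = TRUE)
    oracle <- enum_cluster_oracle(matrix(a - b, n, nt))
    expect_equal(length(res$clusters), length(oracle$masses))
    if (length(res$clusters)) {
      o <- order(vapply(res$clusters, `[[`, 1, "mass"))
      oo <- order(oracle$masses)
      expect_equal(vapply(res$clusters, `[[`, 1, "mass")[o],
                   oracle$masses[oo], tolerance = 1e-10)
      expect_equal(vapply(res$clusters, `[[`, 1, "p")[o], oracle$p[oo],
                   tolerance = 1e-10)
    }
  }
})

test_that("spatial adjacency merges clusters across neighbouring channels", {
  set.seed(72)
  n <- 6
  a <- array(rnorm(n * 2 * 3, 3), c(n, 2, 3))
  b <- array(rnorm(n * 2 * 3), c(n, 2, 3))
  adj <- matrix(TRUE, 2, 2); diag(adj) <- FALSE
  res_adj <- cluster_perm_test(a, b, adjacency = adj, exact = TRUE)
  res_sep <- cluster_perm_test(a, b, adjacency = NULL, exact = TRUE)
  expect_lte(length(res_adj$clusters), length(res_sep$clusters))
  n_adj <- sum(vapply(res_adj$clusters, function(c_) length(c_$nodes), 1L))
  n_sep <- sum(vapply(res_sep$clusters, function(c_) length(c_$nodes), 1L))
  expect_equal(n_adj, n_sep)   # same suprathreshold set, different grouping
})

test_that("Monte-Carlo p values carry the +1 correction and are in (0, 1]", {
  set.seed(73)
  a <- array(rnorm(8 * 1 * 6, 2), c(8, 1, 6))
  b <- array(rnorm(8 * 1 * 6), c(8, 1, 6))
  res <- cluster_perm_test(a, b, n_perm = 200, seed = 4)
  for (cl in res$clusters) {
    expect_gte(cl$p, 1 / 201)
    expect_lte(cl$p, 1)
  }
  expect_warning(cluster_perm_test(a, b, n_perm = 50), "n_perm")
})

test_that("Wilcoxon signed rank: worked examples and base-R agreement", {
  w <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(w$V, 6)
  expect_equal(w$p, 0.25)                      # 2/8 two-sided
  # one negative smallest difference among 3 -> V = 5
  expect_equal(wilcoxon_signed_rank(c(-1, 2, 3))$V, 5)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
  set.seed(74)
  for (n in c(8, 12, 20)) {
    d <- rnorm(n, 0.4)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d)
    expect_equal(ours$V, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact signed-rank distribution sums to one (n <= 12)", {
  for (n in c(5, 9, 12)) {
    cnt <- 1
    for (r in seq_len(n)) cnt <- c(cnt, numeric(r)) + c(numeric(r), cnt)
    expect_equal(sum(cnt), 2^n)
    # matches full enumeration of V over sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% seq_len(n)
    expect_equal(as.numeric(table(factor(v_all, levels = 0:(n * (n + 1) / 2)))),
                 cnt)
  }
})

test_that("Wilcoxon exact p is uniform under a symmetric null", {
  set.seed(75)
  p <- replicate(400, wilcoxon_signed_rank(rnorm(14))$p)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))  # exact p is discrete
  expect_gt(ks$p.value, 0.01)
})

test_that("rm-ANOVA matches the aov error decomposition on a worked table", {
  set.seed(76)
  arr <- array(rnorm(4 * 3 * 2), c(4, 3, 2)) +
    rep(c(0, 0.8, 1.6), each = 4)              # time effect
  res <- rm_anova_2way(arr, c("time", "phase"))
  df <- expand.grid(s = factor(1:4), a = factor(1:3), b = factor(1:2))
  df$y <- as.vector(arr)
  fit <- summary(stats::aov(y ~ a * b + Error(s / (a * b)), df))
  f_aov <- c(fit[["Error: s:a"]][[1]]["a", "F value"],
             fit[["Error: s:b"]][[1]]["b", "F value"],
             fit[["Error: s:a:b"]][[1]]["a:b", "F value"])
  expect_equal(res$F, f_aov, tolerance = 1e-10)
  # ges against hand-assembled sums of squares from the aov tables
  ss_err <- sum(fit[["Error: s"]][[1]]["Residuals", "Sum Sq"],
                fit[["Error: s:a"]][[1]]["Residuals", "Sum Sq"],
                fit[["Error: s:b"]][[1]]["Residuals", "Sum Sq"],
                fit[["Error: s:a:b"]][[1]]["Residuals", "Sum Sq"])
  ss_a <- fit[["Error: s:a"]][[1]]["a", "Sum Sq"]
  expect_equal(res["time", "ges"], ss_a / (ss_a + ss_err), tolerance = 1e-10)
})

test_that("rm-ANOVA: sphericity handling and degenerate inputs", {
  # all cells equal: flat flag, F = 0
  res0 <- rm_anova_2way(array(5, c(4, 3, 2)))
  expect_true(all(res0$flat))
  expect_true(all(res0$F == 0))
  # two-level factor never gets a correction
  set.seed(77)
  res <- rm_anova_2way(array(rnorm(6 * 3 * 2), c(6, 3, 2)))
  expect_true(is.na(res["b", "mauchly_p"]) || res["b", "gg_eps"] == 1)
  expect_false(res["b", "gg_applied"])
  # Mauchly/GG agree with the mlm machinery on the time factor
  y <- matrix(rnorm(12 * 3), 12); y[, 3] <- y[, 3] * 4
  sph <- cardiomotor:::.sphericity(y)
  fit <- stats::lm(y ~ 1)
  ref <- stats::mauchly.test(fit, X = ~1)
  expect_equal(sph$p, ref$p.value, tolerance = 1e-8)
  # an absent design cell is rejected
  bad <- expand.grid(participant = 1:3, a = 1:3, b = 1:2)
  bad$value <- rnorm(nrow(bad))
  bad <- bad[!(bad$participant == 2 & bad$a == 3 & bad$b == 1), ]
  expect_error(rm_anova_2way(bad), "missing cells")
  expect_error(rm_anova_2way(data.frame(participant = 1, a = 1, b = 1,
                                        value = 1)), "at least 2")
})

test_that("LME distance comparison: single-participant OLS oracle", {
  set.seed(78)
  n <- 150
  d <- runif(n, 0, 800)
  y <- exp(6 - 6e-4 * d + rnorm(n, 0, 0.3))
  cmp <- lme_distance_models(y, d, rep(1, n))
  # closed-form nested OLS LRT: chi2 = n * log(RSS0 / RSS1)
  f0 <- lm(log(y) ~ 1); f1 <- lm(log(y) ~ d)
  chi_oracle <- n * log(sum(resid(f0)^2) / sum(resid(f1)^2))
  expect_equal(cmp$tests$chisq[1], chi_oracle, tolerance = 1e-6)
  expect_lt(cmp$tests$p[1], 0.001)
  expect_error(lme_distance_models(c(-1, 2), c(1, 2), c(1, 1)), "> 0")
})

test_that("LME with random intercepts detects the generated decline", {
  cfg <- small_cfg(seed = 79, n_tms = 150, mep_systole_gain = 1,
                   mep_distance_slope = 8e-4)
  tr <- gen_trial_stats(cfg, n_participants = 6)
  tr <- tr[!is.na(tr$distance_ms), ]
  cmp <- lme_distance_models(tr$mep_uv, tr$distance_ms, tr$participant)
  expect_lt(cmp$tests$p[1], 0.01)              # linear beats null
  expect_gt(cmp$tests$p[2], 0.01)              # quadratic adds nothing
})

test_that("power analysis: paper-scale value, monotonicity, degenerate d", {
  expect_equal(power_n_paired(0.48, 0.8, 0.05), 36)
  ns <- sapply(c(0.3, 0.5, 0.8, 1.5, 3), power_n_paired)
  expect_true(all(diff(ns) <= 0))              # monotone nonincreasing in d
  expect_lte(power_n_paired(3), 5)
  expect_gte(power_n_paired(0.48, 0.9), power_n_paired(0.48, 0.8))
  expect_error(power_n_paired(-1), "positive")
})

test_that("Cohen's d and the binned MEP profile behave as documented", {
  expect_equal(cohens_d_paired(c(1, -1)), 0)
  expect_warning(d_inf <- cohens_d_paired(c(2, 2, 2)), "infinite")
  expect_true(is.infinite(d_inf) && d_inf > 0)
  expect_equal(cohens_d_paired(c(0, 0, 0)), 0)
  expect_error(cohens_d_paired(1), "at least 2")
  # monotone log-decline -> decreasing profile
  cfg <- small_cfg(seed = 80, n_tms = 400, mep_systole_gain = 1,
                   mep_distance_slope = 1e-3, mep_log_noise_sd = 0.1)
  tr <- gen_trial_stats(cfg)
  prof <- binned_mep_profile(tr$mep_uv, tr$distance_ms)
  prof <- prof[prof$n >= 10, ]
  fit <- lm(mean_amplitude ~ bin_mid_ms, prof)
  expect_lt(coef(fit)[2], 0)
})

test_that("channel adjacency is symmetric, self-edge free, and sensible", {
  adj <- channel_adjacency(c("C3", "Cz", "C4", "CP4", "Fp1"))
  expect_true(all(adj == t(adj)))
  expect_true(all(!diag(adj)))
  expect_true(adj["C4", "CP4"])                # adjacent grid sites
  expect_false(adj["Fp1", "CP4"])              # far apart
})
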