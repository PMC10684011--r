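#' Spatiotemporal cluster-based permutation t test
#'
#' Paired two-condition test over a (space x [freq x] time) grid.
#' Per-node paired t statistics across participants are thresholded at
#' the two-tailed critical value for `sample_alpha`; suprathreshold nodes
#' are clustered by adjacency (spatial neighbour graph plus chain
#' adjacency along the frequency and time axes), separately for positive
#' and negative signs; cluster mass is the sum of t values. The null
#' distribution of the maximum absolute cluster mass is built from random
#' within-participant sign flips of the condition difference. Monte Carlo
#' p values use the +1-corrected estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`; with `exact = TRUE` all
#' `2^n` sign patterns are enumerated and the raw proportion is reported.
#' Clusters are significant at p < `sample_alpha / 2` per tail
#' (two-tailed convention).
#'
#' @param cond_a,cond_b Numeric arrays, participants x space x [freq x]
#'   time, matching shapes.
#' @param adjacency Space x space logical adjacency matrix (`NULL`: no
#'   spatial links between distinct sites).
#' @param n_perm Number of random sign-flip permutations.
#' @param sample_alpha Per-node threshold alpha (two-tailed).
#' @param seed RNG seed.
#' @param exact Enumerate all sign patterns instead of sampling.
#' @return Object of class `cluster_test_result`: `clusters` (list with
#'   `nodes`, `sign`, `mass`, `p`), `t` (per-node statistics, input
#'   shape), `mask` (significant-cluster membership), `null_max_mass`,
#'   `n_perm`, `seed`.
#' @export
cluster_perm_test <- function(cond_a, cond_b, adjacency = NULL,
                              n_perm = 1000, sample_alpha = 0.05, seed = 1,
                              exact = FALSE) {
  if (!all(dim(cond_a) == dim(cond_b))) stop("condition shapes differ")
  da <- dim(cond_a)
  if (is.null(da)) { da <- c(length(cond_a), 1, 1); dim(cond_a) <- dim(cond_b) <- da }
  n_sub <- da[1]
  if (n_sub < 2) stop("need at least 2 participants")
  grid_dims <- da[-1]
  if (length(grid_dims) == 1) grid_dims <- c(grid_dims, 1)
  n_nodes <- prod(grid_dims)
  diffs <- matrix(cond_a - cond_b, n_sub, n_nodes)
  if (!exact && n_perm < 100) warning("n_perm below 100: p values are coarse")
  nbr <- .grid_neighbors(grid_dims, adjacency)
  tcrit <- stats::qt(1 - sample_alpha / 2, n_sub - 1)
  tstat <- function(d) {
    m <- colMeans(d)
    s <- sqrt(colSums((d - rep(m, each = n_sub))^2) / (n_sub - 1))
    ifelse(s > 0, m / (s / sqrt(n_sub)), 0)
  }
  max_mass <- function(tv) {
    cl <- .find_clusters(tv, tcrit, nbr)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, function(c_) c_$mass, 1)))
  }
  t_obs <- tstat(diffs)
  clusters <- .find_clusters(t_obs, tcrit, nbr)
  if (exact) {
    if (n_sub > 20) stop("exact enumeration limited to 20 participants")
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n_sub)))
    null <- apply(signs, 1, function(s) max_mass(tstat(diffs * s)))
    p_of <- function(m) mean(null >= abs(m))
    n_perm_used <- nrow(signs)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      s <- sample(c(1, -1), n_sub, replace = TRUE)
      max_mass(tstat(diffs * s))
    }, numeric(1))
    p_of <- function(m) (1 + sum(null >= abs(m))) / (1 + n_perm)
    n_perm_used <- n_perm
  }
  mask <- array(FALSE, grid_dims)
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- p_of(clusters[[i]]$mass)
    if (clusters[[i]]$p < sample_alpha / 2) mask[clusters[[i]]$nodes] <- TRUE
  }
  structure(list(clusters = clusters, t = array(t_obs, grid_dims),
                 mask = mask, null_max_mass = null, n_perm = n_perm_used,
                 tcrit = tcrit, seed = seed, exact = exact),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: sign %+d, %d nodes, mass %.2f, p = %.4g\n",
                i, cl$sign, length(cl$nodes), cl$mass, cl$p))
  }
  invisible(x)
}

# neighbour index lists for a (space, freq, time) grid; dims of length 2
# mean (space, time). adjacency links sites; freq/time are chains.
.grid_neighbors <- function(grid_dims, adjacency) {
  if (length(grid_dims) == 2) grid_dims <- c(grid_dims[1], 1, grid_dims[2])
  ns <- grid_dims[1]; nf <- grid_dims[2]; nt <- grid_dims[3]
  if (!is.null(adjacency)) {
    stopifnot(nrow(adjacency) == ns, isTRUE(all(adjacency == t(adjacency))))
    sp_nb <- lapply(seq_len(ns), function(s) which(adjacency[s, ]))
  } else sp_nb <- lapply(seq_len(ns), function(s) integer(0))
  idx <- function(s, f, t) s + (f - 1) * ns + (t - 1) * ns * nf
  nbr <- vector("list", ns * nf * nt)
  for (t in seq_len(nt)) for (f in seq_len(nf)) for (s in seq_len(ns)) {
    nb <- sp_nb[[s]] + (f - 1) * ns + (t - 1) * ns * nf
    if (f > 1) nb <- c(nb, idx(s, f - 1, t))
    if (f < nf) nb <- c(nb, idx(s, f + 1, t))
    if (t > 1) nb <- c(nb, idx(s, f, t - 1))
    if (t < nt) nb <- c(nb, idx(s, f, t + 1))
    nbr[[idx(s, f, t)]] <- nb
  }
  nbr
}

# connected components of suprathreshold nodes, per sign
.find_clusters <- function(tv, tcrit, nbr) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) tv > tcrit else tv < -tcrit
    seen <- logical(length(tv))
    for (start in which(supra)) {
      if (seen[start]) next
      stack <- start; seen[start] <- TRUE; members <- integer(0)
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        members <- c(members, v)
        for (w in nbr[[v]]) if (supra[w] && !seen[w]) {
          seen[w] <- TRUE; stack <- c(stack, w)
        }
      }
      out[[length(out) + 1]] <- list(nodes = sort(members), sign = sgn,
                                     mass = sum(tv[members]))
    }
  }
  out
}

#' Wilcoxon signed-rank test
#'
#' Zeros are dropped, ties mid-ranked; `V` is the sum of ranks of
#' positive differences. The two-sided p value is exact (full null
#' distribution of `V` by convolution over sign assignments) for n <= 25
#' without ties, otherwise a normal approximation with tie and continuity
#' correction.
#'
#' @param diffs Paired differences.
#' @return List: `V`, `p`, `n` (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    # counts of V over all 2^n sign assignments (ranks are 1..n)
    cnt <- 1
    for (rr in seq_len(n)) cnt <- c(cnt, numeric(rr)) + c(numeric(rr), cnt)
    tot <- 2^n
    p_le <- sum(cnt[seq_len(v + 1)]) / tot
    p_ge <- sum(cnt[(v + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(V = v, p = p, n = n, method = method)
}

# Mauchly's sphericity test and Greenhouse-Geisser epsilon for a
# subjects x k matrix of within-factor scores
.sphericity <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  if (k <= 2) return(list(W = NA, p = NA, eps = 1))
  ctr <- stats::contr.helmert(k)
  ctr <- sweep(ctr, 2, sqrt(colSums(ctr^2)), "/")     # orthonormal contrasts
  m <- t(ctr) %*% stats::cov(mat) %*% ctr
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  if (any(lam <= 0)) return(list(W = 0, p = 0, eps = eps))
  W <- prod(lam) / (mean(lam))^(k - 1)
  d <- k - 1
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chi <- -f * (n - 1) * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chi, df, lower.tail = FALSE), eps = eps)
}

#' Two-way repeated-measures ANOVA with ges and sphericity correction
#'
#' Fully-within two-factor decomposition (each effect tested against its
#' interaction with subjects). Generalized eta-squared is
#' `SS_effect / (SS_effect + sum of all subject-related error SS)`.
#' Mauchly's test runs per within effect with more than 1 numerator df;
#' when it rejects at 0.05 the Greenhouse-Geisser epsilon multiplies the
#' degrees of freedom.
#'
#' @param values Numeric array subjects x levels(A) x levels(B), or a
#'   data.frame with columns `participant`, `a`, `b`, `value`.
#' @param factor_names Names for the two factors (output labels).
#' @return data.frame rows `a`, `b`, `a:b` with columns `F`, `df1`,
#'   `df2`, `p`, `ges`, `mauchly_p`, `gg_eps`, `gg_applied`, `flat`.
#' @export
rm_anova_2way <- function(values, factor_names = c("a", "b")) {
  if (is.data.frame(values)) {
    values$participant <- factor(values$participant)
    values$a <- factor(values$a); values$b <- factor(values$b)
    arr <- tapply(values$value, list(values$participant, values$a, values$b),
                  mean)
    if (any(is.na(arr))) stop("missing cells in the design")
    values <- arr
  }
  y <- values
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (is.na(b) || n < 2 || a < 2 || b < 2)
    stop("need at least 2 participants and 2 levels per factor")
  gm <- mean(y)
  m_i <- apply(y, 1, mean); m_j <- apply(y, 2, mean); m_k <- apply(y, 3, mean)
  m_ij <- apply(y, c(1, 2), mean); m_ik <- apply(y, c(1, 3), mean)
  m_jk <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((m_j - gm)^2)
  ss_b <- n * a * sum((m_k - gm)^2)
  ss_s <- a * b * sum((m_i - gm)^2)
  ss_ab <- n * sum((m_jk - outer(m_j, rep(1, b)) - outer(rep(1, a), m_k) + gm)^2)
  ss_as <- b * sum((m_ij - outer(m_i, rep(1, a)) - outer(rep(1, n), m_j) + gm)^2)
  ss_bs <- a * sum((m_ik - outer(m_i, rep(1, b)) - outer(rep(1, n), m_k) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  err_all <- ss_s + ss_as + ss_bs + ss_abs
  row <- function(ss_eff, ss_err, df1, df2, sph_mat) {
    flat <- ss_err < 1e-12 * max(1, ss_tot)
    if (flat) {
      return(data.frame(F = 0, df1 = df1, df2 = df2, p = NA, ges = 0,
                        mauchly_p = NA, gg_eps = 1, gg_applied = FALSE,
                        flat = TRUE))
    }
    F_ <- (ss_eff / df1) / (ss_err / df2)
    sph <- if (is.null(sph_mat)) list(W = NA, p = NA, eps = 1)
           else .sphericity(sph_mat)
    gg <- !is.na(sph$p) && sph$p < 0.05
    d1 <- if (gg) df1 * sph$eps else df1
    d2 <- if (gg) df2 * sph$eps else df2
    data.frame(F = F_, df1 = d1, df2 = d2,
               p = stats::pf(F_, d1, d2, lower.tail = FALSE),
               ges = ss_eff / (ss_eff + err_all),
               mauchly_p = sph$p, gg_eps = sph$eps, gg_applied = gg,
               flat = FALSE)
  }
  # interaction sphericity on per-time difference scores across B
  diff_b <- m_ij * 0
  if (b == 2) diff_b <- y[, , 1] - y[, , 2]
  res <- rbind(
    row(ss_a, ss_as, a - 1, (a - 1) * (n - 1), if (a > 2) m_ij else NULL),
    row(ss_b, ss_bs, b - 1, (b - 1) * (n - 1), if (b > 2) m_ik else NULL),
    row(ss_ab, ss_abs, (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1),
        if (a > 2 && b == 2) diff_b else NULL))
  rownames(res) <- c(factor_names, paste(factor_names, collapse = ":"))
  res
}

#' Hierarchical mixed-model comparison of MEP distance dependence
#'
#' Fits, by maximum likelihood, a random-intercept null model for
#' log-MEP, a model adding the linear distance from the preceding R-peak,
#' and a model adding its square; reports the two likelihood-ratio tests
#' (df = 1 each). With a single participant the models reduce to nested
#' fixed-effects regressions.
#'
#' @param mep_uv Positive MEP amplitudes, uV.
#' @param distance_ms Distance from the preceding R-peak, ms.
#' @param participant Participant identifiers.
#' @return Object of class `lme_comparison`: `models` (loglik, npar),
#'   `tests` (chisq, df, p), `singular` flags.
#' @export
lme_distance_models <- function(mep_uv, distance_ms, participant) {
  stopifnot(all(mep_uv > 0))
  # distance in seconds keeps the linear and quadratic columns on
  # comparable scales; likelihood-ratio tests are invariant to the unit
  df <- data.frame(y = log(mep_uv), d = distance_ms / 1000,
                   participant = factor(participant))
  df$d2 <- df$d^2
  single <- nlevels(df$participant) < 2
  if (single) {
    fits <- list(null = stats::lm(y ~ 1, df),
                 linear = stats::lm(y ~ d, df),
                 quadratic = stats::lm(y ~ d + d2, df))
    ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), 1)
    np <- vapply(fits, function(f) attr(stats::logLik(f), "df"), 1)
    singular <- c(FALSE, FALSE, FALSE)
  } else {
    fits <- list(
      null = lme4::lmer(y ~ 1 + (1 | participant), df, REML = FALSE),
      linear = lme4::lmer(y ~ d + (1 | participant), df, REML = FALSE),
      quadratic = lme4::lmer(y ~ d + d2 + (1 | participant), df, REML = FALSE))
    ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), 1)
    np <- vapply(fits, function(f) attr(stats::logLik(f), "df"), 1)
    singular <- vapply(fits, lme4::isSingular, logical(1))
  }
  chi <- c(linear_vs_null = 2 * (ll[2] - ll[1]),
           quadratic_vs_linear = 2 * (ll[3] - ll[2]))
  chi <- pmax(chi, 0)
  tests <- data.frame(chisq = chi, df = c(1, 1),
                      p = stats::pchisq(chi, 1, lower.tail = FALSE))
  structure(list(models = data.frame(loglik = ll, npar = np),
                 tests = tests, singular = singular, single = single),
            class = "lme_comparison")
}

#' @export
print.lme_comparison <- function(x, ...) {
  cat("<lme_comparison>\n")
  print(round(x$tests, 4))
  if (any(x$singular)) cat("  (singular fit flagged)\n")
  invisible(x)
}

#' A-priori sample size for a paired two-sided t test
#'
#' Solves the noncentral-t power equation
#' `P(|T| > t_crit; df = n - 1, ncp = d * sqrt(n)) = power` for a
#' continuous n (the standard a-priori calculation for a two-sided
#' one-sample test on paired differences) and rounds to the nearest
#' whole participant. Monotone nonincreasing in d and nondecreasing in
#' the power target.
#'
#' @param d Cohen's d (> 0).
#' @param power Target power.
#' @param alpha Two-sided alpha.
#' @return Integer sample size (>= 2).
#' @export
power_n_paired <- function(d, power = 0.8, alpha = 0.05) {
  if (d <= 0) stop("effect size d must be positive")
  if (power_paired_t(2, d, alpha) >= power) return(2L)
  root <- stats::uniroot(function(n) power_paired_t(n, d, alpha) - power,
                         c(2, 10), extendInt = "upX", tol = 1e-8)$root
  max(2L, as.integer(round(root)))
}

#' @rdname power_n_paired
#' @param n Sample size.
#' @return Achieved power for given `n` and `d`.
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  stats::pt(tc, n - 1, ncp, lower.tail = FALSE) + stats::pt(-tc, n - 1, ncp)
}

#' Paired Cohen's d
#'
#' `mean(diffs) / sd(diffs)` (n-1 denominator). A zero SD with nonzero
#' mean yields `Inf` with a degeneracy warning.
#'
#' @param diffs Paired differences (length >= 2).
#' @export
cohens_d_paired <- function(diffs) {
  if (length(diffs) < 2) stop("need at least 2 differences")
  s <- stats::sd(diffs)
  if (s == 0) {
    if (mean(diffs) == 0) return(0)
    warning("zero variance: effect size is infinite")
    return(Inf * sign(mean(diffs)))
  }
  mean(diffs) / s
}

#' Binned MEP profile across the cardiac cycle
#'
#' Mean MEP amplitude in fixed-width bins of distance from the preceding
#' R-peak.
#'
#' @param amplitudes MEP amplitudes.
#' @param distance_ms Distances from the preceding R-peak, ms.
#' @param width_ms Bin width.
#' @return data.frame: `bin_start_ms`, `bin_mid_ms`, `mean_amplitude`, `n`.
#' @export
binned_mep_profile <- function(amplitudes, distance_ms, width_ms = 50) {
  ok <- !is.na(distance_ms)
  b <- floor(distance_ms[ok] / width_ms)
  agg <- tapply(amplitudes[ok], b, mean)
  cnt <- tapply(amplitudes[ok], b, length)
  starts <- as.numeric(names(agg)) * width_ms
  data.frame(bin_start_ms = starts, bin_mid_ms = starts + width_ms / 2,
             mean_amplitude = as.numeric(agg), n = as.integer(cnt))
}
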