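# independent brute-force oracles used by the unit and acceptance suites

# clusters on a 1 x T grid are runs of suprathreshold samples; p values by
# exhaustive sign-flip enumeration (independent of the package's
# adjacency/BFS code path)
enum_cluster_oracle <- function(d) {
  n <- nrow(d)
  tcrit <- qt(0.975, n - 1)
  tfun <- function(m) apply(m, 2, function(v) {
    s <- sd(v); if (s == 0) 0 else mean(v) / (s / sqrt(n))
  })
  masses <- function(tv) {
    out <- numeric(0)
    for (sgn in c(1, -1)) {
      r <- rle(if (sgn > 0) tv > tcrit else tv < -tcrit)
      e <- cumsum(r$lengths); s <- e - r$lengths + 1
      for (i in which(r$values)) out <- c(out, sum(tv[s[i]:e[i]]))
    }
    out
  }
  obs <- masses(tfun(d))
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null <- apply(signs, 1, function(s) {
    m <- masses(tfun(d * s)); if (length(m)) max(abs(m)) else 0
  })
  list(masses = obs, p = vapply(obs, function(m) mean(null >= abs(m)), 1))
}

# exact two-sided signed-rank p by direct enumeration of all sign patterns
enum_wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
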