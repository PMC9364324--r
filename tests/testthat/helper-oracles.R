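# Independent oracles used across tests; deliberately naive implementations.

# element-wise BSAI sum, no matrix shortcuts
oracle_bsai <- function(E, S, A, B, V, nano) {
  nano$c + E * nano$r_e + S * nano$p_s + A * nano$a + B * nano$b + V * nano$v
}

# Bray-Curtis from the definition
oracle_bray <- function(u, v) sum(abs(u - v)) / sum(u + v)

# VIF via explicit regression of one column on the rest
oracle_vif <- function(df, col) {
  others <- setdiff(names(df), col)
  fml <- stats::as.formula(paste0("`", col, "` ~ ", paste0("`", others, "`", collapse = "+")))
  1 / (1 - summary(stats::lm(fml, data = df))$r.squared)
}

# hat diagonal via the textbook projection matrix
oracle_hat <- function(x) {
  diag(x %*% solve(crossprod(x)) %*% t(x))
}

# Dunn z statistics recomputed from rank sums, straight from the published
# procedure (tie-corrected pooled variance)
oracle_dunn <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  r <- rank(y)
  ties <- table(r)
  tc <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, g, mean)
  sz <- table(g)
  pairs <- utils::combn(levels(g), 2)
  apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tc) * (1 / sz[[pr[1]]] + 1 / sz[[pr[2]]]))
    (mr[[pr[1]]] - mr[[pr[2]]]) / se
  })
}

# Pearson r from the covariance definition
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# dense-grid trapezoid of exp(-beta w) for a piecewise-defined profile
oracle_boltzmann_integral <- function(wfun, lower, upper, temperature,
                                      n = 2e5) {
  beta <- 1 / (8.3144621e-3 * temperature)
  z <- seq(lower, upper, length.out = n)
  f <- exp(-beta * wfun(z))
  sum(diff(z) * (f[-n] + f[-1]) / 2)
}

# a small synthetic registry for batch prediction tests
toy_registry <- function(n = 3, seed = 11) {
  withr::with_seed(seed, tibble::tibble(
    enm_id = paste0("enm_", seq_len(n)),
    c = stats::rnorm(n), r_e = stats::rnorm(n), p_s = stats::rnorm(n),
    a = stats::rnorm(n), b = stats::rnorm(n), v = stats::rnorm(n)))
}
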