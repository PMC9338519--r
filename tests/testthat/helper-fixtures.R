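# Shared fixtures and independent oracles, all built in code.

# a null table: uniform p, independent Bernoulli covariate, k folds
make_null_table <- function(m, q_rate = 0.1, n_groups = 4, seed = 1) {
  set.seed(seed)
  data.frame(p = runif(m), q = rbinom(m, 1, q_rate),
             group = rep(seq_len(n_groups), length.out = m))
}

# Brute-force matched-threshold oracle, built from first principles on a
# dense grid: continuity-corrected stratum ECDFs, step ratio
# r_s(x) = x c_s / ecdf_s(x), monotone envelope by suffix minima over the
# grid, target = envelope of the observed stratum at p_i, answer = largest
# grid point whose opposite-stratum envelope is <= target.
oracle_region <- function(p_i, q_i, p_train, q_train, grid_n = 1e4) {
  hi <- p_train > 0.5
  null_q <- if (any(hi)) mean(q_train[hi]) else mean(q_train)
  marg <- mean(q_train)
  ratio <- function(x, s) {
    t <- p_train[q_train == s]
    ec <- (vapply(x, function(xx) sum(t <= xx), numeric(1)) + 1) /
      (length(t) + 1)
    cs <- if (s == 1) null_q / marg else (1 - null_q) / (1 - marg)
    x * cs / ec
  }
  grid <- sort(unique(c(seq(0, 1, length.out = grid_n), p_train, p_i)))
  env <- function(s) rev(cummin(rev(ratio(grid, s))))
  target <- env(q_i)[match(p_i, grid)]
  feasible <- grid[env(1 - q_i) <= target + 1e-12]
  pstar <- if (length(feasible)) max(feasible) else 0
  if (q_i == 0) c(p0 = p_i, p1 = pstar) else c(p0 = pstar, p1 = p_i)
}
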