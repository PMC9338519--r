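# Tests for the block-LD GWAS simulator.

small_cfg <- sim_config(n_blocks = 4, snps_per_block = 50)

test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(snps_per_block = 1001))
  expect_error(sim_config(ld_decay = 1))
  expect_error(sim_config(causal_min = 3, causal_max = 2))
})

test_that("LD blocks have AR(1) correlation, valid MAFs and positions", {
  blocks <- simulate_ld_blocks(small_cfg, seed = 1)
  expect_length(blocks, 4)
  b <- blocks[[2]]
  expect_equal(b$Sigma, 0.9^abs(outer(1:50, 1:50, "-")))
  expect_silent(chol(b$Sigma))  # positive definite
  expect_false(is.unsorted(b$positions, strictly = TRUE))
  expect_true(all(b$maf >= 0.05 & b$maf <= 0.5))
  # independence structure: zero decay gives the identity
  id <- simulate_ld_blocks(sim_config(n_blocks = 1, snps_per_block = 10,
                                      ld_decay = 0), seed = 1)
  expect_equal(id[[1]]$Sigma, diag(10))
  # determinism per seed
  expect_identical(simulate_ld_blocks(small_cfg, seed = 7),
                   simulate_ld_blocks(small_cfg, seed = 7))
})

test_that("causal sampling matches the 2-4 per block, N(0, 0.2^2) design", {
  cfg <- sim_config(n_blocks = 3000, snps_per_block = 10)
  blocks <- replicate(3000, list(NULL))  # only the count is used
  causal <- sample_causal_effects(blocks, cfg, seed = 2)
  k <- vapply(causal, function(x) length(x$causal), numeric(1))
  expect_true(all(k %in% 2:4))
  betas <- unlist(lapply(causal, function(x) x$beta[x$causal]))
  expect_gt(length(betas), 1e4 * 0.8)
  se_sd <- 0.2 / sqrt(2 * length(betas))
  expect_lt(abs(sd(betas) - 0.2), 3 * se_sd)
  # complete null switch
  null_c <- sample_causal_effects(blocks, sim_config(
    n_blocks = 3000, snps_per_block = 10, effect_sd = 0), seed = 3)
  expect_true(all(unlist(lapply(null_c, `[[`, "beta")) == 0))
  expect_error(sample_causal_effects(blocks, sim_config(
    n_blocks = 1, snps_per_block = 3), seed = 1))
})

test_that("null Z-scores are standard normal and null p-values uniform", {
  cfg <- sim_config(n_blocks = 25, snps_per_block = 400, effect_sd = 0)
  study <- simulate_study(cfg, seed = 4)
  expect_equal(nrow(study), 1e4)
  # thinned to ~independent SNPs (KS assumes independence; residual
  # cross-SNP correlation after thinning is 0.9^50)
  thin <- study[study$idx_in_block %% 50 == 1, ]
  expect_gt(stats::ks.test(thin$z, "pnorm")$p.value, 0.01)
  expect_gt(stats::ks.test(thin$p, "punif")$p.value, 0.01)
  expect_equal(study$p, 2 * pnorm(-abs(study$z)))
  # near-zero correlation across block boundaries
  z1 <- study$z[study$block == 1]
  z2 <- study$z[study$block == 2]
  expect_lt(abs(cor(z1, z2)), 3.5 / sqrt(400))
})

test_that("a single strong causal variant dominates its block's signal", {
  cfg <- sim_config(n_blocks = 1, snps_per_block = 100)
  blocks <- simulate_ld_blocks(cfg, seed = 5)
  causal <- list(list(causal = 40L,
                      beta = replace(numeric(100), 40, 5)))
  z <- simulate_z_scores(blocks, causal, cfg, seed = 6)
  expect_equal(which.max(abs(z)), 40)
})

test_that("the functional window is inclusive at exactly 10 kb", {
  pos <- c(1000, 11000, 11001, 500000)
  block <- rep(1, 4)
  causal <- c(TRUE, FALSE, FALSE, FALSE)
  mask <- functional_mask(pos, block, causal, window_bp = 10000)
  expect_identical(mask, c(TRUE, TRUE, FALSE, FALSE))
  # same distance across a block boundary does not count
  mask2 <- functional_mask(pos, c(1, 2, 2, 2), causal, window_bp = 10000)
  expect_identical(mask2, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("covariate scenarios hit their Bernoulli rates", {
  set.seed(7)
  m <- 1e5
  mask <- rbinom(m, 1, 0.3) == 1
  qa <- simulate_covariate("A", mask, n_cols = 1)
  expect_lt(abs(mean(qa) - 0.05), 3 * sqrt(0.05 * 0.95 / m))
  qb <- simulate_covariate("B", mask, n_cols = 1)
  nf <- sum(mask)
  expect_lt(abs(mean(qb[mask, ]) - 0.4), 3 * sqrt(0.4 * 0.6 / nf))
  expect_lt(abs(mean(qb[!mask, ]) - 0.05), 3 * sqrt(0.05 * 0.95 / (m - nf)))
  qc <- simulate_covariate("C", mask, n_cols = 1)
  expect_lt(abs(mean(qc[mask, ]) - 0.8), 3 * sqrt(0.8 * 0.2 / nf))
  expect_error(simulate_covariate("D", mask))
})

test_that("a shared mask correlates covariate columns; scenario A does
           not", {
  set.seed(8)
  m <- 5e4
  mask <- rbinom(m, 1, 0.3) == 1
  qc <- simulate_covariate("C", mask, n_cols = 4)
  cors <- cor(qc)[upper.tri(diag(4))]
  expect_true(all(cors > 0.1))
  qa <- simulate_covariate("A", mask, n_cols = 4)
  expect_true(all(abs(cor(qa)[upper.tri(diag(4))]) < 0.02))
})

test_that("simulated studies are deterministic per seed and internally
           consistent", {
  s1 <- simulate_study(small_cfg, seed = 9)
  s2 <- simulate_study(small_cfg, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$functional[s1$causal]))  # causal SNPs are functional
  expect_true(all(s1$p > 0 & s1$p <= 1))
})
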