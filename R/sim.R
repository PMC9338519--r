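# Synthetic GWAS summary statistics with block LD structure, and the three
# binary-covariate scenarios used in the evaluation harness.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic GWAS generator. Defaults describe
#' the study conditions used throughout the evaluation: a case-control GWAS
#' of 5000 cases and 5000 controls over 24 approximately independent LD
#' blocks of 400 common SNPs each, 2-4 causal variants per block with
#' log-odds-ratio effects drawn from the N(0, 0.2^2) fine-mapping prior,
#' AR(1) within-block LD with adjacent-SNP haplotype correlation 0.9, minor
#' allele frequencies uniform on \[0.05, 0.5\] and a mean inter-SNP spacing
#' of 450 bp (matching the density of ~80k common SNPs on chromosome 22).
#'
#' @param n_blocks Number of independent LD blocks.
#' @param snps_per_block SNPs per block (at most 1000).
#' @param n_cases,n_controls Case-control sample sizes.
#' @param causal_min,causal_max Range of causal variants per block.
#' @param effect_sd Standard deviation of causal log-OR effects.
#' @param ld_decay Adjacent-SNP haplotype correlation, in \[0, 1).
#' @param maf_range Range of minor allele frequencies.
#' @param snp_spacing_bp Mean inter-SNP distance in base pairs.
#' @param functional_window_bp Window around causal variants defining
#'   "functional" SNPs.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_blocks = 24L, snps_per_block = 400L,
                       n_cases = 5000L, n_controls = 5000L,
                       causal_min = 2L, causal_max = 4L,
                       effect_sd = 0.2, ld_decay = 0.9,
                       maf_range = c(0.05, 0.5), snp_spacing_bp = 450,
                       functional_window_bp = 10000) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              causal_min = as.integer(causal_min),
              causal_max = as.integer(causal_max),
              effect_sd = effect_sd, ld_decay = ld_decay,
              maf_range = maf_range, snp_spacing_bp = snp_spacing_bp,
              functional_window_bp = functional_window_bp)
  stopifnot(cfg$n_blocks >= 1L, cfg$snps_per_block >= 1L,
            cfg$snps_per_block <= 1000L,
            cfg$n_cases >= 1L, cfg$n_controls >= 1L,
            cfg$causal_min >= 1L, cfg$causal_max >= cfg$causal_min,
            cfg$effect_sd >= 0, cfg$ld_decay >= 0, cfg$ld_decay < 1,
            length(cfg$maf_range) == 2L, cfg$maf_range[1] > 0,
            cfg$maf_range[2] <= 0.5, cfg$snp_spacing_bp > 0,
            cfg$functional_window_bp >= 0)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Any field of [sim_config()] may be set in the file; the rest keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

ar1_corr <- function(n, rho) {
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' Simulate LD block structure
#'
#' Generates, for each block, SNP positions (cumulative exponential spacing,
#' 1-based, with large gaps between blocks), minor allele frequencies
#' (uniform over `maf_range`) and an AR(1) correlation matrix
#' `Sigma_ij = ld_decay^|i-j|`, which is symmetric positive definite for
#' `ld_decay` in \[0, 1). Blocks are mutually independent.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of blocks, each a list with `block`, `positions`, `maf`
#'   and `Sigma`.
#' @export
simulate_ld_blocks <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$snps_per_block
  Sigma <- ar1_corr(n, config$ld_decay)
  offset <- 0
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    gaps <- pmax(1, round(stats::rexp(n, rate = 1 / config$snp_spacing_bp)))
    pos <- offset + cumsum(gaps)
    offset <- pos[n] + 1e6  # inter-block gap far beyond any LD window
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    blocks[[b]] <- list(block = b, positions = pos, maf = maf, Sigma = Sigma)
  }
  blocks
}

#' Sample causal variants and effect sizes
#'
#' Per block, draws the number of causal variants uniformly from
#' `causal_min:causal_max`, picks their indices without replacement, and
#' assigns log-OR effects from `N(0, effect_sd^2)`; all other SNPs get
#' effect 0.
#'
#' @param blocks Output of [simulate_ld_blocks()].
#' @inheritParams simulate_ld_blocks
#' @return A list per block with `causal` (indices within the block) and
#'   `beta` (length `snps_per_block`).
#' @export
sample_causal_effects <- function(blocks, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$snps_per_block
  if (n < config$causal_max)
    stop("blocks of ", n, " SNPs cannot host ", config$causal_max,
         " causal variants", call. = FALSE)
  lapply(blocks, function(bl) {
    k <- sample(config$causal_min:config$causal_max, 1L)
    causal <- sort(sample.int(n, k))
    beta <- numeric(n)
    beta[causal] <- stats::rnorm(k, 0, config$effect_sd)
    list(causal = causal, beta = beta)
  })
}

#' Simulate GWAS Z-scores
#'
#' One multivariate normal draw per block, independent across blocks:
#' `Z ~ MVN(Sigma %*% lambda, Sigma)` with the standard non-centrality
#' `lambda_j = beta_j * sqrt(2 maf_j (1 - maf_j)) * sqrt(n_eff)` and
#' `n_eff = n_cases * n_controls / (n_cases + n_controls)`, so that under
#' the complete null every Z-score is marginally standard normal.
#'
#' @inheritParams sample_causal_effects
#' @param causal Output of [sample_causal_effects()].
#' @return Numeric vector of Z-scores (blocks concatenated in order).
#' @export
simulate_z_scores <- function(blocks, causal, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_eff <- config$n_cases * config$n_controls /
    (config$n_cases + config$n_controls)
  R <- chol(blocks[[1L]]$Sigma)  # shared across equal-size AR(1) blocks
  unlist(lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    lambda <- causal[[b]]$beta * sqrt(2 * bl$maf * (1 - bl$maf)) *
      sqrt(n_eff)
    mu <- if (all(lambda == 0)) numeric(length(lambda))
          else drop(bl$Sigma %*% lambda)
    mu + drop(crossprod(R, stats::rnorm(nrow(R))))
  }), use.names = FALSE)
}

#' Functional SNP mask
#'
#' Marks a SNP as functional if it is a causal variant or lies within
#' `window_bp` base pairs (inclusive) of a causal variant in the same
#' block.
#'
#' @param positions Base-pair positions (sorted within block).
#' @param block Block identifier per SNP.
#' @param causal Logical vector marking causal SNPs.
#' @param window_bp Window size in base pairs.
#' @return Logical mask, `TRUE` for functional SNPs.
#' @export
functional_mask <- function(positions, block, causal, window_bp = 10000) {
  stopifnot(length(positions) == length(block),
            length(causal) == length(positions))
  mask <- logical(length(positions))
  for (b in unique(block)) {
    i <- which(block == b)
    cpos <- positions[i][causal[i]]
    if (!length(cpos)) next
    d <- vapply(positions[i], function(x) min(abs(x - cpos)), numeric(1))
    mask[i] <- d <= window_bp
  }
  mask
}

#' Simulate binary covariates for scenarios A, B and C
#'
#' Scenario A draws covariates independently of everything,
#' `q ~ Bernoulli(0.05)`. Scenarios B and C draw
#' `q ~ Bernoulli(rate_functional)` for functional SNPs (rate 0.4 for B,
#' 0.8 for C) and `Bernoulli(0.05)` otherwise. Columns are drawn
#' independently given the mask; when the same mask is reused for several
#' columns (the default, and the design of scenario C's repeated
#' functional mark) the columns are positively correlated through it. A
#' matrix `mask` with one column per covariate expresses fresh-mask
#' designs instead.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param mask Logical functional mask (vector, or matrix with `n_cols`
#'   columns). Required for scenarios B and C; for scenario A only its row
#'   count is used.
#' @param n_cols Number of covariate columns (one per planned iteration).
#' @param seed Optional integer seed.
#' @return Integer 0/1 matrix with `n_cols` columns.
#' @export
simulate_covariate <- function(scenario, mask, n_cols = 1L, seed = NULL) {
  scenario <- match.arg(toupper(scenario), c("A", "B", "C"))
  if (!is.null(seed)) set.seed(seed)
  mask <- as.matrix(mask)
  m <- nrow(mask)
  if (!ncol(mask) %in% c(1L, n_cols))
    stop("'mask' must have 1 or n_cols columns", call. = FALSE)
  rate_fun <- switch(scenario, A = 0.05, B = 0.4, C = 0.8)
  q <- matrix(0L, m, n_cols)
  for (k in seq_len(n_cols)) {
    mk <- mask[, min(k, ncol(mask))]
    rates <- if (scenario == "A") rep(0.05, m)
             else ifelse(mk, rate_fun, 0.05)
    q[, k] <- stats::rbinom(m, 1L, rates)
  }
  q
}

#' Simulate one GWAS study
#'
#' Orchestrates the generator: LD blocks, causal variants and effects,
#' Z-scores, two-sided p-values `p = 2 * pnorm(-|Z|)` and the functional
#' mask. The result is the per-SNP table consumed by [binary_cfdr()] and
#' [truth_labels()].
#'
#' @inheritParams simulate_ld_blocks
#' @return An object of class `"sim_study"`: a data.frame with columns
#'   `snp`, `block`, `pos`, `maf`, `beta`, `causal`, `z`, `p`,
#'   `functional`, carrying the configuration as attribute `config`.
#' @examples
#' study <- simulate_study(sim_config(n_blocks = 2, snps_per_block = 50),
#'                         seed = 1)
#' head(study)
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- simulate_ld_blocks(config)
  causal <- sample_causal_effects(blocks, config)
  z <- simulate_z_scores(blocks, causal, config)
  n <- config$snps_per_block
  block_id <- rep(seq_len(config$n_blocks), each = n)
  causal_flag <- unlist(lapply(causal, function(x)
    seq_len(n) %in% x$causal), use.names = FALSE)
  study <- data.frame(
    snp = paste0("snp", seq_along(z)),
    block = block_id,
    idx_in_block = rep(seq_len(n), config$n_blocks),
    pos = unlist(lapply(blocks, `[[`, "positions"), use.names = FALSE),
    maf = unlist(lapply(blocks, `[[`, "maf"), use.names = FALSE),
    beta = unlist(lapply(causal, `[[`, "beta"), use.names = FALSE),
    causal = causal_flag,
    z = z,
    p = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  )
  study$functional <- functional_mask(study$pos, study$block, study$causal,
                                      config$functional_window_bp)
  attr(study, "config") <- config
  class(study) <- c("sim_study", "data.frame")
  study
}
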