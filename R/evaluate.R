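# Evaluation harness: r^2-based truth labels, sensitivity/specificity
# proxies, empirical false discovery proportions, and multi-iteration
# scenario summaries.

#' r^2-based truth labels for a simulated study
#'
#' Labels each SNP by its maximum haplotype r^2 with any causal variant:
#' `associated` if max r^2 >= 0.8, `not_associated` if max r^2 <= 0.01 with
#' every causal variant, and `neither` otherwise. Under the AR(1) block
#' model, r^2 between SNPs i and j of the same block is
#' `ld_decay^(2 |i - j|)` and exactly 0 across blocks, so causal variants
#' are always `associated` (r^2 = 1 with themselves).
#'
#' @param study A [simulate_study()] result.
#' @param r2_assoc,r2_null Label thresholds.
#' @return A factor with levels `associated`, `not_associated`, `neither`,
#'   with the per-SNP maximum r^2 attached as attribute `max_r2`.
#' @export
truth_labels <- function(study, r2_assoc = 0.8, r2_null = 0.01) {
  config <- attr(study, "config")
  rho2 <- config$ld_decay^2
  max_r2 <- numeric(nrow(study))
  for (b in unique(study$block)) {
    i <- which(study$block == b)
    cidx <- study$idx_in_block[i][study$causal[i]]
    if (!length(cidx)) { max_r2[i] <- 0; next }
    max_r2[i] <- vapply(study$idx_in_block[i],
                        function(j) rho2^min(abs(j - cidx)), numeric(1))
  }
  lab <- ifelse(max_r2 >= r2_assoc, "associated",
                ifelse(max_r2 <= r2_null, "not_associated", "neither"))
  lab <- factor(lab, levels = c("associated", "not_associated", "neither"))
  attr(lab, "max_r2") <- max_r2
  lab
}

#' Sensitivity and specificity proxies
#'
#' At FDR threshold `alpha` (default 5e-6, roughly matching the genome-wide
#' significance p-value threshold of 5e-8), the sensitivity proxy is the
#' proportion of truly associated SNPs called significant and the
#' specificity proxy is the proportion of truly not-associated SNPs called
#' not significant. SNPs labelled `neither` enter neither proxy. A proxy
#' whose reference class is empty is returned as `NA`.
#'
#' @param fdr_values Per-SNP FDR-adjusted values.
#' @param labels Output of [truth_labels()].
#' @param alpha Significance threshold on the FDR values.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sensitivity_specificity <- function(fdr_values, labels, alpha = 5e-6) {
  stopifnot(length(fdr_values) == length(labels))
  sig <- fdr_values <= alpha
  assoc <- labels == "associated"
  nulls <- labels == "not_associated"
  c(sensitivity = if (any(assoc)) mean(sig[assoc]) else NA_real_,
    specificity = if (any(nulls)) mean(!sig[nulls]) else NA_real_)
}

#' Empirical false discovery proportion
#'
#' The proportion of SNPs called significant at FDR threshold `alpha` that
#' are truly not-associated (max r^2 <= 0.01 with every causal variant).
#' Returns 0 when nothing is called significant.
#'
#' @inheritParams sensitivity_specificity
#' @param alpha Rejection threshold on the FDR values (default 0.05).
#' @return A number in \[0, 1\].
#' @export
empirical_fdr <- function(fdr_values, labels, alpha = 0.05) {
  stopifnot(length(fdr_values) == length(labels))
  sig <- fdr_values <= alpha
  sum(sig & labels == "not_associated") / max(1L, sum(sig))
}

#' Run a full simulation scenario
#'
#' For each replicate: simulates a study, draws `n_iterations` covariate
#' columns for the requested scenario, applies [iterate_cfdr()], and
#' evaluates sensitivity, specificity and the empirical false discovery
#' proportion at iterations 0 (BH-adjusted raw p-values) through
#' `n_iterations` (BH-adjusted v-values). Results are averaged across
#' replicates with standard errors `sd / sqrt(n_replicates)`.
#'
#' @param scenario `"A"`, `"B"` or `"C"` (see [simulate_covariate()]).
#' @param n_replicates Number of independent replicates.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (single seed for the whole run).
#' @param n_iterations Number of cFDR iterations (covariate columns).
#' @param alpha_sig FDR threshold for the sensitivity/specificity proxies.
#' @param alpha_fdr FDR threshold for the empirical FDR.
#' @return An object of class `"scenario_summary"`: a long-format
#'   data.frame with columns `scenario`, `iteration`, `metric`, `mean`,
#'   `se`, carrying the per-replicate metric array as attribute
#'   `replicates`.
#' @export
run_scenario <- function(scenario, n_replicates = 50L,
                         config = sim_config(), seed = NULL,
                         n_iterations = 5L, alpha_sig = 5e-6,
                         alpha_fdr = 0.05) {
  scenario <- match.arg(toupper(scenario), c("A", "B", "C"))
  if (!is.null(seed)) set.seed(seed)
  metrics <- c("sensitivity", "specificity", "fdr")
  res <- array(NA_real_,
               dim = c(n_replicates, n_iterations + 1L, length(metrics)),
               dimnames = list(NULL, paste0("iter", 0:n_iterations),
                               metrics))
  for (r in seq_len(n_replicates)) {
    study <- simulate_study(config)
    labels <- truth_labels(study)
    q <- simulate_covariate(scenario, study$functional, n_iterations)
    fit <- iterate_cfdr(study$p, q, study$block)
    for (k in 0:n_iterations) {
      fdr_k <- if (k == 0L) fit$fdr0 else fit$fdr[, k]
      ss <- sensitivity_specificity(fdr_k, labels, alpha_sig)
      res[r, k + 1L, "sensitivity"] <- ss[["sensitivity"]]
      res[r, k + 1L, "specificity"] <- ss[["specificity"]]
      res[r, k + 1L, "fdr"] <- empirical_fdr(fdr_k, labels, alpha_fdr)
    }
  }
  out <- expand.grid(iteration = 0:n_iterations, metric = metrics,
                     stringsAsFactors = FALSE)
  out$scenario <- scenario
  out$mean <- mapply(function(k, m) mean(res[, k + 1L, m], na.rm = TRUE),
                     out$iteration, out$metric)
  out$se <- mapply(function(k, m) {
    x <- res[, k + 1L, m]
    stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  }, out$iteration, out$metric)
  out <- out[, c("scenario", "iteration", "metric", "mean", "se")]
  attr(out, "replicates") <- res
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("Scenario", x$scenario[1], "summary over",
      dim(attr(x, "replicates"))[1], "replicates\n\n")
  wide <- stats::reshape(as.data.frame(x)[, -1], idvar = "iteration",
                         timevar = "metric", direction = "wide")
  print(format(wide, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot a scenario summary
#'
#' Three panels (sensitivity, specificity, empirical FDR) against
#' iteration, with mean +/- one standard-error bars; the FDR panel marks
#' the nominal 0.05 level.
#'
#' @param x A `"scenario_summary"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scenario_summary <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in c("sensitivity", "specificity", "fdr")) {
    d <- x[x$metric == m, ]
    ylim <- range(c(d$mean - d$se, d$mean + d$se,
                    if (m == "fdr") 0.05), na.rm = TRUE)
    graphics::plot(d$iteration, d$mean, type = "b", pch = 19, ylim = ylim,
                   xlab = "iteration", ylab = m,
                   main = paste0("Scenario ", x$scenario[1]), ...)
    graphics::arrows(d$iteration, d$mean - d$se, d$iteration, d$mean + d$se,
                     angle = 90, code = 3, length = 0.03)
    if (m == "fdr") graphics::abline(h = 0.05, lty = 2, col = "red")
  }
  invisible(x)
}
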