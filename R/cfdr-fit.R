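# User-facing binary cFDR fits: leave-one-group-out v-values and the
# iterative multi-covariate wrapper.

resolve_table <- function(p, q, group) {
  if (is.data.frame(p)) {
    need <- c("p", "q", "group")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop("data.frame input must contain columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    list(p = p$p, q = p$q, group = p$group,
         snp = if ("snp" %in% names(p)) as.character(p$snp) else NULL)
  } else {
    list(p = p, q = q, group = group, snp = NULL)
  }
}

#' Binary cFDR: transform (p, q) pairs into v-values
#'
#' Computes, for every SNP, a v-value that folds a binary covariate `q`
#' (e.g. overlap with regulatory regions) into the GWAS p-value `p`. The
#' v-value is the null probability mass of the SNP's rejection region
#' `L(p0, p1)` whose two thresholds equalise the estimated null/overall
#' density ratio across the two covariate strata; it is uniformly
#' distributed under the null and can be treated exactly like a p-value.
#'
#' Estimation uses leave-one-group-out fold removal: for each level of
#' `group` (typically chromosome or LD block), stratum ECDFs and the null
#' covariate rate are fitted on all *other* groups, so that rejection rules
#' are never derived from the SNPs they are applied to. If the covariate is
#' constant (globally, or within a training fold, or because a training
#' stratum is empty) it carries no information and the affected SNPs keep
#' `v = p` exactly.
#'
#' @param p Numeric vector of p-values in (0, 1], or a data.frame with
#'   columns `p`, `q`, `group` (and optionally `snp`).
#' @param q Integer/logical vector of binary covariate values (0/1).
#' @param group Fold labels (at least 2 distinct values); coerced to
#'   character.
#' @param allow_p_clamp If `TRUE`, p-values of exactly 0 are clamped to the
#'   smallest positive double instead of raising an error.
#' @param verbose If `TRUE`, per-fold stratum counts and null covariate
#'   rates are reported on the message stream.
#' @return An object of class `"bin_cfdr"`: a list with the input data,
#'   per-SNP `v` (v-values), `fdr` (Benjamini-Hochberg adjusted v-values),
#'   the per-SNP rejection-region thresholds `p0`, `p1`, the per-SNP applied
#'   `null_q`, and the per-fold null rates `fold_null_q`. All vectors are in
#'   input order; the computation is deterministic.
#' @seealso [iterate_cfdr()] for several covariates, [bh_adjust()],
#'   [solve_matched_threshold()].
#' @examples
#' set.seed(1)
#' m <- 2000
#' p <- runif(m); q <- rbinom(m, 1, 0.1); g <- rep(1:4, each = m / 4)
#' fit <- binary_cfdr(p, q, g)
#' head(fit$v)
#' @export
binary_cfdr <- function(p, q = NULL, group = NULL, allow_p_clamp = FALSE,
                        verbose = FALSE) {
  cl <- match.call()
  tab <- resolve_table(p, q, group)
  p <- validate_p(tab$p, allow_p_clamp)
  q <- validate_q(tab$q)
  group <- tab$group
  if (is.null(group) || length(group) != length(p))
    stop("'group' must be supplied and match the length of 'p'",
         call. = FALSE)
  if (length(q) != length(p))
    stop("'q' must match the length of 'p'", call. = FALSE)
  if (anyNA(group))
    stop("missing group labels in rows: ", format_rows(which(is.na(group))),
         call. = FALSE)
  group <- as.character(group)
  groups <- unique(group)
  if (length(groups) < 2L)
    stop("at least 2 distinct groups are required for leave-one-group-out ",
         "estimation", call. = FALSE)

  m <- length(p)
  v <- p0v <- p1v <- nullq <- numeric(m)
  fold_null_q <- stats::setNames(rep(NA_real_, length(groups)), groups)

  for (g in groups) {
    test <- group == g
    model <- fit_stratum_model(p[!test], q[!test])
    fold_null_q[[g]] <- model$null_q
    nullq[test] <- model$null_q
    if (verbose)
      message(sprintf(
        "fold %s: train m0 = %d, m1 = %d, Pr(Q=1) = %.4f, Pr(Q=1|H0) = %.4f",
        g, model$m0, model$m1, model$marginal_q, model$null_q))
    if (!model$stratum0$present || !model$stratum1$present) {
      # covariate uninformative for this fold
      p0v[test] <- p1v[test] <- p[test]
      v[test] <- p[test]
      next
    }
    for (s in 0:1) {
      idx <- which(test & q == s)
      if (!length(idx)) next
      reg <- solve_matched_threshold(p[idx], s, model)
      p0v[idx] <- reg$p0
      p1v[idx] <- reg$p1
    }
    ti <- which(test)
    v[ti] <- v_value(p0v[ti], p1v[ti], model$null_q)
  }

  structure(list(call = cl, m = m, snp = tab$snp, p = p, q = q,
                 group = group, v = v, fdr = bh_adjust(v),
                 p0 = p0v, p1 = p1v, null_q = nullq,
                 fold_null_q = fold_null_q),
            class = "bin_cfdr")
}

#' Iterative binary cFDR over several covariates
#'
#' Applies [binary_cfdr()] once per covariate column, feeding each
#' iteration's v-values in as the next iteration's p-values (iteration 1
#' consumes the input p-values). The full per-iteration trace is kept so
#' that the behaviour of the procedure can be inspected iteration by
#' iteration.
#'
#' @inheritParams binary_cfdr
#' @param covariates A 0/1 matrix (one column per covariate, consumed in
#'   column order), or a list of 0/1 vectors, each of length `length(p)`.
#' @return An object of class `"bin_cfdr_iter"`: a list with the input
#'   `p`, `group` and covariate matrix `q`, the list of per-iteration
#'   `"bin_cfdr"` fits, matrices `v` and `fdr` (one column per iteration),
#'   and `fdr0 = bh_adjust(p)`, the iteration-0 FDR values.
#' @export
iterate_cfdr <- function(p, covariates, group, allow_p_clamp = FALSE,
                         verbose = FALSE) {
  cl <- match.call()
  if (is.list(covariates) && !is.data.frame(covariates))
    covariates <- do.call(cbind, covariates)
  covariates <- as.matrix(covariates)
  if (ncol(covariates) < 1L)
    stop("at least one covariate column is required", call. = FALSE)
  if (nrow(covariates) != length(p))
    stop("covariate length (", nrow(covariates),
         ") does not match length of 'p' (", length(p), ")", call. = FALSE)
  p <- validate_p(p, allow_p_clamp)

  n_iter <- ncol(covariates)
  fits <- vector("list", n_iter)
  vmat <- fdrmat <- matrix(NA_real_, length(p), n_iter)
  cur <- p
  for (k in seq_len(n_iter)) {
    if (verbose) message("iteration ", k)
    fits[[k]] <- binary_cfdr(cur, covariates[, k], group, verbose = verbose)
    cur <- fits[[k]]$v
    vmat[, k] <- cur
    fdrmat[, k] <- fits[[k]]$fdr
  }
  colnames(vmat) <- paste0("v_iter", seq_len(n_iter))
  colnames(fdrmat) <- paste0("fdr_iter", seq_len(n_iter))
  structure(list(call = cl, p = p, group = group, q = covariates,
                 fits = fits, v = vmat, fdr = fdrmat,
                 fdr0 = bh_adjust(p)),
            class = "bin_cfdr_iter")
}

# -- methods ---------------------------------------------------------------

#' @export
print.bin_cfdr <- function(x, ...) {
  cat("Binary cFDR fit\n")
  cat(sprintf("  SNPs: %d  groups: %d  covariate-positive: %d (%.1f%%)\n",
              x$m, length(x$fold_null_q), sum(x$q), 100 * mean(x$q)))
  cat(sprintf("  null covariate rate, across folds: %.4f to %.4f\n",
              min(x$fold_null_q), max(x$fold_null_q)))
  cat(sprintf("  FDR < 0.05: %d SNPs (before leveraging: %d)\n",
              sum(x$fdr < 0.05), sum(bh_adjust(x$p) < 0.05)))
  invisible(x)
}

#' @export
summary.bin_cfdr <- function(object, alpha = 0.05, ...) {
  out <- list(m = object$m, fold_null_q = object$fold_null_q, alpha = alpha,
              n_sig_before = sum(bh_adjust(object$p) < alpha),
              n_sig_after = sum(object$fdr < alpha),
              v_quantiles = stats::quantile(object$v,
                                            c(0, .01, .25, .5, .75, 1)))
  class(out) <- "summary.bin_cfdr"
  out
}

#' @export
print.summary.bin_cfdr <- function(x, ...) {
  cat("Binary cFDR fit of", x$m, "SNPs\n\n")
  cat("Per-fold null covariate rate Pr(Q = 1 | H0):\n")
  print(round(x$fold_null_q, 4))
  cat("\nv-value quantiles:\n")
  print(signif(x$v_quantiles, 4))
  cat(sprintf("\nSNPs with FDR < %g: %d (raw p: %d)\n",
              x$alpha, x$n_sig_after, x$n_sig_before))
  invisible(x)
}

#' @export
as.data.frame.bin_cfdr <- function(x, ...) {
  d <- data.frame(p = x$p, q = x$q, group = x$group, v = x$v, fdr = x$fdr)
  if (!is.null(x$snp)) d <- cbind(snp = x$snp, d)
  d
}

#' @export
plot.bin_cfdr <- function(x, ...) {
  lim <- range(-log10(x$p), -log10(x$v))
  graphics::plot(-log10(x$p), -log10(x$v),
                 col = ifelse(x$q == 1, "#d95f02", "#7570b3"),
                 pch = 20, cex = 0.5, xlim = lim, ylim = lim,
                 xlab = expression(-log[10](p)),
                 ylab = expression(-log[10](v)), ...)
  graphics::abline(0, 1, col = "grey60")
  graphics::legend("topleft", pch = 20, col = c("#7570b3", "#d95f02"),
                   legend = c("q = 0", "q = 1"), bty = "n")
  invisible(x)
}

#' @export
print.bin_cfdr_iter <- function(x, ...) {
  cat("Iterative binary cFDR:", ncol(x$v), "iterations,", length(x$p),
      "SNPs\n")
  sig <- c(sum(x$fdr0 < 0.05), colSums(x$fdr < 0.05))
  names(sig) <- paste0("iter", 0:ncol(x$v))
  cat("SNPs with FDR < 0.05 per iteration:\n")
  print(sig)
  invisible(x)
}

#' @export
as.data.frame.bin_cfdr_iter <- function(x, ...) {
  q <- x$q
  colnames(q) <- paste0("q_iter", seq_len(ncol(q)))
  data.frame(p = x$p, group = x$group, q, x$v, x$fdr)
}

#' @export
plot.bin_cfdr_iter <- function(x, ...) {
  k <- ncol(x$v)
  lim <- range(-log10(x$p), -log10(x$v))
  graphics::plot(-log10(x$p), -log10(x$v[, k]), pch = 20, cex = 0.5,
                 xlim = lim, ylim = lim,
                 xlab = expression(-log[10](p)),
                 ylab = bquote(-log[10](v) ~ "after" ~ .(k) ~ "iterations"),
                 ...)
  graphics::abline(0, 1, col = "grey60")
  invisible(x)
}
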