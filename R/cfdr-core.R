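# Core binary cFDR machinery: per-stratum ECDF models, matched rejection
# thresholds and the v-value transformation.

# -- validation helpers ----------------------------------------------------

format_rows <- function(i, max_show = 5L) {
  shown <- paste(utils::head(i, max_show), collapse = ", ")
  if (length(i) > max_show)
    shown <- paste0(shown, ", ... (", length(i), " rows in total)")
  shown
}

validate_p <- function(p, allow_p_clamp = FALSE) {
  if (!is.numeric(p))
    stop("'p' must be a numeric vector", call. = FALSE)
  zero <- which(p == 0)
  if (length(zero)) {
    if (!allow_p_clamp)
      stop("p-values equal to 0 in rows: ", format_rows(zero),
           " (set allow_p_clamp = TRUE to clamp them to the smallest",
           " positive value)", call. = FALSE)
    p[zero] <- .Machine$double.xmin
  }
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad))
    stop("p-values outside (0, 1] in rows: ", format_rows(bad), call. = FALSE)
  p
}

validate_q <- function(q) {
  if (is.logical(q)) q <- as.integer(q)
  if (!is.numeric(q))
    stop("'q' must be a numeric, integer or logical vector", call. = FALSE)
  bad <- which(is.na(q) | !(q == 0 | q == 1))
  if (length(bad))
    stop("covariate values not in {0, 1} in rows: ", format_rows(bad),
         call. = FALSE)
  as.integer(q)
}

# -- null covariate rate ---------------------------------------------------

#' Estimate the null covariate rate Pr(Q = 1 | H0)
#'
#' Estimates the probability that the binary covariate equals 1 for a SNP at
#' which the null hypothesis of no association holds. Because p-values are
#' uniform under the null and associations are rare in GWAS, the region
#' `p > 1/2` is strongly null-enriched: the estimator is the fraction of
#' covariate-positive SNPs among training SNPs with `p > 1/2`. If no training
#' SNP has `p > 1/2` the overall covariate-positive fraction is returned.
#'
#' @param p Numeric vector of training p-values in (0, 1].
#' @param q Integer (0/1) vector of training covariate values, same length.
#' @return A single number in \[0, 1\].
#' @examples
#' estimate_null_covariate_rate(c(0.6, 0.7, 0.8, 0.9, 0.1), c(0, 1, 0, 1, 1))
#' @export
estimate_null_covariate_rate <- function(p, q) {
  if (length(p) != length(q))
    stop("'p' and 'q' must have the same length", call. = FALSE)
  if (length(p) == 0L)
    stop("empty training fold: cannot estimate the null covariate rate",
         call. = FALSE)
  hi <- p > 0.5
  if (any(hi)) mean(q[hi]) else mean(q)
}

# -- per-stratum ECDF model ------------------------------------------------

#' Fit the two-stratum ECDF model used by binary cFDR
#'
#' For each covariate stratum `q = 0` and `q = 1`, stores a
#' continuity-corrected empirical CDF of the training p-values,
#' `ecdf_q(p) = (#\{p_j <= p in stratum q\} + 1) / (m_q + 1)`,
#' together with the marginal covariate frequency and the estimated null
#' covariate rate (see [estimate_null_covariate_rate()]). The correction
#' keeps every CDF value strictly positive so that density ratios are finite
#' even below the smallest training p-value; it also absorbs the fact that a
#' held-out SNP is never part of its own training fold.
#'
#' @inheritParams estimate_null_covariate_rate
#' @return An object of class `"stratum_model"`: a list with per-stratum
#'   components (sorted knots, stratum size) plus `m0`, `m1`, `marginal_q`
#'   and `null_q`.
#' @export
fit_stratum_model <- function(p, q) {
  if (length(p) != length(q))
    stop("'p' and 'q' must have the same length", call. = FALSE)
  if (length(p) == 0L)
    stop("empty training fold: cannot fit a stratum model", call. = FALSE)
  strata <- lapply(0:1, function(s) {
    t <- sort(p[q == s])
    m <- length(t)
    if (m == 0L)
      return(list(m = 0L, present = FALSE))
    # e[k + 1] = (k + 1)/(m + 1) is the corrected ECDF on segment
    # [t_k, t_{k+1}); base_rho[k + 1] = t_k / e_k is the step-ratio value
    # (divided by the stratum constant) just right of knot t_k (t_0 = 0).
    e <- seq_len(m + 1L) / (m + 1L)
    base_rho <- c(0, t) / e
    base_mono <- rev(cummin(rev(base_rho)))
    list(m = m, present = TRUE, t = t, e = e,
         base_rho = base_rho, base_mono = base_mono)
  })
  m0 <- strata[[1L]]$m
  m1 <- strata[[2L]]$m
  structure(list(stratum0 = strata[[1L]], stratum1 = strata[[2L]],
                 m0 = m0, m1 = m1,
                 marginal_q = m1 / (m0 + m1),
                 null_q = estimate_null_covariate_rate(p, q)),
            class = "stratum_model")
}

#' @export
print.stratum_model <- function(x, ...) {
  cat("Binary cFDR stratum model\n")
  cat(sprintf("  training SNPs: %d (q = 0: %d, q = 1: %d)\n",
              x$m0 + x$m1, x$m0, x$m1))
  cat(sprintf("  Pr(Q = 1) = %.4f,  Pr(Q = 1 | H0) = %.4f\n",
              x$marginal_q, x$null_q))
  invisible(x)
}

get_stratum <- function(model, stratum) {
  if (!(length(stratum) == 1L && stratum %in% c(0, 1)))
    stop("'stratum' must be 0 or 1", call. = FALSE)
  if (stratum == 0) model$stratum0 else model$stratum1
}

null_rate <- function(model, stratum) {
  if (stratum == 1) model$null_q else 1 - model$null_q
}

marginal_rate <- function(model, stratum) {
  if (stratum == 1) model$marginal_q else 1 - model$marginal_q
}

# stratum constant c_s = Pr(Q = s | H0) / Pr(Q = s)
stratum_const <- function(model, stratum) {
  null_rate(model, stratum) / marginal_rate(model, stratum)
}

ecdf_value <- function(st, x) {
  (findInterval(x, st$t) + 1) / (st$m + 1)
}

#' Estimated cFDR density ratio for one stratum
#'
#' Evaluates the conservative cFDR estimate
#' `p * Pr(Q = s | H0) / (ecdf_s(p) * Pr(Q = s))`
#' at p-value `p` in covariate stratum `s`, using a fitted
#' [fit_stratum_model()]. The numerator uses the uniform-null approximation
#' `Pr(P <= p | H0, Q = s) ~ p`; the denominator uses the stratum ECDF. The
#' result estimates the ratio of the null to the overall (p, q) density mass
#' below `p` in that stratum.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param stratum 0 or 1.
#' @param model A `"stratum_model"`.
#' @return Positive finite numeric vector, same length as `p`.
#' @export
cfdr_ratio <- function(p, stratum, model) {
  p <- validate_p(p)
  st <- get_stratum(model, stratum)
  if (!st$present)
    stop("stratum ", stratum, " is empty in the training fold; ",
         "the covariate is uninformative there (degenerate path: v = p)",
         call. = FALSE)
  p * stratum_const(model, stratum) / (ecdf_value(st, p) * 1)
}

# Monotone envelope (greatest nondecreasing minorant) of the step ratio
# r_s(x) = x * c_s / ecdf_s(x): within a flat ECDF segment r is linear
# increasing, and it drops at each knot, so
#   env(x) = min( r(x), min over knots t_j > x of r(t_j) ).
envelope_ratio <- function(model, stratum, x) {
  st <- get_stratum(model, stratum)
  cs <- stratum_const(model, stratum)
  if (cs == 0) return(numeric(length(x)))    # stratum carries no null mass
  k <- findInterval(x, st$t)                 # segment index, 0..m
  raw <- x * cs / st$e[k + 1L]
  tail_min <- c(st$base_mono, Inf)[k + 2L] * cs
  pmin(raw, tail_min)
}

# Largest x in [0, 1] whose envelope ratio in `stratum` is <= target.
# Exact inversion: segment k is feasible iff its left-knot ratio
# rho_k = c * t_k / e_k is <= target; among feasible segments the achievable
# supremum min(t_{k+1}, target * e_k / c) is nondecreasing in k, so the
# answer lives in the LARGEST feasible segment, found by searching the
# (nondecreasing) suffix minima of rho.
invert_envelope <- function(model, stratum, target) {
  st <- get_stratum(model, stratum)
  cs <- stratum_const(model, stratum)
  if (cs == 0) {
    # this stratum carries no null mass: the ratio is identically 0, every
    # threshold is admissible and Eq-17 weight of this coordinate is 0
    return(rep(1, length(target)))
  }
  mono <- st$base_mono * cs
  K <- findInterval(target, mono)            # in 1..(m + 1); mono[1] = 0
  t_next <- c(st$t, 1)[K]                    # right end of segment K - 1
  pstar <- pmin(t_next, target * st$e[K] / cs)
  pmin(pmax(pstar, 0), 1)
}

#' Solve the matched-threshold equation for one SNP
#'
#' Given an observed pair `(p, q)` and a fitted [fit_stratum_model()],
#' returns the rejection region `L(p0, p1) = (P <= p0, Q = 0) union
#' (P <= p1, Q = 1)`. The coordinate of the observed stratum is fixed at
#' `p`, and the other coordinate is the largest value whose estimated
#' density ratio in the opposite stratum does not exceed the observed
#' stratum's ratio at `p`. Both ratios are evaluated through the monotone
#' envelope (greatest nondecreasing minorant) of the step-function estimate,
#' which keeps the mapping p -> region nondecreasing; on flats the largest
#' admissible threshold is returned, which can only enlarge the region (and
#' hence the v-value), a conservative choice. If no threshold achieves the
#' target the coordinate is clamped to 0; if even the threshold 1 is
#' admissible it is clamped to 1. If either stratum is absent from the
#' training fold the covariate is uninformative and the degenerate region
#' `p0 = p1 = p` is returned, so that the v-value reduces to `p`.
#'
#' @param p Numeric vector of observed p-values in (0, 1].
#' @param q Single covariate stratum (0 or 1) shared by all `p`.
#' @param model A `"stratum_model"`.
#' @return A data.frame with columns `p0` and `p1`, one row per element
#'   of `p`.
#' @export
solve_matched_threshold <- function(p, q, model) {
  p <- validate_p(p)
  if (!(length(q) == 1L && q %in% c(0, 1)))
    stop("'q' must be a single value, 0 or 1", call. = FALSE)
  if (!model$stratum0$present || !model$stratum1$present)
    return(data.frame(p0 = p, p1 = p))
  target <- envelope_ratio(model, q, p)
  other <- invert_envelope(model, 1 - q, target)
  if (q == 0) data.frame(p0 = p, p1 = other)
  else        data.frame(p0 = other, p1 = p)
}

#' v-value of a rejection region
#'
#' Integrates the null density of (P, Q) over the rejection region
#' `L(p0, p1)`: `v = p0 * (1 - null_q) + p1 * null_q`, where `null_q`
#' estimates `Pr(Q = 1 | H0)`. The result is clamped into (0, 1] (floored
#' at the smallest positive representable double so that downstream
#' multiple-testing adjustments never see an exact zero).
#'
#' @param p0,p1 Numeric vectors of thresholds in \[0, 1\].
#' @param null_q Null covariate rate in \[0, 1\].
#' @return Numeric vector of v-values in (0, 1].
#' @examples
#' v_value(0.01, 0.1, 0.2)  # 0.028
#' @export
v_value <- function(p0, p1, null_q) {
  stopifnot(all(p0 >= 0 & p0 <= 1), all(p1 >= 0 & p1 <= 1),
            null_q >= 0, null_q <= 1)
  pmin(pmax(p0 * (1 - null_q) + p1 * null_q, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment of v-values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) of a vector of v-values
#' (or p-values), with input validation: all values must lie in (0, 1].
#' Adjusted values are returned in input order and never fall below the
#' input values.
#'
#' @param v Numeric vector of values in (0, 1].
#' @return Numeric vector of BH-adjusted values in (0, 1].
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(v) {
  if (length(v) == 0L)
    stop("'v' must be non-empty", call. = FALSE)
  bad <- which(!is.finite(v) | v <= 0 | v > 1)
  if (length(bad))
    stop("values outside (0, 1] in rows: ", format_rows(bad), call. = FALSE)
  stats::p.adjust(v, method = "BH")
}
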