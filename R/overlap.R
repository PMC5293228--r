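#' Sample-overlap specification for two case-control studies
#'
#' Records per-study case/control counts and the number of subjects shared
#' between the two studies, split into shared cases and shared controls.
#'
#' @param n1_case,n1_control study-1 counts.
#' @param n2_case,n2_control study-2 counts.
#' @param ns_case,ns_control shared cases / shared controls.
#' @export
overlap_spec <- function(n1_case, n1_control, n2_case, n2_control,
                         ns_case, ns_control) {
  if (ns_case < 0 || ns_case > min(n1_case, n2_case))
    stop("ns_case must lie in [0, min(n1_case, n2_case)]")
  if (ns_control < 0 || ns_control > min(n1_control, n2_control))
    stop("ns_control must lie in [0, min(n1_control, n2_control)]")
  structure(list(n1_case = n1_case, n1_control = n1_control,
                 n2_case = n2_case, n2_control = n2_control,
                 ns_case = ns_case, ns_control = ns_control),
            class = "overlap_spec")
}

#' @export
print.overlap_spec <- function(x, ...) {
  cat(sprintf(
    "Overlap: study 1 %d/%d, study 2 %d/%d, shared %d cases + %d controls\n",
    x$n1_case, x$n1_control, x$n2_case, x$n2_control,
    x$ns_case, x$ns_control))
  invisible(x)
}

#' Variance inflation of a z-score set
#'
#' The mean of z-squared over the supplied SNPs approximates the marginal
#' variance of the z-scores (the mean inflation of the association
#' chi-square statistics). Callers should restrict to a well-imputed,
#' approximately independent SNP set; set selection is the caller's
#' concern.
#'
#' @param z numeric vector of z-scores (warns below 100 values).
#' @return mean(z^2).
#' @export
estimate_inflation <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) == 0) stop("estimate_inflation: empty input")
  if (length(z) < 100)
    warning("estimate_inflation: fewer than 100 z-scores; ",
            "estimate will be noisy")
  mean(z^2)
}

#' Theoretical z-score covariance induced by sample overlap
#'
#' For two case-control studies sharing `ns_case` cases and `ns_control`
#' controls, the covariance between their association z-scores at null
#' SNPs (no genetic correlation) is
#' \deqn{c = \frac{n_{s,case}\sqrt{\frac{n_{1,ctl} n_{2,ctl}}{n_{1,case} n_{2,case}}}
#'   + n_{s,ctl}\sqrt{\frac{n_{1,case} n_{2,case}}{n_{1,ctl} n_{2,ctl}}}}
#'   {\sqrt{N_1 N_2}}}
#' where \eqn{N_i} is study i's total sample size. Two identical, fully
#' overlapping studies give c = 1; no shared subjects give c = 0. The
#' formula is symmetric in the two studies.
#'
#' @param spec an [overlap_spec].
#' @return the covariance, a scalar.
#' @export
theoretical_overlap_cov <- function(spec) {
  s <- spec
  if (s$n1_case <= 0 || s$n1_control <= 0 || s$n2_case <= 0 ||
      s$n2_control <= 0)
    stop("theoretical_overlap_cov: all per-study case and control counts ",
         "must be positive")
  n1 <- s$n1_case + s$n1_control
  n2 <- s$n2_case + s$n2_control
  (s$ns_case * sqrt((s$n1_control * s$n2_control) /
                      (s$n1_case * s$n2_case)) +
     s$ns_control * sqrt((s$n1_case * s$n2_case) /
                           (s$n1_control * s$n2_control))) / sqrt(n1 * n2)
}

#' Bivariate-normal null model for paired z-scores
#'
#' The null joint distribution of (z1, z2) at a SNP with no true effect:
#' marginal variances are the studies' inflation factors, the covariance
#' is the overlap-induced term, and the implied correlation is
#' `cov / sqrt(var1 * var2)`.
#'
#' @param var1,var2 marginal z-score variances (> 0).
#' @param cov overlap-induced covariance.
#' @return a `bivariate_null` object with fields `var1`, `var2`, `cov`,
#'   `corr`.
#' @export
build_null <- function(var1, var2, cov) {
  if (var1 <= 0 || var2 <= 0) stop("variances must be positive")
  corr <- cov / sqrt(var1 * var2)
  if (abs(corr) > 1)
    stop("implied |correlation| exceeds 1: ", signif(corr, 4))
  if (var2 - cov^2 / var1 <= 0)
    stop("conditional variance var2 - cov^2/var1 is not positive")
  structure(list(var1 = var1, var2 = var2, cov = cov, corr = corr),
            class = "bivariate_null")
}

#' @export
print.bivariate_null <- function(x, ...) {
  cat(sprintf(
    "Bivariate null: var1 = %.4f, var2 = %.4f, cov = %.4f (corr = %.4f)\n",
    x$var1, x$var2, x$cov, x$corr))
  invisible(x)
}

#' Empirical overlap covariance from paired z-scores
#'
#' Without LD scores, the plain mean of the z-score products `mean(z1*z2)`.
#' With LD scores, the intercept of the ordinary-least-squares regression
#' of `z1*z2` on the LD score — the cross-trait LD-score-regression
#' intercept, which estimates the overlap covariance free of
#' genetic-correlation contamination (the genetic signal loads on the
#' slope).
#'
#' @param z1,z2 paired z-score vectors (same length, >= 100 pairs).
#' @param ld_scores optional per-SNP LD scores, same length.
#' @return scalar covariance estimate; when `ld_scores` is given, the
#'   attribute `"se"` carries the intercept's standard error.
#' @export
empirical_overlap_cov <- function(z1, z2, ld_scores = NULL) {
  if (length(z1) != length(z2))
    stop("z1 and z2 must have equal length")
  if (!is.null(ld_scores) && length(ld_scores) != length(z1))
    stop("ld_scores length must match z1/z2")
  if (length(z1) < 100)
    warning("empirical_overlap_cov: fewer than 100 pairs; noisy estimate")
  if (is.null(ld_scores)) return(mean(z1 * z2))
  fit <- stats::lm(I(z1 * z2) ~ ld_scores)
  est <- unname(stats::coef(fit)[1])
  attr(est, "se") <- unname(sqrt(diag(stats::vcov(fit)))[1])
  est
}

#' Conditional transformation of study-2 z-scores given study 1
#'
#' Under the bivariate null, the distribution of z2 given z1 is normal
#' with mean \eqn{\mu = (c/\sigma_1^2) z_1} and variance
#' \eqn{\tau^2 = \sigma_2^2 - c^2/\sigma_1^2}. The corrected statistic is
#' the standardized conditional residual
#' \deqn{z_{corr} = (z_2 - \mu)/\tau,}
#' with two-sided p-value `2 * pnorm(-|z_corr|)`. Standardizing by the
#' full marginal \eqn{\sigma_2^2} (including polygenic inflation) makes
#' the corrected test conservative; `variance_mode = "unit"` substitutes
#' 1 for \eqn{\sigma_2^2} as a sensitivity analysis.
#'
#' @param z1 conditioning z-scores (study 1).
#' @param z2 z-scores to correct (study 2), same length as `z1`.
#' @param model a [build_null()] model.
#' @param variance_mode `"marginal"` (default, conservative) or `"unit"`.
#' @return data.frame with columns `z_corrected`, `p_corrected`.
#' @export
conditional_transform <- function(z1, z2, model,
                                  variance_mode = c("marginal", "unit")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(model, "bivariate_null"),
            length(z1) == length(z2))
  var2 <- if (variance_mode == "marginal") model$var2 else 1
  tau2 <- var2 - model$cov^2 / model$var1
  if (tau2 <= 0)
    stop("conditional variance is not positive under variance_mode = ",
         variance_mode)
  mu <- (model$cov / model$var1) * z1
  zc <- (z2 - mu) / sqrt(tau2)
  data.frame(z_corrected = zc, p_corrected = 2 * stats::pnorm(-abs(zc)))
}

#' Reverse the conditioning direction of a null model
#'
#' Returns the model with the roles of study 1 and study 2 exchanged, for
#' running the lookup in the other direction (e.g. study-2 hits queried in
#' study 1).
#'
#' @param model a `bivariate_null`.
#' @export
swap_null <- function(model) {
  build_null(model$var2, model$var1, model$cov)
}
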