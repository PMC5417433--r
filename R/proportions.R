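#' Binomial proportion on the logit scale with a Wald interval
#'
#' Core estimator used throughout the stage-wise analysis. For k successes of
#' n, the saturated-binomial MLE of the logit is \eqn{\ln(k/(n-k))} with
#' standard error \eqn{\sqrt{1/k + 1/(n-k)}} (delta method / observed
#' information), and the 95\% CI is the inverse logit of
#' \eqn{\hat\mu \pm 1.96\,\widehat{se}} — asymmetric about \eqn{\hat p}
#' except at 0.5. At the boundary (k = 0 or k = n) the Haldane–Anscombe
#' adjustment adds 0.5 to each cell before the logit computation so all
#' logit-scale quantities stay finite; `p_hat` itself remains the raw k/n
#' (so a boundary `p_hat` of exactly 0 or 1 lies outside its own corrected
#' interval), and `correction_applied` flags the adjustment.
#'
#' @param k,n success and exposure counts, `0 <= k <= n`, `n > 0`.
#' @param conf_z normal quantile for the interval (1.96 for 95\%).
#' @return object of class `proportion_estimate`: list with `k`, `n`,
#'   `p_hat`, `logit_mean`, `logit_se`, `ci_low`, `ci_high`,
#'   `correction_applied`.
#' @examples
#' proportion_estimate(532, 840)   # 63.3% bark entry
#' proportion_estimate(20, 20)     # Haldane-corrected boundary
#' @export
proportion_estimate <- function(k, n, conf_z = 1.96) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  corrected <- (k == 0 || k == n)
  k2 <- if (corrected) k + 0.5 else k
  n2 <- if (corrected) n + 1 else n
  lm_ <- log(k2 / (n2 - k2))
  se <- sqrt(1 / k2 + 1 / (n2 - k2))
  structure(list(
    k = k, n = n, p_hat = k / n,
    logit_mean = lm_, logit_se = se,
    ci_low = stats::plogis(lm_ - conf_z * se),
    ci_high = stats::plogis(lm_ + conf_z * se),
    correction_applied = corrected), class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("proportion: %d/%d = %.4f (95%% CI %.4f-%.4f)%s\n",
              x$k, x$n, x$p_hat, x$ci_low, x$ci_high,
              if (x$correction_applied) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Pooled stage proportion across all records
#'
#' Sums successes and exposures over every record at a colonization stage and
#' returns the pooled [proportion_estimate()]. This is the "532 of 840"
#' style pooled rate reported for each staged experiment.
#'
#' @param records trial records (`data.frame` with `stage`, `n_success`,
#'   `n_exposed`).
#' @param stage `"bark"`, `"phloem"` or `"brood"`.
#' @return a `proportion_estimate`.
#' @export
pooled_proportion <- function(records, stage) {
  check_stage(stage)
  sel <- records[records$stage == stage, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no records at stage '", stage, "'")
  n <- sum(sel$n_exposed)
  if (n <= 0) stop("total exposure must be positive")
  proportion_estimate(sum(sel$n_success), n)
}

#' Per-species logit-scale stage estimate
#'
#' Pools a species' records at one stage and returns the logit-scale MLE,
#' its SE and back-transformed CI — the three per-species inputs the
#' susceptibility integrator consumes (see [integrate_susceptibility()]).
#'
#' @inheritParams pooled_proportion
#' @param species species label present at that stage.
#' @return object of class `stage_estimate`: list with `species`, `stage`
#'   and `estimate` (a `proportion_estimate`).
#' @export
species_logit_estimate <- function(records, species, stage) {
  check_stage(stage)
  sel <- records[records$stage == stage & records$species == species, ,
                 drop = FALSE]
  if (nrow(sel) == 0L)
    stop("species '", species, "' absent at stage '", stage, "'")
  est <- proportion_estimate(sum(sel$n_success), sum(sel$n_exposed))
  structure(list(species = species, stage = stage, estimate = est),
            class = "stage_estimate")
}

#' @export
print.stage_estimate <- function(x, ...) {
  cat(sprintf("[%s / %s] ", x$species, x$stage))
  print(x$estimate)
  invisible(x)
}

#' Build a stage estimate directly from logit mean and SE
#'
#' Convenience constructor for feeding externally computed (or fixture)
#' logit-scale estimates into the integrator.
#'
#' @param species,stage labels.
#' @param logit_mean,logit_se logit-scale mean and SE (`logit_se >= 0`).
#' @return a `stage_estimate`.
#' @export
stage_estimate <- function(species, stage, logit_mean, logit_se) {
  check_stage(stage)
  if (!is.finite(logit_mean) || !is.finite(logit_se))
    stop("logit mean and SE must be finite")
  if (logit_se < 0) stop("logit_se must be >= 0")
  p <- stats::plogis(logit_mean)
  est <- structure(list(
    k = NA_real_, n = NA_real_, p_hat = p,
    logit_mean = logit_mean, logit_se = logit_se,
    ci_low = stats::plogis(logit_mean - 1.96 * logit_se),
    ci_high = stats::plogis(logit_mean + 1.96 * logit_se),
    correction_applied = FALSE), class = "proportion_estimate")
  structure(list(species = species, stage = stage, estimate = est),
            class = "stage_estimate")
}

#' Binomial logistic regression on grouped trial records
#'
#' Fits success/failure counts against a model formula by maximum likelihood
#' (iteratively reweighted least squares, relative tolerance 1e-10, at most
#' 100 iterations). The response is built from `n_success`/`n_exposed`;
#' `formula` gives the right-hand side only, e.g. `~ species + phloem_mm`.
#' Tree- and unit-level random effects are not fitted; clustering, where it
#' matters, is handled by analysing unit-level counts and (optionally)
#' resampling trees.
#'
#' Complete or quasi-complete separation is reported by `converged = FALSE`
#' whenever any coefficient exceeds 15 logits in magnitude, rather than
#' failing silently.
#'
#' @param records trial records (see [simulate_colonization()] for the
#'   schema).
#' @param formula right-hand-side formula of fixed effects.
#' @return object of class `logistic_fit`: coefficients, log-likelihood,
#'   deviance, AIC (= 2·k − 2·logLik), `n_obs`, `converged`, `iter`, and the
#'   underlying `glm` object in `$fit`.
#' @examples
#' p <- colonization_params(sd_tree = 0, sd_unit = 0)
#' tr <- simulate_colonization(p, "bark", seed = 1)
#' fit_logistic(tr, ~ species)
#' @export
fit_logistic <- function(records, formula = ~1) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (any(records$n_success > records$n_exposed) || any(records$n_success < 0))
    stop("need 0 <= n_success <= n_exposed")
  f <- stats::update(formula, cbind(n_success, n_exposed - n_success) ~ .)
  fit <- stats::glm(f, family = stats::binomial(), data = records,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  qr_rank <- fit$rank
  if (qr_rank < length(stats::coef(fit)))
    stop("design matrix is rank deficient")
  cf <- stats::coef(fit)
  separated <- any(abs(cf) > 15)
  structure(list(
    coefficients = cf,
    logLik = as.numeric(stats::logLik(fit)),
    deviance = stats::deviance(fit),
    aic = 2 * length(cf) - 2 * as.numeric(stats::logLik(fit)),
    n_obs = nrow(records),
    converged = fit$converged && !separated,
    separation = separated,
    iter = fit$iter,
    formula = formula,
    fit = fit), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binomial logistic fit:", deparse(x$formula), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.3f  deviance %.3f  AIC %.3f  (n=%d, %s)\n",
              x$logLik, x$deviance, x$aic, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            class = "logLik")
}

#' Likelihood-ratio test of nested logistic fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} on df equal to the
#' difference in coefficient counts, referred to the upper chi-square tail.
#' A statistic below `-tol` signals non-nesting or non-convergence and
#' errors; small negative round-off is clamped to 0.
#'
#' @param full,reduced `logistic_fit` objects on the same records, reduced
#'   nested in full.
#' @param tol numerical tolerance for the non-negativity check.
#' @return object of class `chisq_test`: `statistic`, `df`, `p_value`.
#' @export
lrt_nested <- function(full, reduced, tol = 1e-8) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n_obs != reduced$n_obs)
    stop("fits must be on the same records")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop("`full` has fewer coefficients than `reduced`")
  stat <- 2 * (full$logLik - reduced$logLik)
  if (stat < -tol)
    stop("negative LR statistic: models not nested or fit not converged")
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "chisq_test")
}

#' @export
print.chisq_test <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Historical-vs-novel host contrast at one stage
#'
#' Likelihood-ratio contrast (df = 1) comparing a logistic model with the
#' host-class factor (historical vs novel host) against the intercept-only
#' model, on one stage's records.
#'
#' @inheritParams pooled_proportion
#' @return a `chisq_test`.
#' @export
host_class_contrast <- function(records, stage) {
  check_stage(stage)
  sel <- records[records$stage == stage, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no records at stage '", stage, "'")
  if (length(unique(sel$host_class)) < 2L)
    stop("both host classes must be present")
  lrt_nested(fit_logistic(sel, ~host_class), fit_logistic(sel, ~1))
}
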