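#' Monte-Carlo validation of the significance-based calculations
#'
#' Checks by simulation that the event counts produced by the
#' significance-based calculations deliver their nominal power and type I
#' error.  For the study-based variant (`calc = "B1"`) a "first study" with
#' `e1` events is simulated at the target D, its D bootstrapped to obtain
#' \eqn{\sigma_1^2}, and \eqn{\lambda_s = e_1\sigma_1^2} formed; for the
#' model-based variant (`"B2"`) \eqn{\lambda_m} is computed from the target
#' D and censoring proportion.  The required event count \eqn{e_2} follows
#' from [events_significance()].  Each replicate then simulates an
#' exact-event dataset under the null and under the alternative, estimates D
#' and its bootstrap standard error, and applies a Wald z-test.  Both
#' sidedness variants test a shortfall of \eqn{\delta} relative to the
#' target: one-sided \eqn{H_0\!: D^* - D_2 \ge \delta} rejects when
#' \eqn{(\hat D - (D^* - \delta))/\widehat{se} > z_{1-\alpha}}; two-sided
#' \eqn{H_0\!: D^* - D_2 = \delta} rejects when
#' \eqn{|\hat D - (D^* - \delta)|/\widehat{se} > z_{1-\alpha/2}}.  In both
#' cases the type-I arm generates data at the null value
#' \eqn{D_2 = D^* - \delta} and the power arm at \eqn{D_2 = D^*} (the
#' alternative the design's power refers to, and the D at which the
#' variance assumed by the calculation holds).  The generating log hazard
#' ratio is always (arm D)/\eqn{\kappa}, under which the simulated true D
#' equals the arm's D exactly.
#'
#' @param calc `"B2"` (model-based lambda, default) or `"B1"` (study-based).
#' @param target_d the target discrimination \eqn{D^*}.
#' @param delta significance margin \eqn{\delta > 0}.
#' @param censoring censoring proportion used both in the calculation and in
#'   the generated data.
#' @param alpha,sided,power design parameters as in [events_significance()].
#' @param replications number of Monte-Carlo replicates per arm (>= 2).
#' @param boot bootstrap replications for each replicate's standard error of
#'   D (and for the first study's sigma_1 when `calc = "B1"`).
#' @param e1 first-study event count (required for `"B1"`).
#' @param seed RNG seed for the whole run.
#' @return An object of class `"validation_result"` with the event count
#'   used (`e2`), `observed_type1` and `observed_power` with their binomial
#'   Monte-Carlo standard errors, the arm D values, and the configuration.
#' @examples
#' \donttest{
#' run_significance_study(calc = "B2", target_d = 1.6, delta = 0.4,
#'                        censoring = 0.2, power = 0.8, replications = 50,
#'                        boot = 50, seed = 1)
#' }
#' @export
run_significance_study <- function(calc = c("B2", "B1"), target_d, delta,
                                   censoring, alpha = 0.05, sided = 2,
                                   power = 0.8, replications = 500,
                                   boot = 200, e1 = NULL, seed = NULL) {
  calc <- match.arg(calc)
  if (replications < 2) stop("'replications' must be >= 2", call. = FALSE)
  sided <- .check_sided(sided)
  if (!is.null(seed)) set.seed(seed)

  lam <- .lambda_for_calc(calc, target_d, censoring, e1, boot)
  design <- events_significance(lam, delta, alpha, sided, power, censoring)
  e2 <- design$events

  d_null <- target_d - delta       # null: D2 falls short of D* by delta
  d_alt <- target_d                # alternative the power refers to
  if (sided == 1L) {
    zcrit <- stats::qnorm(1 - alpha)
    reject <- function(dhat, se) (dhat - d_null) / se > zcrit
  } else {
    zcrit <- stats::qnorm(1 - alpha / 2)
    reject <- function(dhat, se) abs(dhat - d_null) / se > zcrit
  }
  if (d_alt < 0 || d_null < 0)
    stop("margin larger than the target D: arm D would be negative",
         call. = FALSE)

  one_arm <- function(d_arm) {
    vapply(seq_len(replications), function(r) {
      dat <- exact_event_dataset(e2, censoring, d = d_arm)
      est <- estimate_d(dat$time, dat$status, dat$pi, boot = boot)
      reject(est$d, est$se_boot)
    }, logical(1L))
  }
  type1 <- one_arm(d_null)
  pow <- one_arm(d_alt)

  .new_validation_result(
    calc = calc, e2 = e2, lambda = lam, replications = replications,
    boot = boot, target_d = target_d, censoring = censoring, alpha = alpha,
    sided = sided, nominal_power = power, delta = delta, width = NA,
    d_null = d_null, d_alt = d_alt,
    observed_type1 = mean(type1), observed_power = mean(pow))
}

#' Monte-Carlo validation of the precision-based calculations
#'
#' Checks that the event count from [events_ci()] delivers the nominal
#' confidence-interval coverage: with \eqn{e_2} events, the estimate of D
#' should fall within `width` of the true \eqn{D = \beta\kappa} in
#' \eqn{100(1-\alpha)\%} of repetitions.  Lambda is obtained as in
#' [run_significance_study()] (`"D1"` study-based, `"D2"` model-based).
#'
#' @inheritParams run_significance_study
#' @param calc `"D2"` (default) or `"D1"`.
#' @param width the designed confidence-interval half-width \eqn{w}.
#' @param boot bootstrap replications for the first study's standard error
#'   (`"D1"` only); the coverage check itself needs no bootstrap.
#' @return An object of class `"validation_result"` with `observed_coverage`
#'   and its Monte-Carlo standard error.
#' @examples
#' \donttest{
#' run_coverage_study(calc = "D2", target_d = 1.6, width = 0.2,
#'                    censoring = 0.2, replications = 100, seed = 1)
#' }
#' @export
run_coverage_study <- function(calc = c("D2", "D1"), target_d, width,
                               censoring, alpha = 0.05, replications = 500,
                               boot = 200, e1 = NULL, seed = NULL) {
  calc <- match.arg(calc)
  if (replications < 2) stop("'replications' must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  lam <- .lambda_for_calc(switch(calc, D1 = "B1", D2 = "B2"),
                          target_d, censoring, e1, boot)
  design <- events_ci(lam, width, alpha, censoring)
  e2 <- design$events

  inside <- vapply(seq_len(replications), function(r) {
    dat <- exact_event_dataset(e2, censoring, d = target_d)
    est <- estimate_d(dat$time, dat$status, dat$pi)
    abs(est$d - target_d) <= width
  }, logical(1L))

  .new_validation_result(
    calc = calc, e2 = e2, lambda = lam, replications = replications,
    boot = boot, target_d = target_d, censoring = censoring, alpha = alpha,
    sided = 2L, nominal_power = NA, delta = NA, width = width,
    d_null = NA, d_alt = NA,
    observed_coverage = mean(inside))
}

.lambda_for_calc <- function(calc, target_d, censoring, e1, boot) {
  if (calc == "B1") {
    if (is.null(e1))
      stop("'e1' (first-study events) is required for the study-based ",
           "calculations", call. = FALSE)
    first <- exact_event_dataset(e1, censoring, d = target_d)
    d1 <- estimate_d(first$time, first$status, first$pi, boot = boot)
    lambda_from_study(se_d1 = d1$se_boot, events = e1, d1 = d1$d,
                      censoring = censoring)
  } else {
    lambda_from_model(target_d, censoring)
  }
}

.mc_se <- function(p, n) sqrt(p * (1 - p) / n)

.new_validation_result <- function(..., observed_type1 = NA,
                                   observed_power = NA,
                                   observed_coverage = NA) {
  x <- list(...)
  n <- x$replications
  x$observed_type1 <- observed_type1
  x$se_type1 <- if (is.na(observed_type1)) NA else .mc_se(observed_type1, n)
  x$observed_power <- observed_power
  x$se_power <- if (is.na(observed_power)) NA else .mc_se(observed_power, n)
  x$observed_coverage <- observed_coverage
  x$se_coverage <- if (is.na(observed_coverage)) NA else
    .mc_se(observed_coverage, n)
  structure(x, class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo validation of calculation %s  (%d replications)\n",
              x$calc, x$replications))
  cat(sprintf("  target D = %g, censoring = %g, e2 = %d (lambda %s = %.4g)\n",
              x$target_d, x$censoring, x$e2, x$lambda$source,
              x$lambda$value))
  pct <- function(p, se) sprintf("%.1f%% (se %.2f)", 100 * p, 100 * se)
  if (!is.na(x$observed_type1))
    cat(sprintf("  type I error: %s   [nominal %.1f%%]\n",
                pct(x$observed_type1, x$se_type1), 100 * x$alpha))
  if (!is.na(x$observed_power))
    cat(sprintf("  power:        %s   [nominal %.1f%%]\n",
                pct(x$observed_power, x$se_power), 100 * x$nominal_power))
  if (!is.na(x$observed_coverage))
    cat(sprintf("  CI coverage (|Dhat - D| <= %g): %s   [nominal %.1f%%]\n",
                x$width, pct(x$observed_coverage, x$se_coverage),
                100 * (1 - x$alpha)))
  invisible(x)
}
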