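# kappa = sqrt(8/pi): scaling that makes D the log hazard ratio between the
# two halves of the prognostic index split at its median.
.kappa <- sqrt(8 / pi)

#' Scaling constant of the D measure
#'
#' Returns \eqn{\kappa = \sqrt{8/\pi} \approx 1.596}, the constant linking D
#' to the standard deviation of a normally distributed prognostic index
#' (\eqn{D = \kappa\sigma^*}) and, in the exponential simulation model of
#' [draw_survival_times()], the true D to the log hazard ratio
#' (\eqn{D = \beta\kappa}).
#'
#' @return A single number.
#' @export
kappa_d <- function() .kappa

#' Expected normal order statistics (rankits) of a vector
#'
#' Maps values to the Blom approximation of expected standard-normal order
#' statistics, \eqn{\Phi^{-1}((i - 3/8)/(n + 1/4))} for rank \eqn{i} of
#' \eqn{n}.  Tied values receive the mean of the rankits of their tied
#' positions, which keeps the scores exactly antisymmetric under sign
#' reversal of the input.
#'
#' @param x numeric vector without missing values.
#' @return Numeric vector of rankit scores, same length as `x`.
#' @export
rankit_scores <- function(x) {
  if (anyNA(x)) stop("'x' must not contain missing values", call. = FALSE)
  n <- length(x)
  s <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  out <- s[rank(x, ties.method = "first")]
  if (anyDuplicated(x)) out <- stats::ave(out, match(x, x))
  out
}

# Cox fit of (time, status) on a single constructed covariate; Efron ties.
# coxph.fit avoids the formula-interface overhead in bootstrap/MC loops.
.cox_coef <- function(time, status, z) {
  o <- order(time)
  fit <- survival::coxph.fit(
    x = matrix(z[o], ncol = 1L),
    y = survival::Surv(time[o], status[o]),
    strata = NULL, offset = NULL, init = 0,
    control = survival::coxph.control(),
    weights = NULL, method = "efron", rownames = NULL)
  c(coef = unname(fit$coefficients), se = sqrt(unname(fit$var[1L])))
}

.check_sample <- function(time, status, min_events = 2L) {
  if (length(time) != length(status))
    stop("'time' and 'status' must have the same length", call. = FALSE)
  if (anyNA(time) || anyNA(status))
    stop("missing values in 'time' or 'status'", call. = FALSE)
  if (any(time <= 0))
    stop("all follow-up times must be strictly positive", call. = FALSE)
  if (!all(status %in% c(0, 1)))
    stop("'status' must be 0 (censored) or 1 (event)", call. = FALSE)
  if (sum(status) < min_events)
    stop(sprintf("at least %d events are required", min_events),
         call. = FALSE)
  invisible(NULL)
}

#' Estimate the D measure of discrimination from survival data
#'
#' Royston-Sauerbrei's D quantifies the separation in survival between
#' patients with differing model-predicted risks; it is interpretable as the
#' log hazard ratio between two equal-sized groups formed by splitting the
#' prognostic index at its median, and equals \eqn{\kappa\sigma^*} where
#' \eqn{\sigma^*} is the standard deviation of the (assumed normal)
#' prognostic index.  It is estimated by a rank-based construction: the
#' prognostic index values are replaced by their expected normal order
#' statistics ([rankit_scores()]) divided by \eqn{\kappa}, and D is the
#' coefficient of this constructed covariate in an auxiliary Cox
#' proportional-hazards fit (Efron tie handling).  Being rank-based, the
#' estimate is invariant to any strictly increasing transformation of the
#' prognostic index.
#'
#' The model-based standard error of the auxiliary fit (`se`) is known to be
#' biased downwards, increasingly so for large D; the subject-resampling
#' bootstrap (`boot` > 0, see [bootstrap_se_d()]) is recommended whenever the
#' standard error feeds a sample size calculation, particularly for D >= 2.
#'
#' @param time positive follow-up times.
#' @param status event indicator, 1 = event, 0 = censored; at least 2 events.
#' @param pi prognostic index (linear predictor) per subject.  If omitted,
#'   `x` must be given.
#' @param x alternatively, a matrix or data frame of covariate columns; a Cox
#'   model of `Surv(time, status)` on `x` is fitted first and its linear
#'   predictor used as the prognostic index.
#' @param boot number of bootstrap replications for the resampling standard
#'   error; 0 (default) skips the bootstrap.
#' @param seed optional seed for the bootstrap resampling.
#' @return An object of class `"d_estimate"`: `d`, `se` (auxiliary-model
#'   standard error), `se_boot` and `n_boot` when requested, `boot_skipped`
#'   (replicates dropped for having fewer than 2 events), `events`, `n`.
#' @examples
#' dat <- draw_survival_times(400, beta = 1, censoring_rate = 0.2, seed = 42)
#' estimate_d(dat$time, dat$status, dat$pi)
#' @seealso [bootstrap_se_d()], [c_to_d()], [d_to_r2()]
#' @export
estimate_d <- function(time, status, pi = NULL, x = NULL, boot = 0,
                       seed = NULL) {
  .check_sample(time, status)
  if (is.null(pi)) {
    if (is.null(x))
      stop("supply either 'pi' or covariates 'x'", call. = FALSE)
    x <- as.matrix(x)
    if (anyNA(x)) stop("missing values in 'x'", call. = FALSE)
    cfit <- survival::coxph(survival::Surv(time, status) ~ x,
                            ties = "efron")
    pi <- unname(cfit$linear.predictors)
  }
  if (anyNA(pi)) stop("missing values in 'pi'", call. = FALSE)
  if (length(pi) != length(time))
    stop("'pi' must have one value per subject", call. = FALSE)

  if (length(unique(pi)) == 1L) {
    warning("prognostic index is constant: no discrimination, D = 0",
            call. = FALSE)
    return(structure(list(d = 0, se = NA_real_, se_boot = NULL,
                          n_boot = 0L, boot_skipped = 0L,
                          events = as.integer(sum(status)),
                          n = length(time)),
                     class = "d_estimate"))
  }
  z <- rankit_scores(pi) / .kappa
  est <- .cox_coef(time, status, z)
  se_boot <- NULL; skipped <- 0L
  if (boot > 0) {
    bs <- bootstrap_se_d(time, status, pi, reps = boot, seed = seed)
    se_boot <- bs$se
    skipped <- bs$skipped
  }
  structure(
    list(d = est[["coef"]], se = est[["se"]], se_boot = se_boot,
         n_boot = if (boot > 0) as.integer(boot) else 0L,
         boot_skipped = skipped,
         events = as.integer(sum(status)), n = length(time)),
    class = "d_estimate")
}

#' Bootstrap standard error of D
#'
#' Resamples subjects (their time, status, prognostic index triples) with
#' replacement, re-estimates D on each resample — recomputing the rankit
#' scores within the resample — and returns the standard deviation of the
#' replicate estimates.  Replicates that draw fewer than 2 events or a
#' constant prognostic index are skipped and counted; if more than half of
#' the replicates are skipped the bootstrap aborts.
#'
#' @inheritParams estimate_d
#' @param reps number of bootstrap replications (>= 2); 500 is the
#'   recommended default when the result feeds a lambda estimate.
#' @param seed optional seed; a fixed seed makes the result reproducible.
#' @return A list: `se`, `reps`, `skipped`, and `d_values` (the replicate
#'   estimates, `NA` where skipped).
#' @export
bootstrap_se_d <- function(time, status, pi, reps = 500, seed = NULL) {
  .check_sample(time, status)
  if (reps < 2) stop("'reps' must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  dvals <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    st <- status[idx]
    p <- pi[idx]
    if (sum(st) < 2 || length(unique(p)) == 1L) next
    z <- rankit_scores(p) / .kappa
    dvals[r] <- .cox_coef(time[idx], st, z)[["coef"]]
  }
  skipped <- sum(is.na(dvals))
  if (skipped > reps / 2)
    stop("bootstrap failed: more than half of the replicates had fewer ",
         "than 2 events", call. = FALSE)
  list(se = stats::sd(dvals, na.rm = TRUE), reps = as.integer(reps),
       skipped = as.integer(skipped), d_values = dvals)
}

#' @export
print.d_estimate <- function(x, ...) {
  cat(sprintf("D = %.4f  (SE %.4f", x$d, x$se))
  if (!is.null(x$se_boot))
    cat(sprintf("; bootstrap SE %.4f over %d reps, %d skipped",
                x$se_boot, x$n_boot, x$boot_skipped))
  cat(")\n")
  cat(sprintf("  n = %d subjects, %d events; R2_D = %.3f\n",
              x$n, x$events, d_to_r2(x$d)))
  invisible(x)
}

#' Convert Harrell's c-index to D
#'
#' Empirical conversion fitted as a fractional polynomial to published
#' paired (c, D) values:
#' \deqn{D = 5.50\,(c - 0.5) + 10.26\,(c - 0.5)^3.}
#' Valid for \eqn{c \ge 0.5}; values below 0.5 (worse-than-random ordering)
#' are outside the fitted range and rejected.
#'
#' @param c concordance index value(s) in `[0.5, 1]`.
#' @return D value(s).
#' @examples
#' c_to_d(0.70)
#' @export
c_to_d <- function(c) {
  if (!is.numeric(c) || anyNA(c)) stop("'c' must be numeric", call. = FALSE)
  if (any(c < 0.5 | c > 1))
    stop("'c' must lie in [0.5, 1]", call. = FALSE)
  5.50 * (c - 0.5) + 10.26 * (c - 0.5)^3
}

#' Explained variation R^2_D from D
#'
#' The D measure has a functional relationship with an explained-variation
#' measure on the familiar 0-100\% scale:
#' \deqn{R^2_D = \frac{D^2/\kappa^2}{\pi^2/6 + D^2/\kappa^2},}
#' with \eqn{\kappa^2 = 8/\pi}; \eqn{\pi^2/6} is the variance of the
#' standard log-Weibull (Gumbel) error of the underlying accelerated
#' failure-time representation.
#'
#' @param d D value(s), finite.
#' @return Value(s) in `[0, 1)`.
#' @examples
#' d_to_r2(c_to_d(0.70))
#' @export
d_to_r2 <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)))
    stop("'d' must be finite numeric", call. = FALSE)
  u <- d^2 / .kappa^2
  u / (pi^2 / 6 + u)
}

#' Tabulate the c - D - R^2_D relationship
#'
#' @param c grid of concordance values (default 0.50 to 0.92 in steps of
#'   0.02).
#' @return A data frame with columns `c`, `d` and `r2_d`, monotone
#'   increasing in all three columns.
#' @examples
#' conversion_table()
#' @export
conversion_table <- function(c = seq(0.50, 0.92, by = 0.02)) {
  d <- c_to_d(c)
  data.frame(c = c, d = d, r2_d = d_to_r2(d))
}
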