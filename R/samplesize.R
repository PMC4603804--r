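#' Sum of normal quantiles entering the significance-based calculations
#'
#' Returns \eqn{zz = z_{1-\alpha/2} + z_{1-\beta}} for a two-sided
#' (superiority) test or \eqn{zz = z_{1-\alpha} + z_{1-\beta}} for a
#' one-sided (non-inferiority) test, with the standard normal quantiles
#' computed at full double precision.
#'
#' @param alpha significance level, in (0, 1).
#' @param sided 1 (non-inferiority) or 2 (superiority).
#' @param power desired power \eqn{1-\beta}, in (0, 1).
#' @return The quantile sum as a single number.
#' @examples
#' zz_quantile(0.05, sided = 1, power = 0.90)  # 1.6449 + 1.2816
#' @export
zz_quantile <- function(alpha, sided = 2, power = 0.5) {
  .check_prob(alpha, "alpha")
  .check_prob(power, "power")
  sided <- .check_sided(sided)
  za <- if (sided == 2L) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  za + stats::qnorm(power)
}

.check_sided <- function(sided) {
  if (length(sided) != 1L || !sided %in% c(1, 2))
    stop("'sided' must be 1 (non-inferiority) or 2 (superiority)",
         call. = FALSE)
  as.integer(sided)
}

.as_lambda <- function(lambda) {
  if (inherits(lambda, "lambda_estimate")) return(lambda)
  if (is.numeric(lambda) && length(lambda) == 1L && is.finite(lambda) &&
      lambda > 0)
    return(structure(list(value = lambda, source = "user",
                          d_input = NULL, cens_input = NULL),
                     class = "lambda_estimate"))
  stop("'lambda' must be a lambda_estimate or a single positive number",
       call. = FALSE)
}

.new_samplesize_result <- function(raw_events, lambda, zz, censoring, type,
                                   margin = NA, width = NA, alpha, sided = NA,
                                   power = NA, sigma1_sq = 0, min_precision = NA) {
  events <- as.integer(ceiling(raw_events))
  structure(
    list(events = events,
         patients = patients_from_events(events, censoring),
         raw_events = raw_events,
         lambda = lambda, zz = zz,
         type = type, margin = margin, width = width,
         alpha = alpha, sided = sided, power = power,
         censoring = censoring, sigma1_sq = sigma1_sq,
         min_precision = min_precision),
    class = "samplesize_result")
}

#' Significance-based event count for a new prognostic study
#'
#' Number of events required so that a shortfall (one-sided,
#' non-inferiority) or difference (two-sided, superiority) of `margin` in
#' the discrimination measure D, relative to a fixed target \eqn{D^*}
#' assumed known without error, is just significant at level `alpha` with
#' the desired power:
#' \deqn{e = \lambda \left(\frac{\delta}{zz}\right)^{-2},}
#' where \eqn{zz} is the quantile sum of [zz_quantile()].  The event count is
#' the ceiling of the unrounded value; the patient count inflates it by the
#' expected censoring proportion.
#'
#' @param lambda a [lambda_from_study()] / [lambda_from_model()] estimate, or
#'   a bare positive number.
#' @param margin the margin \eqn{\delta > 0} on the D scale.
#' @param censoring expected censoring proportion in the new study, used only
#'   to convert events to patients.
#' @inheritParams zz_quantile
#' @return An object of class `"samplesize_result"` with elements `events`,
#'   `patients`, `raw_events` (unrounded), `lambda`, `zz` and the design
#'   parameters.
#' @examples
#' lam <- lambda_from_study(se_d1 = 0.09, events = 502)
#' ## non-inferiority margin 0.25, one-sided alpha 0.05, 90% power
#' events_significance(lam, margin = 0.25, alpha = 0.05, sided = 1,
#'                     power = 0.90)
#' @seealso [events_ci()] for precision-based designs, [events_with_prior()]
#'   when the prior study's uncertainty is carried through,
#'   [composite_events()] for the combined absolute/relative design.
#' @export
events_significance <- function(lambda, margin, alpha = 0.05, sided = 2,
                                power = 0.9, censoring = 0) {
  lambda <- .as_lambda(lambda)
  if (!is.numeric(margin) || length(margin) != 1L || !is.finite(margin) ||
      margin <= 0)
    stop("'margin' must be a single positive number", call. = FALSE)
  .check_cens(censoring)
  sided <- .check_sided(sided)
  zz <- zz_quantile(alpha, sided, power)
  raw <- lambda$value * (zz / margin)^2
  .new_samplesize_result(raw, lambda, zz, censoring, "significance",
                         margin = margin, alpha = alpha, sided = sided,
                         power = power)
}

#' Precision-based event count for a new prognostic study
#'
#' Number of events required so that the new study's estimate of D has a
#' \eqn{100(1-\alpha)\%} confidence interval of half-width `width`:
#' \deqn{e = \lambda \left(\frac{w}{z_{1-\alpha/2}}\right)^{-2}.}
#' Equivalent to [events_significance()] with a two-sided `alpha`,
#' `margin = width` and 50\% power.
#'
#' @inheritParams events_significance
#' @param width the desired confidence-interval half-width \eqn{w > 0} on
#'   the D scale.
#' @return An object of class `"samplesize_result"`; see
#'   [events_significance()].
#' @examples
#' lam <- lambda_from_model(d = 1.3, censoring = 0.10)
#' events_ci(lam, width = 0.2, alpha = 0.05, censoring = 0.10)
#' @export
events_ci <- function(lambda, width, alpha = 0.05, censoring = 0) {
  lambda <- .as_lambda(lambda)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0)
    stop("'width' must be a single positive number", call. = FALSE)
  .check_prob(alpha, "alpha")
  .check_cens(censoring)
  z <- stats::qnorm(1 - alpha / 2)
  raw <- lambda$value * (z / width)^2
  .new_samplesize_result(raw, lambda, z, censoring, "ci",
                         width = width, alpha = alpha)
}

#' Event count carrying a prior study's uncertainty
#'
#' The ancestral forms of the calculations retain the prior study's
#' sampling variance \eqn{\sigma_1^2} rather than treating the target D as
#' fixed:
#' \deqn{e_2 = \lambda_s\left[\left(\frac{\delta}{zz}\right)^2 -
#'   \sigma_1^2\right]^{-1}}
#' (significance mode; the precision mode replaces \eqn{\delta/zz} with
#' \eqn{w/z_{1-\alpha/2}}).  A positive event count requires
#' \eqn{\delta > \sigma_1 \, zz} (or \eqn{w > \sigma_1 z_{1-\alpha/2}}); an
#' infeasible margin or width raises an error reporting that lower bound.
#' With \eqn{\sigma_1^2 = 0} these reduce exactly to
#' [events_significance()] / [events_ci()].
#'
#' @param prior a [prior_study()] object.
#' @param margin margin \eqn{\delta} (significance mode); exactly one of
#'   `margin` / `width` must be given.
#' @param width confidence-interval half-width \eqn{w} (precision mode).
#' @param sigma1 standard error of D carried for the prior study; defaults
#'   to the prior study's reported `se_d1`.  Setting it to 0 recovers the
#'   fixed-target calculations exactly.
#' @inheritParams events_significance
#' @return An object of class `"samplesize_result"`, additionally carrying
#'   `sigma1_sq` and `min_precision` (the feasibility bound on the margin or
#'   width).
#' @examples
#' ps <- prior_study(se_d1 = 0.09, events = 502)
#' events_with_prior(ps, margin = 0.4, alpha = 0.05, sided = 1, power = 0.9)
#' @export
events_with_prior <- function(prior, margin = NULL, width = NULL,
                              alpha = 0.05, sided = 2, power = 0.9,
                              censoring = 0, sigma1 = NULL) {
  if (!inherits(prior, "prior_study"))
    stop("'prior' must be a prior_study object", call. = FALSE)
  if (is.null(margin) == is.null(width))
    stop("give exactly one of 'margin' or 'width'", call. = FALSE)
  .check_cens(censoring)
  sided <- .check_sided(sided)
  if (is.null(sigma1)) sigma1 <- prior$se_d1
  if (!is.numeric(sigma1) || length(sigma1) != 1L || !is.finite(sigma1) ||
      sigma1 < 0)
    stop("'sigma1' must be a single non-negative number", call. = FALSE)
  s1sq <- sigma1^2
  lam <- prior$lambda
  if (!is.null(margin)) {
    zz <- zz_quantile(alpha, sided, power)
    bound <- sigma1 * zz
    if (margin <= bound)
      stop(sprintf(paste0("infeasible margin: a positive event count ",
                          "requires margin > %.4f (= SE(D1) * zz)"), bound),
           call. = FALSE)
    raw <- lam$value / ((margin / zz)^2 - s1sq)
    .new_samplesize_result(raw, lam, zz, censoring, "significance",
                           margin = margin, alpha = alpha, sided = sided,
                           power = power, sigma1_sq = s1sq,
                           min_precision = bound)
  } else {
    .check_prob(alpha, "alpha")
    z <- stats::qnorm(1 - alpha / 2)
    bound <- sigma1 * z
    if (width <= bound)
      stop(sprintf(paste0("infeasible width: a positive event count ",
                          "requires width > %.4f (= SE(D1) * z)"), bound),
           call. = FALSE)
    raw <- lam$value / ((width / z)^2 - s1sq)
    .new_samplesize_result(raw, lam, z, censoring, "ci",
                           width = width, alpha = alpha, sigma1_sq = s1sq,
                           min_precision = bound)
  }
}

#' Composite absolute/relative precision design
#'
#' Specifying the precision of D only in absolute terms risks underpowering
#' when the realised D is larger than anticipated; specifying it only as a
#' proportion `p` of D risks underpowering when D is smaller.  The composite
#' design accepts whichever of the two precisions needs fewer events at each
#' value of D.  The resulting lower-envelope event profile peaks where the
#' two curves cross, at \eqn{D = \delta_{abs} / p}; the maximum event count
#' is the absolute-margin calculation evaluated with the model-based lambda
#' at that peak D.
#'
#' @param delta_abs absolute precision (margin or CI half-width) on the D
#'   scale.
#' @param p relative precision as a proportion of D, in (0, 1).
#' @param type `"significance"` (margin interpretation, uses `sided` and
#'   `power`) or `"ci"` (half-width interpretation).
#' @param d_grid grid of D values over which the absolute, relative and
#'   composite event curves are tabulated.
#' @inheritParams events_significance
#' @return An object of class `"composite_result"`: `peak_d`, `lambda` (at
#'   the peak), `result` (the [events_significance()]/[events_ci()] result at
#'   the peak), `events`, and `profile`, a data frame with columns `d`,
#'   `lambda_m`, `events_abs`, `events_rel`, `events_composite`.
#' @examples
#' composite_events(delta_abs = 0.25, p = 0.20, alpha = 0.05, sided = 2,
#'                  power = 0.90, censoring = 0.10)
#' @export
composite_events <- function(delta_abs, p, alpha = 0.05, sided = 2,
                             power = 0.9, censoring = 0,
                             type = c("significance", "ci"),
                             d_grid = seq(0.4, 3, by = 0.05)) {
  type <- match.arg(type)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single proportion strictly inside (0, 1)",
         call. = FALSE)
  if (!is.numeric(delta_abs) || length(delta_abs) != 1L ||
      !is.finite(delta_abs) || delta_abs <= 0)
    stop("'delta_abs' must be a single positive number", call. = FALSE)
  peak_d <- delta_abs / p
  lam_peak <- lambda_from_model(peak_d, censoring)
  one <- function(lam, prec) {
    if (type == "significance")
      events_significance(lam, prec, alpha, sided, power, censoring)
    else
      events_ci(lam, prec, alpha, censoring)
  }
  res <- one(lam_peak, delta_abs)
  prof <- do.call(rbind, lapply(d_grid, function(d) {
    lam <- lambda_from_model(d, censoring)
    ea <- one(lam, delta_abs)$events
    er <- one(lam, p * d)$events
    data.frame(d = d, lambda_m = lam$value, events_abs = ea, events_rel = er,
               events_composite = min(ea, er))
  }))
  structure(
    list(peak_d = peak_d, lambda = lam_peak, result = res,
         events = res$events, patients = res$patients,
         delta_abs = delta_abs, p = p, profile = prof),
    class = "composite_result")
}

#' Precision actually achieved by a study of a given size
#'
#' Inverts the significance-based calculation: given a realised (or
#' anticipated) value of D and an event count, returns the smallest margin
#' detectable at the stated level and power,
#' \deqn{\delta = zz \sqrt{\lambda_m(D, \mathrm{cens}) / e}.}
#' Useful after a composite design, to see the precision delivered if D
#' turns out different from the design's peak.
#'
#' @param events number of events in the study (>= 1).
#' @param d the value of D at which to evaluate the precision.
#' @inheritParams events_significance
#' @return The achievable margin \eqn{\delta} as a single number.
#' @examples
#' ## 753 events, D turns out to be 2: detectable margin ~0.32
#' achieved_margin(753, d = 2, censoring = 0.10, alpha = 0.05, sided = 2,
#'                 power = 0.90)
#' @export
achieved_margin <- function(events, d, censoring = 0, alpha = 0.05,
                            sided = 2, power = 0.9) {
  if (!is.numeric(events) || length(events) != 1L || !is.finite(events) ||
      events < 1)
    stop("'events' must be a single number >= 1", call. = FALSE)
  lam <- lambda_from_model(d, censoring)
  zz <- zz_quantile(alpha, sided, power)
  zz * sqrt(lam$value / events)
}

#' Convert an event count to a patient count
#'
#' Under an expected censoring proportion `censoring`, a study observing `events`
#' events needs `ceiling(events / (1 - censoring))` patients.
#'
#' @param events number of events (>= 1).
#' @param censoring expected censoring proportion, in `[0, 1)`.
#' @return Integer patient count.
#' @examples
#' patients_from_events(392, 0.10)
#' @export
patients_from_events <- function(events, censoring = 0) {
  if (!is.numeric(events) || length(events) < 1L || any(!is.finite(events)) ||
      any(events < 1))
    stop("'events' must be >= 1", call. = FALSE)
  .check_cens(censoring)
  as.integer(ceiling(events / (1 - censoring)))
}

#' @export
print.samplesize_result <- function(x, ...) {
  hdr <- if (x$type == "significance") {
    sprintf("Significance-based design (%s-sided alpha = %g, power = %g, margin = %g)",
            if (identical(x$sided, 1L)) "one" else "two", x$alpha, x$power,
            x$margin)
  } else {
    sprintf("Precision-based design (%.0f%% CI half-width = %g)",
            100 * (1 - x$alpha), x$width)
  }
  cat(hdr, "\n")
  cat(sprintf("  events required:   %d   (unrounded %.4f)\n",
              x$events, x$raw_events))
  cat(sprintf("  patients required: %d   (censoring %g)\n",
              x$patients, x$censoring))
  cat(sprintf("  lambda = %.6g (%s); quantile sum = %.6g\n",
              x$lambda$value, x$lambda$source, x$zz))
  if (x$sigma1_sq > 0)
    cat(sprintf("  prior variance carried: sigma1^2 = %.6g (min %s %.4f)\n",
                x$sigma1_sq, if (x$type == "significance") "margin" else
                  "width", x$min_precision))
  invisible(x)
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("Composite design: absolute precision %g or %.0f%% of D\n",
              x$delta_abs, 100 * x$p))
  cat(sprintf("  curves cross at D = %g (lambda_m = %.6g)\n",
              x$peak_d, x$lambda$value))
  cat(sprintf("  maximum events required: %d (%d patients)\n",
              x$events, x$patients))
  invisible(x)
}
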