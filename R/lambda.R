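#' The structural constant lambda
#'
#' The sample size calculations in this package rest on a proportionality
#' assumption: for a given prognostic model with a fixed true discrimination
#' \eqn{D}, the variance of the estimated \eqn{D} is inversely proportional to
#' the number of events, so that \eqn{e \cdot \mathrm{var}(\hat D) = \lambda}
#' is a model- and disease-specific constant.  \code{lambda_from_study}
#' estimates \eqn{\lambda} from a previous study's reported standard error of
#' \eqn{D} and event count (\eqn{\lambda_s = e_1 \sigma_1^2});
#' \code{lambda_from_model} uses an empirical approximation in the target
#' \eqn{D} and the expected censoring proportion,
#' \deqn{\lambda_m = 2.66 + 1.26\,D^{1.9} - 1.65\,(D \cdot \mathrm{cens})^{1.3}.}
#'
#' The model-based approximation was fitted on simulated data spanning the
#' range of discrimination seen in published prognostic models (roughly
#' \eqn{0.1 \le D \le 3.5}) at low-to-moderate censoring; a warning (not an
#' error) is issued when the inputs fall outside that region.
#'
#' The unrounded value is always retained and used downstream; displayed
#' values are rounded only for printing.
#'
#' @param d1 the prior study's estimate of D (log hazard ratio scale).
#'   Optional; recorded for provenance only.
#' @param se_d1 standard error of `d1` in the prior study (> 0).  A bootstrap
#'   standard error is recommended, as the usual model-based standard error
#'   of D is biased downwards at high D.
#' @param events number of events observed in the prior study (>= 1).
#' @param censoring censoring proportion, in `[0, 1)`.  For
#'   `lambda_from_study` it is recorded for provenance only.
#' @param d target value of D for the planned study (>= 0).
#'
#' @return An object of class `"lambda_estimate"`: a list with elements
#'   `value` (the unrounded lambda), `source` (`"study"` or `"model"`), and
#'   the inputs it was computed from.
#'
#' @examples
#' ## prior study with 502 events and SE(D) = 0.09
#' lambda_from_study(se_d1 = 0.09, events = 502)
#'
#' ## no prior study: target D = 1.3, 10% censoring expected
#' lambda_from_model(d = 1.3, censoring = 0.10)
#' @seealso [events_significance()], [events_ci()], [prior_study()]
#' @export
lambda_from_study <- function(se_d1, events, d1 = NULL, censoring = NA) {
  if (!is.numeric(se_d1) || length(se_d1) != 1L || !is.finite(se_d1) ||
      se_d1 <= 0)
    stop("'se_d1' must be a single positive number", call. = FALSE)
  if (!is.numeric(events) || length(events) != 1L || !is.finite(events) ||
      events < 1 || events != round(events))
    stop("'events' must be a single integer >= 1", call. = FALSE)
  if (!is.na(censoring)) .check_cens(censoring)
  structure(
    list(value = events * se_d1^2, source = "study",
         d_input = d1, cens_input = censoring,
         se_d1 = se_d1, events = as.integer(events)),
    class = "lambda_estimate")
}

#' @rdname lambda_from_study
#' @export
lambda_from_model <- function(d, censoring = 0) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d))
    stop("'d' must be a single finite number", call. = FALSE)
  if (d < 0)
    stop("'d' must be non-negative", call. = FALSE)
  .check_cens(censoring)
  if (d > 3.5 || (d > 0 && d < 0.1) || censoring > 0.9)
    warning("lambda_from_model: inputs outside the region the approximation ",
            "was fitted on (0.1 <= d <= 3.5, censoring <= 0.9); ",
            "treat the result with caution", call. = FALSE)
  value <- 2.66 + 1.26 * d^1.9 - 1.65 * (d * censoring)^1.3
  structure(
    list(value = value, source = "model",
         d_input = d, cens_input = censoring),
    class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, digits = 2, ...) {
  src <- if (x$source == "study")
    sprintf("prior study (%d events, SE(D) = %g)", x$events, x$se_d1)
  else
    sprintf("model-based approximation (D = %g, censoring = %g)",
            x$d_input, x$cens_input)
  cat("lambda =", format(round(x$value, digits), nsmall = digits),
      sprintf("(unrounded %.6g)\n", x$value))
  cat("  source:", src, "\n")
  invisible(x)
}

#' Describe a prior study of the same prognostic model
#'
#' Bundles the quantities reported by a previous study that are needed by
#' the calculations that carry the prior study's uncertainty
#' ([events_with_prior()]) or that estimate lambda from it
#' ([lambda_from_study()]).
#'
#' @inheritParams lambda_from_study
#' @return An object of class `"prior_study"`.
#' @examples
#' prior_study(d1 = 1.01, se_d1 = 0.09, events = 502, censoring = 0.07)
#' @export
prior_study <- function(se_d1, events, d1 = NULL, censoring = NA) {
  lam <- lambda_from_study(se_d1 = se_d1, events = events, d1 = d1,
                           censoring = censoring)  # validates inputs
  structure(
    list(d1 = d1, se_d1 = se_d1, events = as.integer(events),
         censoring = censoring, lambda = lam),
    class = "prior_study")
}

#' @export
print.prior_study <- function(x, ...) {
  cat("Prior study:", x$events, "events, SE(D) =", x$se_d1)
  if (!is.null(x$d1)) cat(", D =", x$d1)
  if (!is.na(x$censoring)) cat(", censoring =", x$censoring)
  cat("\n")
  cat(sprintf("  lambda_s = %.6g\n", x$lambda$value))
  invisible(x)
}

.check_cens <- function(censoring) {
  if (!is.numeric(censoring) || length(censoring) != 1L ||
      !is.finite(censoring) || censoring < 0 || censoring >= 1)
    stop("'censoring' must be a single proportion in [0, 1)", call. = FALSE)
  invisible(censoring)
}

.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop(sprintf("'%s' must be a single probability strictly inside (0, 1)",
                 name), call. = FALSE)
  invisible(p)
}
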