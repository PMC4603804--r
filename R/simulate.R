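#' Exponential censoring rate matching a target censoring proportion
#'
#' With event times generated by the proportional-hazards exponential model
#' (hazard \eqn{h_0 e^{\beta X}}, \eqn{X \sim N(0,1)}) and independent
#' exponential censoring at rate \eqn{\theta}, the probability that a
#' subject is censored is
#' \deqn{P(T_c < T_s) = E_X\left[\frac{\theta}{\theta + h_0
#'   e^{\beta X}}\right].}
#' This solves for \eqn{\theta} so that the marginal censoring probability
#' equals `censoring`, by numerical integration over the covariate
#' distribution and root finding on the log-rate scale.
#'
#' @param beta log hazard ratio per unit of the covariate.
#' @param censoring target censoring proportion in `[0, 1)`; 0 returns rate 0
#'   (no censoring).
#' @param baseline_hazard rate of the exponential baseline (default 1; D and
#'   the sample size calculations are invariant to the time scale).
#' @return The exponential censoring rate as a single number.
#' @export
censoring_rate_for_target <- function(beta, censoring, baseline_hazard = 1) {
  .check_cens(censoring)
  if (censoring == 0) return(0)
  cens_prob <- function(log_theta) {
    th <- exp(log_theta)
    stats::integrate(function(x)
      stats::dnorm(x) * th / (th + baseline_hazard * exp(beta * x)),
      -Inf, Inf)$value
  }
  f <- function(lt) cens_prob(lt) - censoring
  root <- stats::uniroot(f, lower = -30, upper = 30, extendInt = "upX",
                         tol = 1e-10)
  exp(root$root)
}

#' Simulate exponential survival data with a normal prognostic index
#'
#' Draws `n` subjects with covariate \eqn{X \sim N(0,1)} and event times
#' from the proportional-hazards exponential model by inverting the
#' cumulative hazard: \eqn{T_s = -\log(U)\,e^{-\beta X}/h_0} with
#' \eqn{U \sim U(0,1)}.  Censoring times are exponential with rate
#' `censoring_rate`, independent of \eqn{X}; the recorded time is
#' \eqn{\min(T_s, T_c)} with status 1 iff the event came first.  The
#' prognostic index is \eqn{\beta X}, so the true discrimination of the
#' generating model is \eqn{D = \beta\kappa}.
#'
#' @param n number of subjects.
#' @param beta log hazard ratio per unit of X (true D is `beta * kappa_d()`).
#' @param baseline_hazard exponential baseline rate.
#' @param censoring_rate exponential censoring rate; 0 means no censoring.
#'   See [censoring_rate_for_target()] to match a target censoring
#'   proportion.
#' @param seed optional RNG seed; omit to draw from the current stream.
#' @return A data frame with columns `time`, `status`, `pi` and attribute
#'   `true_d`.
#' @examples
#' dat <- draw_survival_times(200, beta = 1, seed = 1)
#' attr(dat, "true_d")   # 1.596
#' @export
draw_survival_times <- function(n, beta, baseline_hazard = 1,
                                censoring_rate = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (!is.finite(beta)) stop("'beta' must be finite", call. = FALSE)
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be > 0",
                                 call. = FALSE)
  if (censoring_rate < 0) stop("'censoring_rate' must be >= 0",
                               call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  u <- stats::runif(n)
  ts <- -log(u) * exp(-beta * x) / baseline_hazard
  tc <- if (censoring_rate > 0) stats::rexp(n, censoring_rate) else
    rep(Inf, n)
  out <- data.frame(time = pmin(ts, tc),
                    status = as.integer(ts <= tc),
                    pi = beta * x)
  attr(out, "true_d") <- beta * .kappa
  out
}

#' Simulate a dataset with an exact event count and censoring proportion
#'
#' Sample size calculations and their Monte-Carlo validation are phrased in
#' events, so the simulator must deliver datasets with exactly the requested
#' number of events and censored records.  An oversampled pool of
#' \eqn{2\,e/(1-\mathrm{cens})} records is generated at a censoring rate
#' solved to match the target proportion ([censoring_rate_for_target()]);
#' exactly `events` failure records and `round(events/(1-censoring)) - events`
#' censored records are then drawn at random from the pool.  If the pool
#' falls short the generation is retried with a doubled pool, a bounded
#' number of times.
#'
#' @param events required number of events (>= 2).
#' @param censoring required censoring proportion in `[0, 1)`.
#' @param beta log hazard ratio of the generating model; alternatively give
#'   `d`, the true D, from which `beta = d / kappa_d()`.
#' @param d true D of the generating model (used when `beta` is missing).
#' @param baseline_hazard exponential baseline rate.
#' @param seed optional RNG seed.
#' @param max_tries regeneration attempts before giving up.
#' @return A data frame with columns `time`, `status`, `pi`; attributes
#'   `true_d`, `target_events`, `target_censoring`.
#' @examples
#' dat <- exact_event_dataset(events = 100, censoring = 0.25, d = 1.6,
#'                            seed = 7)
#' sum(dat$status)   # exactly 100
#' @export
exact_event_dataset <- function(events, censoring, beta = NULL, d = NULL,
                                baseline_hazard = 1, seed = NULL,
                                max_tries = 6L) {
  if (!is.numeric(events) || length(events) != 1L || events < 2 ||
      events != round(events))
    stop("'events' must be a single integer >= 2", call. = FALSE)
  .check_cens(censoring)
  if (is.null(beta)) {
    if (is.null(d)) stop("supply 'beta' or 'd'", call. = FALSE)
    beta <- d / .kappa
  }
  if (!is.null(seed)) set.seed(seed)
  total <- round(events / (1 - censoring))
  n_cens <- total - events
  rate <- censoring_rate_for_target(beta, censoring, baseline_hazard)
  pool_mult <- 2
  for (try in seq_len(max_tries)) {
    pool <- draw_survival_times(ceiling(pool_mult * total), beta,
                                baseline_hazard, rate)
    ev_idx <- which(pool$status == 1L)
    cn_idx <- which(pool$status == 0L)
    if (length(ev_idx) >= events && length(cn_idx) >= n_cens) {
      keep <- c(ev_idx[sample.int(length(ev_idx), events)],
                if (n_cens > 0) cn_idx[sample.int(length(cn_idx), n_cens)])
      out <- pool[keep[sample.int(length(keep))], , drop = FALSE]  # shuffle
      rownames(out) <- NULL
      attr(out, "true_d") <- beta * .kappa
      attr(out, "target_events") <- as.integer(events)
      attr(out, "target_censoring") <- censoring
      return(out)
    }
    pool_mult <- pool_mult * 2
  }
  stop("could not assemble the requested event/censoring structure after ",
       max_tries, " attempts", call. = FALSE)
}
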