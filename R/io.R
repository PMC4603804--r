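#' Read a survival sample from delimited text
#'
#' Reads a CSV or TSV file (extension-detected, or set `sep`) with one row
#' per subject and returns a validated data frame with columns `time`,
#' `status` and, when available, `pi`.  Lines starting with `#` (the
#' metadata header written by [write_survival_sample()]) are skipped.
#'
#' @param file path to the delimited file.
#' @param time,status,pi names of the corresponding columns in the file.
#' @param covariates optional character vector of covariate column names to
#'   carry through (for [estimate_d()]'s `x` argument when no prognostic
#'   index column exists).
#' @param sep field separator; default chosen from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A data frame with columns `time`, `status`, optionally `pi`, and
#'   any requested covariate columns.
#' @export
read_survival_sample <- function(file, time = "time", status = "status",
                                 pi = "pi", covariates = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c(time, status, covariates)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- data.frame(time = raw[[time]], status = raw[[status]])
  has_pi <- pi %in% names(raw)
  if (has_pi) out$pi <- raw[[pi]]
  for (cv in covariates) out[[cv]] <- raw[[cv]]
  .check_sample(out$time, out$status, min_events = 0L)
  if (anyNA(out)) stop("missing values after load", call. = FALSE)
  out
}

#' Write a survival sample as delimited text
#'
#' Writes the data as CSV preceded by `#`-prefixed metadata lines echoing
#' the generating parameters (true D, target event count and censoring when
#' the sample came from [exact_event_dataset()] or [draw_survival_times()]).
#'
#' @param x data frame with columns `time`, `status` and optionally `pi`.
#' @param file output path.
#' @param meta named list of extra metadata to record; attributes `true_d`,
#'   `target_events`, `target_censoring` of `x` are included automatically.
#' @return `file`, invisibly.
#' @export
write_survival_sample <- function(x, file, meta = list()) {
  auto <- list(true_d = attr(x, "true_d"),
               target_events = attr(x, "target_events"),
               target_censoring = attr(x, "target_censoring"))
  meta <- c(meta, auto[!vapply(auto, is.null, logical(1L))])
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(file)
}

#' Sample size table over a grid of D and censoring values
#'
#' The model-based lambda makes it cheap to tabulate required study sizes
#' over plausible ranges of the target D and the censoring proportion — the
#' recommended way to plan when either is uncertain.  Each grid cell
#' reports the lambda, the required events and the required patients for
#' the chosen design.
#'
#' @param d vector of target D values.
#' @param censoring vector of censoring proportions.
#' @param width CI half-width for a precision-based grid (exactly one of
#'   `width` / `margin`).
#' @param margin significance margin for a significance-based grid.
#' @inheritParams events_significance
#' @return A data frame with columns `d`, `censoring`, `lambda_m`,
#'   `raw_events`, `events`, `patients`.
#' @examples
#' grid_report(d = c(1.1, 1.3, 1.5), censoring = 0.10, width = 0.2)
#' @export
grid_report <- function(d, censoring, width = NULL, margin = NULL,
                        alpha = 0.05, sided = 2, power = 0.9) {
  if (is.null(width) == is.null(margin))
    stop("give exactly one of 'width' or 'margin'", call. = FALSE)
  if (length(d) < 1L || length(censoring) < 1L)
    stop("'d' and 'censoring' must be non-empty", call. = FALSE)
  grid <- expand.grid(d = d, censoring = censoring,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lam <- lambda_from_model(grid$d[i], grid$censoring[i])
    res <- if (!is.null(width))
      events_ci(lam, width, alpha, grid$censoring[i])
    else
      events_significance(lam, margin, alpha, sided, power,
                          grid$censoring[i])
    data.frame(d = grid$d[i], censoring = grid$censoring[i],
               lambda_m = lam$value, raw_events = res$raw_events,
               events = res$events, patients = res$patients)
  })
  do.call(rbind, rows)
}

#' Recommend a calculation given what the user has
#'
#' Encodes the decision flow for choosing among the calculation families:
#' the model-based calculations (significance `B2` / precision `D2`) are
#' recommended in most cases because they allow ranges of D and censoring
#' to be explored; the study-based pair (`B1`/`D1`) is preferred when a
#' reliable previous study of the same model exists and the intent is
#' validation — in which case lambda should be built from a bootstrap
#' standard error of D.  When no value of D is available at all, a published
#' c-index can be converted via [c_to_d()]; failing that, D = 1.4 (the mean
#' across a large collection of published prognostic models) is a suggested
#' fallback.
#'
#' @param has_prior is a reliable previous study of the same model
#'   available?
#' @param use_prior should it drive the calculation (validation intent)?
#' @param framing `"precision"` (CI half-width) or `"significance"`.
#' @param have_d is a target value of D available (directly or via a prior
#'   study)?
#' @param have_c is a published c-index available instead?
#' @return A list with elements `calculation` (one of `"B1"`, `"B2"`,
#'   `"D1"`, `"D2"`), `default_d` (`NA` unless the 1.4 fallback applies)
#'   and `notes` (character vector of caveats).
#' @examples
#' decision_flow(has_prior = FALSE, framing = "precision")
#' @export
decision_flow <- function(has_prior = FALSE, use_prior = has_prior,
                          framing = c("precision", "significance"),
                          have_d = TRUE, have_c = FALSE) {
  framing <- match.arg(framing)
  notes <- character()
  default_d <- NA_real_
  if (has_prior && use_prior) {
    calc <- if (framing == "significance") "B1" else "D1"
    notes <- c(notes, paste(
      "use a bootstrap estimate of the standard error of D from the prior",
      "study to form lambda_s; the default model-based standard error is",
      "biased downwards, especially for D >= 2"))
  } else {
    calc <- if (framing == "significance") "B2" else "D2"
    if (!have_d) {
      if (have_c) {
        notes <- c(notes, "convert the published c-index to D with c_to_d()")
      } else {
        default_d <- 1.4
        notes <- c(notes, paste(
          "no value of D available: D = 1.4 (mean over a large collection",
          "of published prognostic models) is used as a fallback; treat",
          "the resulting size as indicative only"))
      }
    }
    notes <- c(notes, paste(
      "model-based lambda: consider a grid of plausible D and censoring",
      "values (grid_report) rather than a single point"))
  }
  list(calculation = calc, default_d = default_d, notes = notes)
}
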