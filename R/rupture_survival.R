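#' Cumulative rupture probability (Kaplan-Meier)
#'
#' Estimates the cumulative probability of a bridging rupture as a function
#' of time within the pulling step, 1 - S(t) with S the Kaplan-Meier
#' survival estimate. Cycles whose bridge outlasts the pulling step are
#' right-censored at the step duration; without censoring the curve equals
#' the empirical CDF of the lifetimes.
#'
#' @param records classified \code{cycle_records}; rows with a finite
#'   \code{rupture_time_s} are used (Class I cycles, which rupture at time 0,
#'   may be excluded upstream by subsetting on \code{event_class}).
#' @param pull_duration_s censoring time; defaults to the records'
#'   \code{pull_duration_s} column.
#' @return object of class \code{rupture_curve}: list with \code{time_s}
#'   (event-time grid), \code{cum_prob}, \code{n_events}, \code{n_censored}
#'   and the underlying \code{survival::survfit} object.
#' @export
#' @examples
#' recs <- data.frame(dz0_um = -0.3, dz_end_um = 0,
#'                    rupture_time_s = c(10, 20, 30), censored = FALSE,
#'                    pull_duration_s = 180, cycle = 1:3, bead_id = "b")
#' rc <- rupture_survival(recs)
#' cumulative_rupture_probability(rc, 25)  # 2/3
rupture_survival <- function(records, pull_duration_s = NULL) {
  stopifnot(is.data.frame(records),
            all(c("rupture_time_s", "censored") %in% names(records)))
  if (nrow(records) == 0L) stop("no cycles to analyse")
  tt <- records$rupture_time_s
  cens <- records$censored
  if (!is.null(pull_duration_s)) tt[cens] <- pull_duration_s
  ok <- is.finite(tt)
  tt <- tt[ok]; cens <- cens[ok]
  if (!length(tt)) stop("no usable rupture times")
  fit <- survival::survfit(survival::Surv(tt, !cens) ~ 1)
  structure(list(time_s = fit$time,
                 cum_prob = 1 - fit$surv,
                 n_events = sum(!cens),
                 n_censored = sum(cens),
                 survfit = fit),
            class = "rupture_curve")
}

#' Evaluate a cumulative rupture curve at arbitrary times
#'
#' Right-continuous step-function evaluation of the Kaplan-Meier cumulative
#' rupture probability.
#'
#' @param curve a \code{rupture_curve}.
#' @param at_s times (s).
#' @return cumulative rupture probabilities in [0, 1].
#' @export
cumulative_rupture_probability <- function(curve, at_s) {
  stopifnot(inherits(curve, "rupture_curve"))
  vapply(at_s, function(t0) {
    i <- which(curve$time_s <= t0)
    if (!length(i)) 0 else curve$cum_prob[max(i)]
  }, numeric(1))
}

#' @export
print.rupture_curve <- function(x, ...) {
  cat(sprintf("Cumulative rupture curve: %d events, %d censored\n",
              x$n_events, x$n_censored))
  if (length(x$time_s))
    cat(sprintf("  reaches %.3f at t = %.1f s\n",
                max(x$cum_prob), max(x$time_s)))
  invisible(x)
}

#' @export
plot.rupture_curve <- function(x, xlab = "Time (s)",
                               ylab = "Cumulative rupture probability", ...) {
  plot(c(0, x$time_s), c(0, x$cum_prob), type = "s", ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
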