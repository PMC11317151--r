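#' Estimate a 1D diffusion constant from MSD curves
#'
#' Fits the linear law MSD = 2 D dt + b to the first \code{fit_lags}
#' non-zero lags of each trajectory's time-averaged MSD by weighted least
#' squares (weights = pair counts); the intercept b absorbs static
#' localization noise. Per-trajectory estimates are aggregated to
#' mean +/- SEM, the headline statistic; the fit to the ensemble
#' (pair-weighted) MSD is also reported. Negative fitted D values are kept
#' and flagged, never clipped.
#'
#' @param trajs a single trajectory/\code{msd_curve} or a list of them.
#' @param fit_lags number of non-zero lags used in the fit (default 5).
#' @param line_time_s passed to \code{\link{compute_msd}} when raw
#'   trajectories are given.
#' @param boundaries optional tether end coordinates (um) enabling the
#'   boundary-exclusion MSD of \code{\link{compute_msd}}; trajectories left
#'   without enough usable lags after exclusion are dropped from the
#'   per-trajectory aggregate.
#' @param margin_factor see \code{\link{compute_msd}}.
#' @return object of class \code{diffusion_fit} with elements
#'   \code{d_um2_s} (ensemble fit), \code{intercept_um2},
#'   \code{per_trajectory_d}, \code{mean_d}, \code{sem_d}, \code{n_traj},
#'   \code{fit_lags}, \code{negative_d} (quality flag), \code{ensemble_msd}.
#' @export
#' @examples
#' msd <- structure(data.frame(lag_s = 0:5 * 0.0224,
#'                             msd_um2 = 2 * 3.9 * (0:5) * 0.0224,
#'                             n_pairs = 100 - 0:5),
#'                  class = c("msd_curve", "data.frame"))
#' coef(estimate_diffusion(msd))
estimate_diffusion <- function(trajs, fit_lags = 5, line_time_s = NULL,
                               boundaries = NULL, margin_factor = 1.5) {
  .chk_num(fit_lags, "fit_lags", 1)
  if (inherits(trajs, "msd_curve") || is.data.frame(trajs)) trajs <- list(trajs)
  d_margin <- NULL
  if (!is.null(boundaries)) {
    # shared first pass: pooled raw lag-1 MSD sizes the exclusion margins,
    # so no trajectory's own noise feeds back into its pair selection
    raw1 <- lapply(trajs, function(x)
      if (inherits(x, "msd_curve")) x[x$lag_s > 0, ][1, ] else {
        cv <- compute_msd(x, max_lag = 1, line_time_s = line_time_s)
        cv[cv$lag_s > 0, ][1, ]
      })
    w <- vapply(raw1, function(r) r$n_pairs, numeric(1))
    m1 <- vapply(raw1, function(r) r$msd_um2, numeric(1))
    dt1 <- vapply(raw1, function(r) r$lag_s, numeric(1))
    ok <- is.finite(m1) & w > 0
    d_margin <- sum(m1[ok] * w[ok]) / sum(w[ok]) / (2 * stats::median(dt1[ok]))
  }
  curves <- lapply(trajs, function(x)
    if (inherits(x, "msd_curve")) x else
      compute_msd(x, line_time_s = line_time_s, boundaries = boundaries,
                  margin_factor = margin_factor, d_margin_um2_s = d_margin))

  fit_one <- function(cv) {
    use <- cv[cv$lag_s > 0 & !is.na(cv$msd_um2) & cv$n_pairs > 0, ,
              drop = FALSE]
    if (nrow(use) < fit_lags)
      stop(sprintf("only %d usable lags; need %d", nrow(use), fit_lags))
    use <- use[seq_len(fit_lags), , drop = FALSE]
    fit <- lm(msd_um2 ~ lag_s, data = use, weights = use$n_pairs)
    c(d = unname(coef(fit)[2]) / 2, b = unname(coef(fit)[1]))
  }

  per_list <- lapply(curves, function(cv)
    tryCatch(fit_one(cv), error = function(e) NULL))
  usable <- !vapply(per_list, is.null, logical(1))
  if (!any(usable)) stop("no trajectory had enough usable lags to fit")
  if (length(curves) > 1 && !all(usable))
    warning(sprintf("%d of %d trajectories dropped (too few usable lags)",
                    sum(!usable), length(curves)))
  per <- do.call(rbind, per_list[usable])
  colnames(per) <- c("d", "b")
  ens <- fit_one(aggregate_msd(curves))
  d_list <- per[, "d"]
  structure(list(d_um2_s = ens[["d"]],
                 intercept_um2 = ens[["b"]],
                 per_trajectory_d = d_list,
                 mean_d = mean(d_list),
                 sem_d = if (length(d_list) > 1) sd(d_list) / sqrt(length(d_list))
                         else NA_real_,
                 n_traj = length(d_list),
                 fit_lags = fit_lags,
                 negative_d = any(d_list < 0),
                 ensemble_msd = aggregate_msd(curves)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, digits = 3, ...) {
  cat(sprintf("1D diffusion estimate from %d trajectory(ies), first %d lags\n",
              x$n_traj, x$fit_lags))
  cat(sprintf("  per-trajectory mean D = %.*g +/- %.*g um^2/s (mean +/- SEM)\n",
              digits, x$mean_d, digits, x$sem_d))
  cat(sprintf("  ensemble-MSD fit:  D = %.*g um^2/s, intercept %.*g um^2\n",
              digits, x$d_um2_s, digits, x$intercept_um2))
  if (x$negative_d)
    cat("  warning: at least one per-trajectory D is negative\n")
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(d_um2_s = object$d_um2_s, intercept_um2 = object$intercept_um2)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  structure(list(fit = object,
                 quartiles = quantile(object$per_trajectory_d,
                                      c(0.25, 0.5, 0.75))),
            class = "summary.diffusion_fit")
}

#' @export
print.summary.diffusion_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-trajectory D quartiles (um^2/s):\n")
  print(x$quartiles)
  invisible(x)
}

#' @export
plot.diffusion_fit <- function(x, ...) {
  msd <- x$ensemble_msd
  plot(msd$lag_s, msd$msd_um2,
       xlab = expression(Delta * t ~ "(s)"),
       ylab = expression(MSD ~ "(" * mu * m^2 * ")"), ...)
  abline(x$intercept_um2, 2 * x$d_um2_s, lty = 2)
  legend("topleft", bty = "n",
         legend = sprintf("D = %.3g um^2/s", x$d_um2_s))
  invisible(x)
}
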