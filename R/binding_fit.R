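#' Fit an equilibrium binding isotherm
#'
#' Nonlinear least-squares fit of signal = s_free + (s_bound - s_free) *
#' f(T; Kd) over (Kd, s_free, s_bound), with f the hyperbolic or
#' depletion-aware quadratic model (\code{\link{fraction_bound}}).
#' Levenberg-Marquardt optimisation with data-driven starting values; a
#' seeded residual-resampling bootstrap yields percentile confidence limits
#' for Kd. A weak-binding flag is raised when the fitted Kd exceeds the
#' highest titrant concentration (the curve never approaches saturation, as
#' for constructs whose binding is too weak for a reliable Kd).
#'
#' @param data an \code{\link{isotherm}}, or a data.frame with columns
#'   \code{conc_nM} and \code{signal}. At least 6 points spanning at least
#'   one decade of concentration are required.
#' @param model \code{"hyperbolic"} (the simple binding model, default) or
#'   \code{"quadratic"}.
#' @param readout \code{"anisotropy"} or \code{"quench"}; taken from the
#'   isotherm when present. Informational (the fitted form is identical; a
#'   quench readout has s_bound < s_free).
#' @param probe_nM probe concentration for the quadratic model; taken from
#'   the isotherm when present.
#' @param n_boot bootstrap resamples for the Kd confidence interval
#'   (default 1000; 0 disables).
#' @param seed integer RNG seed for the bootstrap.
#' @return object of class \code{binding_fit}.
#' @export
#' @examples
#' iso <- simulate_isotherm(66)
#' fit <- fit_isotherm(iso, n_boot = 0)
#' coef(fit)
fit_isotherm <- function(data, model = c("hyperbolic", "quadratic"),
                         readout = NULL, probe_nM = NULL,
                         n_boot = 1000, seed = 1) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data),
            all(c("conc_nM", "signal") %in% names(data)))
  if (is.null(readout))
    readout <- attr(data, "readout") %||% "anisotropy"
  if (is.null(probe_nM))
    probe_nM <- attr(data, "probe_nM") %||% 5
  conc <- data$conc_nM
  sig <- data$signal
  ok <- is.finite(conc) & is.finite(sig)
  conc <- conc[ok]; sig <- sig[ok]
  if (length(conc) < 6)
    stop("need at least 6 titration points")
  pos <- conc[conc > 0]
  if (length(pos) < 2 || max(pos) / min(pos) < 10)
    stop("titration must span at least one decade of concentration")

  fit_once <- function(conc, sig) {
    s_free0 <- sig[which.min(conc)]
    s_bound0 <- sig[which.max(conc)]
    half <- (s_free0 + s_bound0) / 2
    kd0 <- tryCatch(
      approx(sig, conc, xout = half, ties = mean)$y,
      error = function(e) NA_real_)
    if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(pos)
    df <- data.frame(conc = conc, sig = sig)
    fit <- minpack.lm::nlsLM(
      sig ~ s_free + (s_bound - s_free) *
        fraction_bound(conc, kd, probe_nM, model),
      data = df,
      start = list(kd = kd0, s_free = s_free0, s_bound = s_bound0),
      lower = c(kd = 1e-9, s_free = -Inf, s_bound = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    fit
  }

  fit <- tryCatch(fit_once(conc, sig), error = function(e)
    stop("isotherm fit did not converge: ", conditionMessage(e),
         call. = FALSE))
  est <- coef(fit)
  fitted_sig <- predict(fit)
  res <- sig - fitted_sig
  rmse <- sqrt(mean(res^2))

  ci <- c(NA_real_, NA_real_)
  boot_kd <- numeric(0)
  if (n_boot > 0) {
    boot_kd <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        sig_b <- fitted_sig + sample(res, length(res), replace = TRUE)
        out <- tryCatch(coef(fit_once(conc, sig_b))[["kd"]],
                        error = function(e) NA_real_)
        out
      }, numeric(1))
    })
    boot_kd <- boot_kd[is.finite(boot_kd)]
    if (length(boot_kd) >= 10)
      ci <- unname(quantile(boot_kd, c(0.025, 0.975)))
  }

  structure(list(kd_nM = unname(est[["kd"]]),
                 signal_free = unname(est[["s_free"]]),
                 signal_bound = unname(est[["s_bound"]]),
                 model = model, readout = readout, probe_nM = probe_nM,
                 ci_low = ci[1], ci_high = ci[2], n_boot = length(boot_kd),
                 rmse = rmse,
                 weak_binding = unname(est[["kd"]]) > max(conc),
                 data = data.frame(conc_nM = conc, signal = sig,
                                   fitted = fitted_sig),
                 nls = fit),
            class = "binding_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binding_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Binding isotherm fit (%s model, %s readout)\n",
              x$model, x$readout))
  cat(sprintf("  Kd = %.*g nM", digits, x$kd_nM))
  if (is.finite(x$ci_low))
    cat(sprintf("  [95%% bootstrap CI %.*g - %.*g, %d resamples]",
                digits, x$ci_low, digits, x$ci_high, x$n_boot))
  cat("\n")
  cat(sprintf("  signal: free %.*g, bound %.*g; RMSE %.3g\n",
              digits, x$signal_free, digits, x$signal_bound, x$rmse))
  if (x$weak_binding)
    cat("  WARNING: fitted Kd exceeds the highest titrant concentration;\n",
        "  binding too weak for a reliable Kd at this titration design\n")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd_nM = object$kd_nM, signal_free = object$signal_free,
    signal_bound = object$signal_bound)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc_nM else newdata$conc_nM
  f <- fraction_bound(conc, object$kd_nM, object$probe_nM, object$model)
  predict_signal(f, object$signal_free, object$signal_bound)
}

#' @export
residuals.binding_fit <- function(object, ...) {
  object$data$signal - object$data$fitted
}

#' @export
summary.binding_fit <- function(object, ...) {
  s <- summary(object$nls)
  structure(list(fit = object, nls_summary = s), class = "summary.binding_fit")
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying nonlinear least squares fit:\n")
  print(x$nls_summary)
  invisible(x)
}

#' @export
plot.binding_fit <- function(x, log = "x", ...) {
  d <- x$data
  pos <- d$conc_nM > 0
  grid <- 10^seq(log10(min(d$conc_nM[pos])), log10(max(d$conc_nM)),
                 length.out = 200)
  plot(d$conc_nM[pos], d$signal[pos], log = log,
       xlab = "[titrant] (nM)", ylab = "Signal", ...)
  lines(grid, predict(x, data.frame(conc_nM = grid)), lty = 2)
  legend("bottomright", bty = "n",
         legend = sprintf("Kd = %.3g nM (%s)", x$kd_nM, x$model))
  invisible(x)
}
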