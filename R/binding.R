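#' Equilibrium fraction of probe bound
#'
#' Two non-cooperative single-site models of the bound fraction of a
#' labelled probe at total titrant concentration T:
#' \describe{
#'   \item{hyperbolic}{f = T / (T + Kd), valid when the probe is far below
#'     Kd (no ligand depletion).}
#'   \item{quadratic}{depletion-aware closed form for total probe P:
#'     f = ((T + P + Kd) - sqrt((T + P + Kd)^2 - 4 T P)) / (2 P).}
#' }
#' Both are monotone in T, map T = 0 to 0 and converge to each other as the
#' probe concentration goes to zero.
#'
#' @param titrant_nM total titrant (protein) concentration, nM (>= 0,
#'   vectorised). Monomer units.
#' @param kd_nM dissociation constant, nM (> 0).
#' @param probe_nM total labelled probe concentration, nM (quadratic only).
#' @param model \code{"hyperbolic"} or \code{"quadratic"}.
#' @return fraction bound in [0, 1].
#' @export
#' @examples
#' fraction_bound(66, 66)                         # 0.5
#' fraction_bound(66, 66, probe_nM = 5, model = "quadratic")  # ~0.4905
fraction_bound <- function(titrant_nM, kd_nM, probe_nM = 5,
                           model = c("hyperbolic", "quadratic")) {
  model <- match.arg(model)
  if (any(titrant_nM < 0)) stop("concentrations must be non-negative")
  .chk_num(kd_nM, "kd_nM", 0, strict = TRUE)
  if (model == "hyperbolic") {
    titrant_nM / (titrant_nM + kd_nM)
  } else {
    .chk_num(probe_nM, "probe_nM", 0, strict = TRUE)
    s <- titrant_nM + probe_nM + kd_nM
    (s - sqrt(s^2 - 4 * titrant_nM * probe_nM)) / (2 * probe_nM)
  }
}

#' Signal from fraction bound
#'
#' Linear two-state readout: signal = signal_free + (signal_bound -
#' signal_free) * f, for both anisotropy (signal rises on binding) and
#' fluorescence quenching (signal_bound < signal_free).
#'
#' @param f fraction bound in [0, 1] (vectorised).
#' @param signal_free,signal_bound the two plateaus.
#' @return signal values.
#' @export
predict_signal <- function(f, signal_free, signal_bound) {
  if (any(f < -1e-12 | f > 1 + 1e-12)) stop("fraction bound must be in [0, 1]")
  signal_free + (signal_bound - signal_free) * f
}

#' Binding isotherm container
#'
#' @param titrant_nM titrant concentrations (nM, >= 0).
#' @param signal measured signal (anisotropy or fluorescence intensity).
#' @param signal_sd optional per-point standard deviations.
#' @param probe_nM labelled probe concentration (nM); 5 nM in the assays
#'   emulated here.
#' @param readout \code{"anisotropy"} or \code{"quench"}.
#' @return data.frame of class \code{isotherm} with attributes
#'   \code{probe_nM} and \code{readout}.
#' @export
isotherm <- function(titrant_nM, signal, signal_sd = NULL, probe_nM = 5,
                     readout = c("anisotropy", "quench")) {
  readout <- match.arg(readout)
  if (any(titrant_nM < 0)) stop("concentrations must be non-negative")
  stopifnot(length(titrant_nM) == length(signal))
  out <- data.frame(conc_nM = titrant_nM, signal = signal)
  if (!is.null(signal_sd)) out$signal_sd <- signal_sd
  attr(out, "probe_nM") <- probe_nM
  attr(out, "readout") <- readout
  class(out) <- c("isotherm", "data.frame")
  out
}

#' Simulate a binding isotherm with known ground truth
#'
#' Generates signal values from the chosen binding model plus i.i.d.
#' Gaussian noise. With \code{noise_sd = 0} the exact model values are
#' returned. Default plateaus emulate fluorescence anisotropy
#' (0.08 free, 0.20 bound) or quenching (1.0 free, 0.35 bound).
#'
#' @param kd_nM ground-truth dissociation constant (nM).
#' @param concentrations_nM titrant concentrations (nM).
#' @param model \code{"hyperbolic"} or \code{"quadratic"}.
#' @param readout \code{"anisotropy"} or \code{"quench"}.
#' @param probe_nM labelled probe concentration (nM).
#' @param signal_free,signal_bound plateaus; defaults depend on the readout.
#' @param noise_sd Gaussian noise sd (same units as the signal).
#' @param seed integer RNG seed (required when \code{noise_sd > 0}).
#' @return an \code{\link{isotherm}} with attribute \code{truth} recording
#'   the generating parameters.
#' @export
simulate_isotherm <- function(kd_nM,
                              concentrations_nM = 10^seq(0, log10(2000),
                                                         length.out = 12),
                              model = c("hyperbolic", "quadratic"),
                              readout = c("anisotropy", "quench"),
                              probe_nM = 5,
                              signal_free = NULL, signal_bound = NULL,
                              noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  readout <- match.arg(readout)
  if (is.null(signal_free))
    signal_free <- if (readout == "anisotropy") 0.08 else 1.0
  if (is.null(signal_bound))
    signal_bound <- if (readout == "anisotropy") 0.20 else 0.35
  f <- fraction_bound(concentrations_nM, kd_nM, probe_nM, model)
  sig <- predict_signal(f, signal_free, signal_bound)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("an explicit 'seed' is required when noise_sd > 0")
    sig <- sig + with_local_seed(seed, rnorm(length(sig), sd = noise_sd))
  }
  out <- isotherm(concentrations_nM, sig, probe_nM = probe_nM,
                  readout = readout)
  attr(out, "truth") <- list(kd_nM = kd_nM, model = model,
                             signal_free = signal_free,
                             signal_bound = signal_bound,
                             noise_sd = noise_sd)
  out
}
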