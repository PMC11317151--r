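#' Double-stranded DNA tether model
#'
#' Describes the elastic tether held in the magnetic tweezers: a worm-like
#' chain of given contour length and persistence length at temperature
#' \code{temperature}, attached to a superparamagnetic bead.
#'
#' The default contour length corresponds to a 4292 bp central duplex at
#' 0.34 nm/bp (about 1.46 um). Persistence length 45 nm and T = 298 K are
#' standard dsDNA values under physiological ionic strength.
#'
#' @param contour_length_um contour length in um (> 0).
#' @param persistence_length_nm persistence length in nm (> 0).
#' @param temperature temperature in kelvin (> 0).
#' @param bead_radius_um bead radius in um (> 0); sets the Stokes drag used
#'   for the Ornstein-Uhlenbeck bead dynamics.
#' @return object of class \code{tether_model}.
#' @export
#' @examples
#' tm <- tether_model()
#' wlc_extension(4, tm)
tether_model <- function(contour_length_um = 4292 * 0.34e-3,
                         persistence_length_nm = 45,
                         temperature = 298,
                         bead_radius_um = 0.5) {
  .chk_num(contour_length_um, "contour_length_um", 0, strict = TRUE)
  .chk_num(persistence_length_nm, "persistence_length_nm", 0, strict = TRUE)
  .chk_num(temperature, "temperature", 0, strict = TRUE)
  .chk_num(bead_radius_um, "bead_radius_um", 0, strict = TRUE)
  structure(list(contour_length_um = contour_length_um,
                 persistence_length_nm = persistence_length_nm,
                 temperature = temperature,
                 bead_radius_um = bead_radius_um),
            class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat("Worm-like chain tether\n")
  cat(sprintf("  contour length:     %.3f um\n", x$contour_length_um))
  cat(sprintf("  persistence length: %.1f nm\n", x$persistence_length_nm))
  cat(sprintf("  temperature:        %.1f K\n", x$temperature))
  cat(sprintf("  bead radius:        %.2f um\n", x$bead_radius_um))
  invisible(x)
}

#' Worm-like chain force at a given fractional extension
#'
#' Marko-Siggia interpolation
#' \deqn{F = (k_B T / L_p) (1/(4(1-x/L)^2) - 1/4 + x/L).}
#'
#' @param rel_ext fractional extension x/L in [0, 1).
#' @param model a \code{\link{tether_model}}.
#' @return force in pN (vectorised over \code{rel_ext}).
#' @export
wlc_force <- function(rel_ext, model = tether_model()) {
  stopifnot(inherits(model, "tether_model"))
  if (any(rel_ext < 0 | rel_ext >= 1))
    stop("fractional extension must lie in [0, 1)")
  kT_over_lp <- kBT(model$temperature) * 1000 / model$persistence_length_nm # pN
  kT_over_lp * (1 / (4 * (1 - rel_ext)^2) - 0.25 + rel_ext)
}

#' Worm-like chain equilibrium extension at a given force
#'
#' Numerically inverts the Marko-Siggia interpolation for the fractional
#' extension at force \code{force_pN}, then scales by the contour length.
#' Monotonically increasing in force; always below the contour length.
#'
#' @param force_pN applied force in pN (>= 0; vectorised).
#' @param model a \code{\link{tether_model}}.
#' @param contour_length_um optional contour length override in um (used for
#'   tethers shortened by bridging loops); defaults to the model's value.
#' @return extension in um.
#' @export
#' @examples
#' wlc_extension(0, tether_model())       # 0
#' wlc_extension(4, tether_model())       # ~0.92 of the contour
wlc_extension <- function(force_pN, model = tether_model(),
                          contour_length_um = model$contour_length_um) {
  stopifnot(inherits(model, "tether_model"))
  if (any(force_pN < 0)) stop("force must be non-negative")
  .chk_num(contour_length_um, "contour_length_um", 0)
  contour_length_um * vapply(force_pN, function(f) {
    wlc_relative_extension(f, model)
  }, numeric(1))
}

#' Fractional worm-like chain extension at a given force
#'
#' @inheritParams wlc_extension
#' @return x/L in [0, 1).
#' @export
wlc_relative_extension <- function(force_pN, model = tether_model()) {
  stopifnot(inherits(model, "tether_model"))
  if (length(force_pN) != 1L) {
    return(vapply(force_pN, wlc_relative_extension, numeric(1), model = model))
  }
  if (force_pN < 0) stop("force must be non-negative")
  if (force_pN == 0) return(0)
  f <- function(x) wlc_force(x, model) - force_pN
  uniroot(f, c(0, 1 - 1e-9), tol = 1e-12)$root
}
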