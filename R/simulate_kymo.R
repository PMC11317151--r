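#' Kymograph simulation configuration
#'
#' Parameters of the synthetic confocal line-scan experiment: fluorescent
#' particles diffusing in one dimension along a tethered DNA, imaged by
#' repeated line scans. Defaults match the instrument settings of the
#' tracking assay: 100 nm pixels, 22.4 ms per line, a ~25 kb tether
#' (~8.6 um) and the measured diffusion constant 3.9 um^2/s.
#'
#' @param diffusion_um2_s diffusion constant D (um^2/s, >= 0).
#' @param dna_length_um tether length (um, > 0); particles are confined to
#'   [0, dna_length_um] by reflection.
#' @param line_time_s time per scanned line (s).
#' @param pixel_size_um pixel size (um).
#' @param psf_sigma_um Gaussian point-spread-function sigma (um). A warning
#'   is issued when narrower than half a pixel (localization becomes
#'   pixel-limited).
#' @param photons_per_line mean photons emitted per particle per line.
#' @param background_photons mean background photons per pixel per line.
#' @param bleach_rate_s single-step photobleaching rate (1/s, >= 0).
#' @param n_particles number of particles.
#' @param duration_s scan duration (s).
#' @return list of class \code{kymo_config}.
#' @export
kymo_config <- function(diffusion_um2_s = 3.9,
                        dna_length_um = 25427 * 0.34e-3,
                        line_time_s = 0.0224,
                        pixel_size_um = 0.1,
                        psf_sigma_um = 0.15,
                        photons_per_line = 200,
                        background_photons = 2,
                        bleach_rate_s = 0,
                        n_particles = 1,
                        duration_s = 2.5) {
  .chk_num(diffusion_um2_s, "diffusion_um2_s", 0)
  for (nm in c("dna_length_um", "line_time_s", "pixel_size_um",
               "psf_sigma_um", "photons_per_line", "duration_s"))
    .chk_num(get(nm), nm, 0, strict = TRUE)
  .chk_num(background_photons, "background_photons", 0)
  .chk_num(bleach_rate_s, "bleach_rate_s", 0)
  .chk_num(n_particles, "n_particles", 1)
  if (psf_sigma_um < pixel_size_um / 2)
    warning("PSF sigma below half a pixel: localization will be pixel-limited")
  structure(list(diffusion_um2_s = diffusion_um2_s,
                 dna_length_um = dna_length_um, line_time_s = line_time_s,
                 pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
                 photons_per_line = photons_per_line,
                 background_photons = background_photons,
                 bleach_rate_s = bleach_rate_s,
                 n_particles = as.integer(n_particles),
                 duration_s = duration_s),
            class = "kymo_config")
}

# reflect positions into [0, L] (billiard reflection, handles large steps)
reflect_into <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

#' Simulate a confocal kymograph with diffusing particles
#'
#' Particles perform reflected 1D Brownian motion on [0, L]; each scanned
#' line records, per pixel, Poisson photon counts whose expectation is the
#' particle's Gaussian point-spread profile integrated over the pixel, plus
#' a uniform background. Photobleaching terminates a particle's emission
#' after an exponential time. Ground-truth positions are returned at line
#' resolution.
#'
#' @param config a \code{\link{kymo_config}}.
#' @param seed integer RNG seed (required).
#' @param noise logical; FALSE returns the expected (Poisson-mean) image.
#' @return object of class \code{kymograph}: list with \code{intensity}
#'   (lines x pixels matrix), \code{line_time_s}, \code{pixel_size_um} and
#'   \code{truth} (data.frame \code{particle_id, line, time_s, position_um,
#'   emitting}).
#' @export
#' @examples
#' ky <- simulate_kymograph(kymo_config(duration_s = 0.5), seed = 1)
#' dim(ky$intensity)
simulate_kymograph <- function(config = kymo_config(), seed, noise = TRUE) {
  stopifnot(inherits(config, "kymo_config"))
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  n_lines <- max(2L, as.integer(round(config$duration_s / config$line_time_s)))
  n_px <- as.integer(ceiling(config$dna_length_um / config$pixel_size_um))
  # pixel-centre convention: pixel j (1-based) spans [(j-1)*px, j*px),
  # centre at (j - 0.5) * px ... coordinate of pixel 0 centre is 0 under the
  # 0-based convention used for positions, i.e. position_um = px_index0 * px.
  edges <- (seq_len(n_px + 1L) - 1.5) * config$pixel_size_um

  out <- with_local_seed(seed, {
    # trajectories
    step_sd <- sqrt(2 * config$diffusion_um2_s * config$line_time_s)
    pos <- matrix(0, n_lines, config$n_particles)
    pos[1, ] <- runif(config$n_particles, 0, config$dna_length_um)
    if (n_lines > 1) {
      steps <- matrix(rnorm((n_lines - 1L) * config$n_particles, sd = step_sd),
                      n_lines - 1L, config$n_particles)
      for (i in 2:n_lines)
        pos[i, ] <- reflect_into(pos[i - 1L, ] + steps[i - 1L, ],
                                 config$dna_length_um)
    }
    # bleaching times
    bleach_t <- if (config$bleach_rate_s > 0)
      rexp(config$n_particles, config$bleach_rate_s) else rep(Inf, config$n_particles)
    time_lines <- (seq_len(n_lines) - 1L) * config$line_time_s
    emitting <- outer(time_lines, bleach_t, `<`)

    img <- matrix(config$background_photons, n_lines, n_px)
    s <- config$psf_sigma_um
    for (p in seq_len(config$n_particles)) {
      mu <- pos[, p]
      # expected photons per pixel: N * (Phi(e_{j+1}) - Phi(e_j))
      cdf <- pnorm(outer(mu, edges, function(m, e) (e - m) / s))
      prof <- config$photons_per_line * (cdf[, -1L, drop = FALSE] -
                                           cdf[, -(n_px + 1L), drop = FALSE])
      prof[!emitting[, p], ] <- 0
      img <- img + prof
    }
    if (noise) img[] <- rpois(length(img), lambda = img)
    list(img = img, pos = pos, emitting = emitting, time_lines = time_lines)
  })

  truth <- data.frame(
    particle_id = rep(seq_len(config$n_particles), each = n_lines),
    line = rep(seq_len(n_lines), config$n_particles),
    time_s = rep(out$time_lines, config$n_particles),
    position_um = as.vector(out$pos),
    emitting = as.vector(out$emitting)
  )
  structure(list(intensity = out$img,
                 line_time_s = config$line_time_s,
                 pixel_size_um = config$pixel_size_um,
                 truth = truth, config = config, seed = seed),
            class = "kymograph")
}

#' Construct a kymograph object from an intensity grid
#'
#' @param intensity lines x pixels matrix of non-negative intensities.
#' @param line_time_s time per line (s).
#' @param pixel_size_um pixel size (um).
#' @return object of class \code{kymograph}.
#' @export
kymograph <- function(intensity, line_time_s, pixel_size_um) {
  stopifnot(is.matrix(intensity), all(intensity >= 0))
  .chk_num(line_time_s, "line_time_s", 0, strict = TRUE)
  .chk_num(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  structure(list(intensity = intensity, line_time_s = line_time_s,
                 pixel_size_um = pixel_size_um, truth = NULL),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d lines x %d pixels (%.1f ms/line, %.0f nm/px)\n",
              nrow(x$intensity), ncol(x$intensity),
              1000 * x$line_time_s, 1000 * x$pixel_size_um))
  invisible(x)
}
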