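#' Localize fluorescent particles on each kymograph line
#'
#' Per scanned line, candidate peaks are pixels exceeding a noise-adaptive
#' threshold (median + \code{min_snr} * robust sigma, Poisson-aware) that are
#' local maxima; each candidate is refined to a sub-pixel centre by an
#' iterative Gaussian-weighted centroid over a window of +/- 3 PSF sigma,
#' with a localization uncertainty of approximately
#' psf_sigma / sqrt(photons). Flat lines yield no detections.
#'
#' @param kymo a \code{\link{kymograph}}.
#' @param min_snr detection threshold in robust noise sigmas above the
#'   background (default 5).
#' @param psf_sigma_um assumed PSF sigma used for the refinement window
#'   (defaults to the simulation value when present, else 1.5 pixels).
#' @param min_separation_um minimum distance between two detections on a
#'   line; closer candidates are merged keeping the brighter.
#' @return data.frame \code{line, time_s, position_um, photons,
#'   uncertainty_um}, positions under the 0-based pixel-centre convention
#'   (pixel 0 centre is coordinate 0).
#' @export
localize_lines <- function(kymo, min_snr = 5, psf_sigma_um = NULL,
                           min_separation_um = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  if (!length(img)) stop("empty intensity grid")
  px <- kymo$pixel_size_um
  if (is.null(psf_sigma_um))
    psf_sigma_um <- if (!is.null(kymo$config)) kymo$config$psf_sigma_um else 1.5 * px
  if (is.null(min_separation_um)) min_separation_um <- 3 * psf_sigma_um
  s_px <- psf_sigma_um / px
  w <- max(2L, as.integer(ceiling(3 * s_px)))
  n_px <- ncol(img)

  refine <- function(line_int, peak_px) {
    # iterative Gaussian-weighted centroid around the peak (0-based centre)
    lo <- max(1L, peak_px - w); hi <- min(n_px, peak_px + w)
    xs <- (lo:hi) - 1L
    bg <- median(line_int)
    I <- pmax(line_int[lo:hi] - bg, 0)
    if (sum(I) <= 0) return(NULL)
    mu <- sum(xs * I) / sum(I)
    for (it in 1:3) {
      wts <- exp(-(xs - mu)^2 / (2 * s_px^2))
      denom <- sum(wts * I)
      if (denom <= 0) break
      mu <- sum(xs * wts * I) / denom
    }
    photons <- sum(I)
    list(mu_px = mu, photons = photons,
         unc_um = psf_sigma_um / sqrt(max(photons, 1)))
  }

  res <- vector("list", nrow(img))
  for (i in seq_len(nrow(img))) {
    line_int <- img[i, ]
    bg <- median(line_int)
    sig <- max(mad(line_int), sqrt(max(bg, 1)))  # Poisson floor
    thr <- bg + min_snr * sig
    cand <- which(line_int > thr)
    if (!length(cand)) next
    # local maxima among candidates
    is_max <- vapply(cand, function(j) {
      l <- if (j > 1L) line_int[j - 1L] else -Inf
      r <- if (j < n_px) line_int[j + 1L] else -Inf
      line_int[j] >= l && line_int[j] >= r
    }, logical(1))
    cand <- cand[is_max]
    if (!length(cand)) next
    fits <- lapply(cand, function(j) refine(line_int, j))
    keep <- !vapply(fits, is.null, logical(1))
    fits <- fits[keep]
    if (!length(fits)) next
    pos <- vapply(fits, function(f) f$mu_px, numeric(1)) * px
    phot <- vapply(fits, function(f) f$photons, numeric(1))
    unc <- vapply(fits, function(f) f$unc_um, numeric(1))
    # merge detections closer than the separation limit (keep brighter)
    o <- order(pos)
    pos <- pos[o]; phot <- phot[o]; unc <- unc[o]
    keep <- rep(TRUE, length(pos))
    if (length(pos) > 1L) {
      for (j in 2:length(pos)) {
        prev <- max(which(keep[1:(j - 1L)]))
        if (pos[j] - pos[prev] < min_separation_um) {
          if (phot[j] > phot[prev]) keep[prev] <- FALSE else keep[j] <- FALSE
        }
      }
    }
    res[[i]] <- data.frame(line = i, time_s = (i - 1L) * kymo$line_time_s,
                           position_um = pos[keep], photons = phot[keep],
                           uncertainty_um = unc[keep])
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(line = integer(0), time_s = numeric(0),
                      position_um = numeric(0), photons = numeric(0),
                      uncertainty_um = numeric(0))
  rownames(out) <- NULL
  out
}

#' Link per-line detections into trajectories
#'
#' Greedy nearest-neighbour linking with a hard displacement gate
#' (\code{max_step_um}) and gap closing over up to \code{max_gap} missed
#' lines. Trajectories are truncated to \code{max_duration_s} (2.5 s, to
#' homogenise the statistical sample) and those shorter than
#' \code{min_length} detections are dropped. Kymographs where more than two
#' particles are present concurrently (more than 2 detections on over
#' \code{multi_frac} of detection-bearing lines) are rejected, mirroring the
#' rule that DNA molecules carrying more than two particles are discarded.
#'
#' @param detections output of \code{\link{localize_lines}}.
#' @param line_time_s line time (s), used for the time axis and truncation.
#' @param max_step_um linking gate; defaults to
#'   5 * sqrt(2 * D_prior * line_time) with \code{d_prior_um2_s}.
#' @param max_gap maximum number of consecutive missed lines bridged.
#' @param max_duration_s truncation length (s).
#' @param min_length minimum detections per kept trajectory.
#' @param d_prior_um2_s prior diffusion constant for the default gate.
#' @param multi_frac tolerated fraction of lines with > 2 detections before
#'   the whole kymograph is discarded.
#' @return list of trajectories (data.frames \code{particle_id, line,
#'   time_s, position_um, uncertainty_um}); attribute \code{discarded} is
#'   TRUE (with an empty list) when the kymograph was rejected.
#' @export
link_trajectories <- function(detections, line_time_s,
                              max_step_um = NULL, max_gap = 3,
                              max_duration_s = 2.5, min_length = 10,
                              d_prior_um2_s = 5, multi_frac = 0.02) {
  stopifnot(is.data.frame(detections))
  if (is.null(max_step_um))
    max_step_um <- 5 * sqrt(2 * d_prior_um2_s * line_time_s)
  empty <- structure(list(), discarded = FALSE)
  if (!nrow(detections)) return(empty)
  det_lines <- split(detections, detections$line)
  n_multi <- sum(vapply(det_lines, nrow, integer(1)) > 2L)
  if (n_multi > max(2L, multi_frac * length(det_lines))) {
    res <- structure(list(), discarded = TRUE)
    return(res)
  }

  tracks <- list()     # finished
  active <- list()     # each: list(rows = data.frame, last_line, last_pos)
  for (ln in sort(unique(detections$line))) {
    d <- det_lines[[as.character(ln)]]
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(a) ln - a$last_line > max_gap + 1L,
                      logical(1))
      tracks <- c(tracks, lapply(active[stale], function(a) a$rows))
      active <- active[!stale]
    }
    unmatched <- rep(TRUE, nrow(d))
    if (length(active) && nrow(d)) {
      # greedy: repeatedly take the globally closest (track, detection) pair
      cost <- outer(vapply(active, function(a) a$last_pos, numeric(1)),
                    d$position_um, function(a, b) abs(a - b))
      free_tr <- rep(TRUE, length(active))
      repeat {
        cc <- cost
        cc[!free_tr, ] <- Inf
        cc[, !unmatched] <- Inf
        m <- which.min(cc)
        if (!length(m) || !is.finite(cc[m])) break
        i <- (m - 1L) %% length(active) + 1L
        j <- (m - 1L) %/% length(active) + 1L
        if (cc[m] > max_step_um * (ln - active[[i]]$last_line)) break
        active[[i]]$rows <- rbind(active[[i]]$rows, d[j, , drop = FALSE])
        active[[i]]$last_line <- ln
        active[[i]]$last_pos <- d$position_um[j]
        free_tr[i] <- FALSE
        unmatched[j] <- FALSE
        if (!any(free_tr) || !any(unmatched)) break
      }
    }
    for (j in which(unmatched)) {
      active[[length(active) + 1L]] <- list(rows = d[j, , drop = FALSE],
                                            last_line = ln,
                                            last_pos = d$position_um[j])
    }
  }
  tracks <- c(tracks, lapply(active, function(a) a$rows))

  max_lines <- as.integer(floor(max_duration_s / line_time_s)) + 1L
  tracks <- lapply(tracks, function(tr) {
    tr <- tr[order(tr$line), , drop = FALSE]
    tr <- tr[tr$line - tr$line[1] < max_lines, , drop = FALSE] # truncate 2.5 s
    tr
  })
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= min_length]
  tracks <- lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]
    data.frame(particle_id = k, line = tr$line, time_s = tr$time_s,
               position_um = tr$position_um,
               uncertainty_um = if ("uncertainty_um" %in% names(tr))
                 tr$uncertainty_um else NA_real_)
  })
  structure(tracks, discarded = FALSE)
}

#' Time-averaged mean square displacement of a trajectory
#'
#' MSD(k dt) computed over all ordered (overlapping) pairs at each lag,
#' using only pairs whose line spacing equals the lag (gaps are respected).
#' Lag 0 (MSD = 0) is included.
#'
#' When the particle diffuses on a finite tether, displacements that reflect
#' off the tether ends depress the MSD. Supplying \code{boundaries} enables
#' the standard correction by exclusion: at each lag k, pairs whose starting
#' position lies within \code{margin_factor * sqrt(2 * d_margin * k * dt)} of
#' either boundary are discarded, so the retained pairs are effectively
#' free-diffusion pairs. \code{d_margin_um2_s} should come from a first-pass
#' estimate that is shared across trajectories (as
#' \code{\link{estimate_diffusion}} arranges); when NULL the trajectory's own
#' raw MSD sets the margin, which is adequate for ensemble curves but couples
#' the exclusion to the noise of a single short trajectory. With the default
#' \code{boundaries = NULL} all pairs are used.
#'
#' @param traj data.frame with \code{line} (or \code{time_s}) and
#'   \code{position_um}; at least \code{min_points} positions.
#' @param max_lag maximum lag in lines (default: third of the span).
#' @param line_time_s line time (s); inferred from \code{time_s} if absent.
#' @param min_points minimum number of positions.
#' @param boundaries optional length-2 vector: tether end coordinates (um).
#' @param margin_factor boundary-exclusion margin in units of the expected
#'   root-MSD at each lag (default 1.5).
#' @param d_margin_um2_s diffusion constant used to size the exclusion
#'   margins (um^2/s); see Details.
#' @return object of class \code{msd_curve}: data.frame \code{lag_s, msd_um2,
#'   n_pairs}.
#' @export
compute_msd <- function(traj, max_lag = NULL, line_time_s = NULL,
                        min_points = 10, boundaries = NULL,
                        margin_factor = 1.5, d_margin_um2_s = NULL) {
  stopifnot(is.data.frame(traj), "position_um" %in% names(traj))
  if (nrow(traj) < min_points)
    stop(sprintf("trajectory has %d positions; need at least %d",
                 nrow(traj), min_points))
  if (!"line" %in% names(traj)) {
    dt <- median(diff(traj$time_s))
    traj$line <- as.integer(round(traj$time_s / dt)) + 1L
    if (is.null(line_time_s)) line_time_s <- dt
  }
  if (is.null(line_time_s)) {
    line_time_s <- if ("time_s" %in% names(traj) && nrow(traj) > 1)
      median(diff(traj$time_s) / diff(traj$line)) else 1
  }
  span <- max(traj$line) - min(traj$line)
  if (is.null(max_lag)) max_lag <- max(1L, span %/% 3L)
  pos <- rep(NA_real_, span + 1L)
  pos[traj$line - min(traj$line) + 1L] <- traj$position_um
  lags <- 0:max_lag
  msd_at <- function(k, interior) {
    x0 <- pos[1:(length(pos) - k)]
    d <- pos[(1 + k):length(pos)] - x0
    ok <- !is.na(d)
    if (!is.null(interior)) ok <- ok & x0 >= interior[1] & x0 <= interior[2]
    d <- d[ok]
    list(msd = if (length(d)) mean(d^2) else NA_real_, n = length(d))
  }
  msd <- numeric(length(lags)); npairs <- integer(length(lags))
  msd[1] <- 0; npairs[1] <- sum(!is.na(pos))
  for (k in seq_len(max_lag)) {
    if (is.null(boundaries)) {
      r <- msd_at(k, NULL)
    } else {
      expected_msd <- if (!is.null(d_margin_um2_s)) {
        2 * d_margin_um2_s * k * line_time_s
      } else {
        raw <- msd_at(k, NULL)
        max(raw$msd, 0)
      }
      m <- margin_factor * sqrt(expected_msd)
      interior <- c(min(boundaries) + m, max(boundaries) - m)
      r <- if (interior[1] < interior[2]) msd_at(k, interior)
           else list(msd = NA_real_, n = 0L)
    }
    npairs[k + 1L] <- r$n
    msd[k + 1L] <- r$msd
  }
  out <- data.frame(lag_s = lags * line_time_s, msd_um2 = msd,
                    n_pairs = npairs)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Ensemble (pair-weighted) MSD over several trajectories
#'
#' Averages squared displacements over all pairs of all trajectories at each
#' lag, weighting each trajectory by its pair count. Duplicating a
#' trajectory in the input leaves the result unchanged.
#'
#' @param trajs list of trajectories or of \code{msd_curve}s.
#' @param ... passed to \code{\link{compute_msd}}.
#' @return an \code{msd_curve}.
#' @export
aggregate_msd <- function(trajs, ...) {
  curves <- lapply(trajs, function(x)
    if (inherits(x, "msd_curve")) x else compute_msd(x, ...))
  lags <- sort(unique(unlist(lapply(curves, function(cv) cv$lag_s))))
  msd <- numeric(length(lags)); npairs <- numeric(length(lags))
  for (cv in curves) {
    i <- match(cv$lag_s, lags)
    ok <- !is.na(cv$msd_um2)
    msd[i[ok]] <- msd[i[ok]] + cv$msd_um2[ok] * cv$n_pairs[ok]
    npairs[i[ok]] <- npairs[i[ok]] + cv$n_pairs[ok]
  }
  out <- data.frame(lag_s = lags,
                    msd_um2 = ifelse(npairs > 0, msd / npairs, NA_real_),
                    n_pairs = npairs)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
plot.msd_curve <- function(x, xlab = expression(Delta * t ~ "(s)"),
                           ylab = expression(MSD ~ "(" * mu * m^2 * ")"), ...) {
  plot(x$lag_s, x$msd_um2, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
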