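#' Bridging ground-truth parameters for the bead simulator
#'
#' Governs the hidden bridging state machine of
#' \code{\link{simulate_bead_timecourse}}: during each low-force relaxation
#' step a bridge may form with probability \code{bridge_formation_prob}
#' (subject to at most \code{max_bridges} concurrent bridges), sequestering a
#' loop of contour drawn uniformly from \code{loop_size_range_um}. During
#' high force each active bridge ruptures after an exponentially distributed
#' holding time with mean \code{mean_lifetime_s}; bridges outlasting the
#' pulling step persist into later cycles (the memoryless clock restarts).
#'
#' @param bridge_formation_prob probability of forming one new bridge per
#'   relaxation step, in [0, 1].
#' @param mean_lifetime_s mean exponential rupture time at the pulling force
#'   (s, > 0).
#' @param loop_size_range_um length-2 range (um) of sequestered loop contour.
#' @param max_bridges maximum number of concurrent bridges (>= 1).
#' @return object of class \code{bridging_params}.
#' @export
bridging_params <- function(bridge_formation_prob = 0.7,
                            mean_lifetime_s = 26.3,
                            loop_size_range_um = c(0.1, 0.5),
                            max_bridges = 3) {
  .chk_num(bridge_formation_prob, "bridge_formation_prob", 0, 1)
  .chk_num(mean_lifetime_s, "mean_lifetime_s", 0, strict = TRUE)
  stopifnot(length(loop_size_range_um) == 2L,
            all(loop_size_range_um > 0),
            loop_size_range_um[1] <= loop_size_range_um[2])
  .chk_num(max_bridges, "max_bridges", 1)
  structure(list(bridge_formation_prob = bridge_formation_prob,
                 mean_lifetime_s = mean_lifetime_s,
                 loop_size_range_um = loop_size_range_um,
                 max_bridges = as.integer(max_bridges)),
            class = "bridging_params")
}

# Ornstein-Uhlenbeck samples with stationary sd `sd` and correlation time
# `tau_s`, sampled every `dt` seconds; starts from the stationary law.
ou_noise <- function(n, sd, tau_s, dt) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau_s)
  innov <- rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sd) # stationary start
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Stokes drag on the bead in pN.s/um (eta in Pa.s)
stokes_drag <- function(bead_radius_um, eta = 1e-3) {
  6 * pi * eta * bead_radius_um # N.s/m == pN.s/um numerically
}

#' Simulate transverse bead excursions of a tethered bead
#'
#' Overdamped Ornstein-Uhlenbeck motion of the bead transverse coordinate in
#' the inverted-pendulum regime: stationary variance k_B T z / F with corner
#' time gamma / (F / z) from Stokes drag. Used as the ground-truth input for
#' \code{\link{calibrate_force}}.
#'
#' @param n number of samples.
#' @param force_pN applied force (pN, > 0).
#' @param extension_um tether extension (um, > 0).
#' @param model a \code{\link{tether_model}} (temperature, bead radius).
#' @param rate_hz sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return numeric vector of transverse positions (um).
#' @export
simulate_transverse_positions <- function(n, force_pN, extension_um,
                                          model = tether_model(),
                                          rate_hz = 120, seed) {
  .chk_num(force_pN, "force_pN", 0, strict = TRUE)
  .chk_num(extension_um, "extension_um", 0, strict = TRUE)
  var_um2 <- kBT(model$temperature) * extension_um / force_pN
  tau <- stokes_drag(model$bead_radius_um) / (force_pN / extension_um)
  with_local_seed(seed, ou_noise(n, sqrt(var_um2), tau, 1 / rate_hz))
}

#' Simulate a magnetic-tweezers bead time course with bridging
#'
#' Generates the (time, extension, force) record of one bead across the
#' force-cycle protocol, together with the ground-truth log of every bridging
#' event. The tether extension follows the worm-like chain at the applied
#' force with an effective contour length shortened by every active bridge's
#' loop. Axial measurement noise is an Ornstein-Uhlenbeck process of
#' stationary standard deviation \code{z_noise_sd_um}; the transverse bead
#' coordinate (column \code{x_um}) obeys the pendulum relation
#' var(x) = k_B T z / F.
#'
#' @param protocol a \code{\link{force_protocol}}.
#' @param tether a \code{\link{tether_model}}.
#' @param bridging a \code{\link{bridging_params}}.
#' @param noise logical; FALSE yields the noiseless mean trace (and zero
#'   transverse excursions).
#' @param seed integer RNG seed (required; all randomness is local).
#' @param bead_id identifier copied into the output.
#' @param rate_hz sampling rate (Hz); the instrument records at 120 Hz.
#' @param z_noise_sd_um stationary sd of the axial noise (um).
#' @return list of class \code{bead_sim} with elements
#'   \describe{
#'     \item{timecourse}{data.frame \code{bead_id, time_s, z_um, force_pN,
#'       x_um}}
#'     \item{events}{ground-truth bridge log: \code{bridge_id, loop_um,
#'       formed_cycle, ruptured_cycle, rupture_time_s} (time within the
#'       rupturing pull step; NA when the bridge never ruptured)}
#'     \item{protocol, tether, bridging, seed}{inputs, for provenance}
#'   }
#' @export
#' @examples
#' sim <- simulate_bead_timecourse(force_protocol(n_cycles = 1),
#'                                 seed = 1, noise = FALSE)
#' head(sim$timecourse)
simulate_bead_timecourse <- function(protocol = force_protocol(),
                                     tether = tether_model(),
                                     bridging = bridging_params(),
                                     noise = TRUE,
                                     seed,
                                     bead_id = "bead1",
                                     rate_hz = 120,
                                     z_noise_sd_um = 0.005) {
  stopifnot(inherits(protocol, "force_protocol"),
            inherits(tether, "tether_model"),
            inherits(bridging, "bridging_params"))
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  if (nrow(protocol) == 0L || sum(protocol$duration_s) <= 0)
    stop("protocol must have positive total duration")
  if (bridging$loop_size_range_um[2] >= tether$contour_length_um)
    stop("loop sizes must lie within (0, contour length)")

  dt <- 1 / rate_hz
  n_steps <- nrow(protocol)
  n_per_step <- as.integer(round(protocol$duration_s * rate_hz))
  if (any(n_per_step < 1L)) stop("every protocol step must span >= 1 sample")
  offsets <- c(0L, cumsum(n_per_step))
  n_total <- offsets[n_steps + 1L]
  step_start_s <- protocol_step_starts(protocol)
  time_s <- numeric(n_total)
  force <- numeric(n_total)
  L_eff <- numeric(n_total) # effective contour at each sample

  # fractional WLC extension cached per distinct force
  relext_of <- local({
    cache <- new.env(parent = emptyenv())
    function(f) {
      key <- format(f, digits = 15)
      if (is.null(cache[[key]])) cache[[key]] <- wlc_relative_extension(f, tether)
      cache[[key]]
    }
  })

  L0 <- tether$contour_length_um

  run <- function() {
    # active bridges: data.frame id, loop
    active <- data.frame(id = integer(0), loop = numeric(0))
    events <- list()
    next_id <- 1L

    for (i in seq_len(n_steps)) {
      idx <- (offsets[i] + 1L):offsets[i + 1L]
      tl <- (seq_len(n_per_step[i]) - 1L) * dt
      time_s[idx] <<- step_start_s[i] + tl
      force[idx] <<- protocol$force_pN[i]
      L_step <- rep(L0 - sum(active$loop), n_per_step[i])

      if (protocol$phase[i] == "relax" &&
          nrow(active) < bridging$max_bridges &&
          runif(1) < bridging$bridge_formation_prob) {
        avail <- L0 - sum(active$loop)
        loop <- NA_real_
        for (try in 1:100) {
          cand <- runif(1, bridging$loop_size_range_um[1],
                        bridging$loop_size_range_um[2])
          if (cand < avail - 0.05 * L0) { loop <- cand; break }
        }
        if (is.na(loop))
          stop("could not draw a loop size within the available contour")
        t_form <- runif(1, 0, protocol$duration_s[i])
        L_step <- L_step - loop * (tl >= t_form)
        events[[next_id]] <- list(bridge_id = next_id, loop_um = loop,
                                  formed_cycle = protocol$cycle[i],
                                  ruptured_cycle = NA_integer_,
                                  rupture_time_s = NA_real_)
        active <- rbind(active, data.frame(id = next_id, loop = loop))
        next_id <- next_id + 1L
      }

      if (protocol$phase[i] == "pull" && nrow(active) > 0L) {
        taus <- rexp(nrow(active), rate = 1 / bridging$mean_lifetime_s)
        for (j in seq_len(nrow(active))) {
          if (taus[j] < protocol$duration_s[i]) {
            L_step <- L_step + active$loop[j] * (tl >= taus[j])
            ev <- events[[active$id[j]]]
            ev$ruptured_cycle <- protocol$cycle[i]
            ev$rupture_time_s <- taus[j]
            events[[active$id[j]]] <- ev
          }
        }
        keep <- taus >= protocol$duration_s[i]
        active <- active[keep, , drop = FALSE]
      }

      L_eff[idx] <<- L_step
    }
    events
  }

  sim <- with_local_seed(seed, {
    events <- run()
    # noiseless mean extension
    z <- numeric(n_total)
    for (i in seq_len(n_steps)) {
      idx <- (offsets[i] + 1L):offsets[i + 1L]
      z[idx] <- relext_of(protocol$force_pN[i]) * L_eff[idx]
    }
    x <- numeric(n_total)
    if (noise) {
      gamma <- stokes_drag(tether$bead_radius_um)
      for (i in seq_len(n_steps)) {
        idx <- (offsets[i] + 1L):offsets[i + 1L]
        f <- protocol$force_pN[i]
        zbar <- mean(z[idx])
        tau_c <- gamma / (f / max(zbar, 1e-6))
        z[idx] <- z[idx] + ou_noise(length(idx), z_noise_sd_um, tau_c, dt)
        x[idx] <- ou_noise(length(idx),
                           sqrt(kBT(tether$temperature) * max(zbar, 1e-6) / f),
                           tau_c, dt)
      }
    }
    list(z = z, x = x, events = events)
  })

  events_df <- if (length(sim$events)) {
    do.call(rbind, lapply(sim$events, function(e)
      data.frame(bridge_id = e$bridge_id, loop_um = e$loop_um,
                 formed_cycle = e$formed_cycle,
                 ruptured_cycle = e$ruptured_cycle,
                 rupture_time_s = e$rupture_time_s)))
  } else {
    data.frame(bridge_id = integer(0), loop_um = numeric(0),
               formed_cycle = integer(0), ruptured_cycle = integer(0),
               rupture_time_s = numeric(0))
  }

  structure(list(
    timecourse = data.frame(bead_id = bead_id, time_s = time_s,
                            z_um = sim$z, force_pN = force, x_um = sim$x,
                            stringsAsFactors = FALSE),
    events = events_df,
    protocol = protocol, tether = tether, bridging = bridging, seed = seed
  ), class = "bead_sim")
}

#' @export
print.bead_sim <- function(x, ...) {
  cat(sprintf("Simulated bead time course '%s': %d samples, %d cycle(s), %d bridge(s)\n",
              x$timecourse$bead_id[1], nrow(x$timecourse),
              max(x$protocol$cycle), nrow(x$events)))
  invisible(x)
}
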