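#' Transform absolute extension to relative extension
#'
#' Converts the absolute tether extension z to the relative extension
#' dz = z - baseline, where the baseline is the averaged extension during the
#' initial high-force step. dz = 0 means the molecule holds its initial
#' extension; dz < 0 indicates bridging-induced shortening, dz > 0
#' elongation. Removing the per-tether baseline suppresses the variability of
#' absolute extensions arising from different anchoring geometries.
#'
#' @param timecourse data.frame with columns \code{time_s}, \code{z_um} (and
#'   optionally \code{bead_id}, \code{force_pN}); or a \code{bead_sim}.
#' @param protocol the \code{\link{force_protocol}} that produced the trace;
#'   used to locate the initial step and the pulling steps.
#' @param baseline_um optional explicit baseline (um). Required when the
#'   trace does not cover the protocol's initial step.
#' @param baseline_window_s portion of the initial step averaged for the
#'   baseline (defaults to the whole step).
#' @return the input data.frame with columns \code{dz_um} and
#'   \code{baseline_um} added; class \code{c("bead_timecourse", "data.frame")}.
#' @export
compute_relative_extension <- function(timecourse, protocol = force_protocol(),
                                       baseline_um = NULL,
                                       baseline_window_s = NULL) {
  if (inherits(timecourse, "bead_sim")) timecourse <- timecourse$timecourse
  stopifnot(is.data.frame(timecourse),
            all(c("time_s", "z_um") %in% names(timecourse)))
  if (is.unsorted(timecourse$time_s, strictly = TRUE))
    stop("time must be strictly increasing")
  if (is.null(baseline_um)) {
    ini <- which(protocol$phase == "initial")[1]
    if (is.na(ini))
      stop("protocol has no initial step: supply an explicit 'baseline_um'")
    t0 <- protocol_step_starts(protocol)[ini]
    t1 <- t0 + if (is.null(baseline_window_s)) protocol$duration_s[ini]
               else min(baseline_window_s, protocol$duration_s[ini])
    sel <- timecourse$time_s >= t0 & timecourse$time_s < t1
    if (!any(sel))
      stop("trace does not cover the initial high-force step: ",
           "supply an explicit 'baseline_um'")
    baseline_um <- mean(timecourse$z_um[sel])
  }
  timecourse$baseline_um <- baseline_um
  timecourse$dz_um <- timecourse$z_um - baseline_um
  class(timecourse) <- c("bead_timecourse", "data.frame")
  timecourse
}

#' Extract per-cycle bridging features from a relative-extension trace
#'
#' For each pulling step of the protocol, computes the initial extension
#' dz0 (mean of the first \code{n_avg} samples), the final extension
#' dz_end (mean of the last \code{n_avg} samples), and the rupture time:
#' the elapsed time from the start of the pulling step until the relative
#' extension first re-enters the extended-molecule band
#' (\code{-threshold_um < dz < threshold_um}). Cycles that never re-enter the
#' band are right-censored at the pulling-step duration.
#'
#' An optional running-median pre-filter (window \code{smooth_window_s},
#' default 0.5 s) makes first-crossing detection robust on noisy traces; it
#' is off by default so that noiseless traces are analysed verbatim.
#'
#' @param timecourse output of \code{\link{compute_relative_extension}}.
#' @param protocol the \code{\link{force_protocol}}.
#' @param n_avg number of samples averaged for dz0 / dz_end (default 12).
#' @param threshold_um half-width of the extended-molecule band (um).
#' @param smooth logical; apply the running-median pre-filter before rupture
#'   detection (dz0/dz_end always use the raw samples).
#' @param smooth_window_s window of the pre-filter in seconds.
#' @return data.frame of class \code{cycle_records} with columns
#'   \code{bead_id, cycle, dz0_um, dz_end_um, rupture_time_s, censored,
#'   pull_duration_s}.
#' @export
extract_cycle_features <- function(timecourse, protocol = force_protocol(),
                                   n_avg = 12, threshold_um = 0.05,
                                   smooth = FALSE, smooth_window_s = 0.5) {
  stopifnot(is.data.frame(timecourse), "dz_um" %in% names(timecourse))
  .chk_num(n_avg, "n_avg", 1)
  .chk_num(threshold_um, "threshold_um", 0, strict = TRUE)
  idx_list <- pull_step_indices(timecourse$time_s, protocol)
  cycles <- protocol$cycle[protocol$phase == "pull"]
  bead <- if ("bead_id" %in% names(timecourse)) timecourse$bead_id[1] else "bead1"
  recs <- lapply(seq_along(idx_list), function(k) {
    idx <- idx_list[[k]]
    if (length(idx) < 2 * n_avg)
      stop(sprintf("pulling step %d has %d samples; need at least %d",
                   k, length(idx), 2 * n_avg))
    dz <- timecourse$dz_um[idx]
    tt <- timecourse$time_s[idx]
    dz0 <- mean(dz[seq_len(n_avg)])
    dz_end <- mean(dz[seq(length(dz) - n_avg + 1L, length(dz))])
    dz_det <- dz
    if (smooth) {
      dt <- median(diff(tt))
      k_win <- max(3L, as.integer(round(smooth_window_s / dt)))
      if (k_win %% 2L == 0L) k_win <- k_win + 1L
      if (k_win < length(dz)) dz_det <- stats::runmed(dz, k_win)
    }
    inband <- which(dz_det > -threshold_um & dz_det < threshold_um)
    pull_dur <- protocol$duration_s[protocol$phase == "pull"][k]
    if (length(inband)) {
      tau <- tt[inband[1]] - tt[1]
      cens <- FALSE
    } else {
      tau <- pull_dur
      cens <- TRUE
    }
    data.frame(bead_id = bead, cycle = cycles[k], dz0_um = dz0,
               dz_end_um = dz_end, rupture_time_s = tau, censored = cens,
               pull_duration_s = pull_dur, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  class(out) <- c("cycle_records", "data.frame")
  out
}

#' Classify per-cycle bridging events (Class I--V)
#'
#' Applies the event taxonomy to the per-cycle features of one bead, using
#' a band half-width of \code{threshold_um} (0.05 um):
#' \describe{
#'   \item{I}{no bridge: dz0 within the extended band.}
#'   \item{II}{bridged at the start (dz0 below the band) and fully ruptured
#'     by the end (dz_end within the band); the rupture time is the bridge
#'     lifetime.}
#'   \item{III}{partial rupture: both dz0 and dz_end below the band and
#'     dz_end - dz0 > threshold.}
#'   \item{IV}{stable bridge (dz_end - dz0 < threshold, still bridged)
#'     confined to a single cycle.}
#'   \item{V}{stable bridge persisting over two or more consecutive cycles.}
#' }
#' Boundary tie-breaks (the inequalities above are strict and leave
#' measure-zero gaps): |dz0| exactly equal to the threshold is Class I;
#' dz_end - dz0 exactly equal to the threshold is Class III. Elongation
#' cycles (dz0 above the band) are labelled \code{excluded}, as are -- by
#' default -- stable runs spanning every cycle of the record (bridges lasting
#' the entire experiment have unidentifiable kinetics).
#'
#' @param records \code{cycle_records} for a single bead (or several beads;
#'   runs are determined within each bead), ordered by cycle.
#' @param threshold_um band half-width (um).
#' @param exclude_full_runs drop stable runs spanning all cycles of a bead
#'   (labelled \code{excluded}) rather than calling them Class V.
#' @return the records with an \code{event_class} factor column (levels
#'   I, II, III, IV, V, excluded).
#' @export
classify_events <- function(records, threshold_um = 0.05,
                            exclude_full_runs = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("dz0_um", "dz_end_um", "cycle") %in% names(records)))
  if (anyNA(records$dz0_um) || anyNA(records$dz_end_um))
    stop("dz0 and dz_end must be present for every cycle")
  th <- threshold_um
  classify_bead <- function(df) {
    df <- df[order(df$cycle), , drop = FALSE]
    dz0 <- df$dz0_um; dze <- df$dz_end_um
    cls <- character(nrow(df))
    bridged <- dz0 < -th                         # |dz0| = th ties to I
    elong <- dz0 > th
    cls[!bridged & !elong] <- "I"
    cls[elong] <- "excluded"
    recovered <- dze >= -th                      # back in (or above) the band
    cls[bridged & recovered] <- "II"
    diff_ok <- (dze - dz0) >= th                 # tie (= th) to III
    cls[bridged & !recovered & diff_ok] <- "III"
    stable <- bridged & !recovered & !diff_ok
    # consecutive-run grouping of stable cycles
    if (any(stable)) {
      r <- rle(stable)
      pos <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
      for (j in seq_along(r$lengths)) {
        if (!r$values[j]) next
        run_idx <- pos[j]:(pos[j] + r$lengths[j] - 1L)
        lab <- if (r$lengths[j] >= 2L) "V" else "IV"
        if (exclude_full_runs && r$lengths[j] == nrow(df)) lab <- "excluded"
        cls[run_idx] <- lab
      }
    }
    df$event_class <- cls
    df
  }
  bead <- if ("bead_id" %in% names(records)) records$bead_id else "bead1"
  parts <- lapply(split(seq_len(nrow(records)), bead), function(i)
    classify_bead(records[i, , drop = FALSE]))
  out <- do.call(rbind, parts)
  out <- out[order(match(paste(out$bead_id, out$cycle),
                         paste(records$bead_id, records$cycle))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$event_class <- factor(out$event_class,
                            levels = c("I", "II", "III", "IV", "V", "excluded"))
  class(out) <- c("cycle_records", "data.frame")
  out
}

#' Per-class event frequencies
#'
#' Proportions of Class I--V events among classified cycles; excluded cycles
#' are reported separately and do not enter the denominator.
#'
#' @param records classified \code{cycle_records}.
#' @return list with \code{frequencies} (named numeric over I--V, summing to
#'   1 when any classified cycle exists), \code{counts}, \code{n_excluded}.
#' @export
class_frequencies <- function(records) {
  stopifnot("event_class" %in% names(records))
  cls <- records$event_class
  counts <- table(factor(cls, levels = c("I", "II", "III", "IV", "V")))
  n <- sum(counts)
  freqs <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, 5)
  list(frequencies = setNames(freqs, names(counts)),
       counts = setNames(as.integer(counts), names(counts)),
       n_excluded = sum(cls == "excluded", na.rm = TRUE))
}

#' Boxplot statistics of the initial length reductions
#'
#' Five-number summary used for the dz0 boxplots: quartiles (type 7),
#' median, whiskers at Q1 - 1.5 IQR and Q3 + 1.5 IQR, with the mean reported
#' separately.
#'
#' @param x numeric vector (typically dz0 of bridged cycles, um).
#' @return list with \code{mean, median, q1, q3, whisker_low, whisker_high,
#'   n, empty}; when \code{x} is empty all statistics are NA and
#'   \code{empty} is TRUE.
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x))
    return(list(mean = NA_real_, median = NA_real_, q1 = NA_real_,
                q3 = NA_real_, whisker_low = NA_real_, whisker_high = NA_real_,
                n = 0L, empty = TRUE))
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr,
       n = length(x), empty = FALSE)
}

#' Pooled, area-normalised histogram of relative extensions
#'
#' Pools every sample from every pulling step of every bead and bins the
#' relative extension dz. Heights are densities: the area under the
#' histogram is exactly 1.
#'
#' @param timecourses a \code{bead_timecourse} or list of them (each with
#'   \code{dz_um}).
#' @param protocol the \code{\link{force_protocol}}.
#' @param bin_width_um bin width (um, default 0.02).
#' @return object of class \code{dz_histogram}: list with \code{breaks},
#'   \code{mids}, \code{density}, \code{counts}, \code{bin_width_um},
#'   \code{n_beads}, \code{n_samples}.
#' @export
pooled_dz_histogram <- function(timecourses, protocol = force_protocol(),
                                bin_width_um = 0.02) {
  if (is.data.frame(timecourses)) timecourses <- list(timecourses)
  .chk_num(bin_width_um, "bin_width_um", 0, strict = TRUE)
  pooled <- unlist(lapply(timecourses, function(tc) {
    stopifnot("dz_um" %in% names(tc))
    idx <- unlist(pull_step_indices(tc$time_s, protocol))
    tc$dz_um[idx]
  }))
  if (!length(pooled)) stop("no pulling-step samples to pool")
  lo <- floor(min(pooled) / bin_width_um) * bin_width_um
  hi <- ceiling(max(pooled) / bin_width_um) * bin_width_um
  if (hi <= lo) hi <- lo + bin_width_um
  breaks <- seq(lo, hi, by = bin_width_um)
  h <- hist(pooled, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 counts = h$counts, bin_width_um = bin_width_um,
                 n_beads = length(timecourses), n_samples = length(pooled)),
            class = "dz_histogram")
}

#' @export
print.dz_histogram <- function(x, ...) {
  cat(sprintf("Relative-extension histogram: %d beads, %d samples, bin %.3f um, area %.6f\n",
              x$n_beads, x$n_samples, x$bin_width_um,
              sum(x$density * diff(x$breaks))))
  invisible(x)
}

#' @export
plot.dz_histogram <- function(x, xlab = expression(Delta * z ~ "(" * mu * "m)"),
                              ylab = "Probability density", main = NULL, ...) {
  plot(x$mids, x$density, type = "h", lwd = 3, xlab = xlab, ylab = ylab,
       main = main, ...)
  invisible(x)
}

#' Equipartition (inverted pendulum) force calibration
#'
#' Estimates the applied force from the Brownian transverse excursions of a
#' tethered bead: for a bead on a tether of extension z the transverse
#' stiffness is F/z, so by equipartition
#' \deqn{F = k_B T \, z / \mathrm{var}(x).}
#'
#' @param transverse_um transverse bead positions (um), at least 1000
#'   samples.
#' @param extension_um tether extension (um, > 0).
#' @param temperature temperature (K).
#' @return force in pN.
#' @export
#' @examples
#' # variance 1028.5 nm^2 at z = 1 um, 298 K -> ~4 pN
#' calibrate_force(rnorm(2000, sd = sqrt(1028.5e-6)), 1, 298)
calibrate_force <- function(transverse_um, extension_um, temperature = 298) {
  if (length(transverse_um) < 1000)
    stop("need at least 1000 transverse samples for calibration")
  .chk_num(extension_um, "extension_um", 0, strict = TRUE)
  v <- var(transverse_um) # unbiased sample variance
  if (v <= 0) stop("transverse positions have zero variance")
  kBT(temperature) * extension_um / v
}
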