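# CSV/plain-text interchange. Dialect everywhere: comma-separated, '.'
# decimal, UTF-8, mandatory header row. Lengths in um, times in s, forces in
# pN, concentrations in nM (stated in the column names).

#' Write / read a bead time course
#'
#' Columns \code{bead_id, time_s, z_um, force_pN} (plus \code{x_um},
#' \code{dz_um}, \code{baseline_um} when present).
#'
#' @param timecourse data.frame (or \code{bead_sim}).
#' @param path file path.
#' @return \code{read_bead_timecourse} returns the data.frame.
#' @export
write_bead_timecourse <- function(timecourse, path) {
  if (inherits(timecourse, "bead_sim")) timecourse <- timecourse$timecourse
  write.csv(timecourse, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_timecourse
#' @export
read_bead_timecourse <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bead_id", "time_s", "z_um")
  if (!all(need %in% names(df)))
    stop("bead time-course file must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' Write / read classified cycle records
#'
#' @param records \code{cycle_records} data.frame.
#' @param path file path.
#' @export
write_cycle_records <- function(records, path) {
  df <- as.data.frame(records)
  if ("event_class" %in% names(df)) df$event_class <- as.character(df$event_class)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycle_records
#' @export
read_cycle_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("event_class" %in% names(df))
    df$event_class <- factor(df$event_class,
                             levels = c("I", "II", "III", "IV", "V", "excluded"))
  class(df) <- c("cycle_records", "data.frame")
  df
}

#' Write / read a kymograph as a plain-text matrix
#'
#' Header comment lines carry the required attributes
#' (\code{# line_time_s = ...}, \code{# pixel_size_um = ...}); the body is a
#' whitespace-separated lines-by-pixels intensity matrix.
#'
#' @param kymo a \code{\link{kymograph}}.
#' @param path file path.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# line_time_s = %.17g", kymo$line_time_s),
               sprintf("# pixel_size_um = %.17g", kymo$pixel_size_um)), con)
  utils::write.table(kymo$intensity, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_attr <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(ln)) stop("kymograph file lacks attribute '", key, "'")
    as.numeric(sub(".*=\\s*", "", ln[1]))
  }
  m <- as.matrix(read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  kymograph(m, get_attr("line_time_s"), get_attr("pixel_size_um"))
}

#' Write / read trajectories
#'
#' Long-format CSV with columns \code{particle_id, line, time_s,
#' position_um, uncertainty_um}.
#'
#' @param trajs list of trajectory data.frames.
#' @param path file path.
#' @export
write_trajectories <- function(trajs, path) {
  df <- if (is.data.frame(trajs)) trajs else do.call(rbind, trajs)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  split(df, df$particle_id)
}

#' Write / read an isotherm
#'
#' Columns \code{conc_nM, signal} (plus \code{signal_sd} when present);
#' header comments carry \code{probe_nM} and \code{readout}.
#'
#' @param iso an \code{\link{isotherm}}.
#' @param path file path.
#' @export
write_isotherm <- function(iso, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# probe_nM = %.17g", attr(iso, "probe_nM") %||% 5),
               sprintf("# readout = %s", attr(iso, "readout") %||% "anisotropy")),
             con)
  utils::write.table(as.data.frame(iso), con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  hdr <- readLines(path, n = 5)
  hdr <- hdr[startsWith(hdr, "#")]
  probe <- as.numeric(sub(".*=\\s*", "",
                          grep("probe_nM", hdr, value = TRUE)[1]))
  readout <- trimws(sub(".*=\\s*", "",
                        grep("readout", hdr, value = TRUE)[1]))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1] <- sub("^X\\.+", "", names(df)[1])
  isotherm(df$conc_nM, df$signal, df$signal_sd,
           probe_nM = if (is.finite(probe)) probe else 5,
           readout = if (readout %in% c("anisotropy", "quench")) readout
                     else "anisotropy")
}

#' Write an MSD curve
#'
#' @param msd an \code{msd_curve}.
#' @param path file path.
#' @export
write_msd <- function(msd, path) {
  write.csv(as.data.frame(msd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("msd_curve", "data.frame")
  df
}
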