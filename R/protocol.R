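#' Magnetic tweezers force-cycle protocol
#'
#' The bridging assay applies a short initial extended step followed by
#' repeated cycles of a low-force relaxation step (which permits bridging)
#' and a high-force pulling step (which reports on bridges and eventually
#' ruptures them). Defaults reproduce the assay protocol: 10 s at 4 pN, then
#' five repetitions of 0.1 pN for 1 min and 4 pN for 3 min.
#'
#' @param n_cycles number of relax/pull cycles (>= 1).
#' @param initial_force_pN,initial_duration_s the initial extended step.
#' @param relax_force_pN,relax_duration_s the low-force (bridging) step.
#' @param pull_force_pN,pull_duration_s the high-force (pulling) step.
#' @return object of class \code{force_protocol}: a data.frame with columns
#'   \code{force_pN}, \code{duration_s}, \code{phase} (initial/relax/pull) and
#'   \code{cycle} (0 for the initial step).
#' @export
#' @examples
#' force_protocol()
force_protocol <- function(n_cycles = 5,
                           initial_force_pN = 4, initial_duration_s = 10,
                           relax_force_pN = 0.1, relax_duration_s = 60,
                           pull_force_pN = 4, pull_duration_s = 180) {
  .chk_num(n_cycles, "n_cycles", 1)
  for (nm in c("initial_duration_s", "relax_duration_s", "pull_duration_s"))
    .chk_num(get(nm), nm, 0, strict = TRUE)
  if (pull_force_pN <= relax_force_pN)
    stop("pulling force must exceed the relaxation force")
  steps <- data.frame(
    force_pN = c(initial_force_pN,
                 rep(c(relax_force_pN, pull_force_pN), n_cycles)),
    duration_s = c(initial_duration_s,
                   rep(c(relax_duration_s, pull_duration_s), n_cycles)),
    phase = c("initial", rep(c("relax", "pull"), n_cycles)),
    cycle = c(0L, rep(seq_len(n_cycles), each = 2L)),
    stringsAsFactors = FALSE
  )
  structure(steps, class = c("force_protocol", "data.frame"))
}

#' @export
print.force_protocol <- function(x, ...) {
  cat(sprintf("Force protocol: %d cycle(s), total %.0f s\n",
              max(x$cycle), sum(x$duration_s)))
  print.data.frame(x, ...)
  invisible(x)
}

# start times of each protocol step (seconds from experiment start)
protocol_step_starts <- function(protocol) {
  c(0, cumsum(protocol$duration_s))[seq_len(nrow(protocol))]
}

# locate pulling steps of a protocol inside a sampled time grid; returns a
# list of integer index vectors, one per pulling step in order
pull_step_indices <- function(time_s, protocol) {
  starts <- protocol_step_starts(protocol)
  ends <- starts + protocol$duration_s
  which_pull <- which(protocol$phase == "pull")
  lapply(which_pull, function(i) {
    which(time_s >= starts[i] & time_s < ends[i])
  })
}
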