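# Published composition of the HeartWave corpus the synthetic generator
# emulates.  The recordings themselves are not publicly deposited; only
# the printed per-class counts and durations travel with the package, and
# summaries are recomputed from the rows rather than quoted.

#' HeartWave corpus composition tables
#'
#' @param which `"recordings"` (per-diagnosis recording counts and mean
#'   durations) or `"cycles"` (per-class counts of manually segmented
#'   heartbeat cycles).
#' @return data.frame of the requested table.
#' @export
heartwave_composition <- function(which = c("recordings", "cycles")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("heartwave_", which, ".csv"),
                   package = "heartcam", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Recomputed summary of the HeartWave corpus composition
#'
#' Sums the composition rows: total recordings, the recording-weighted mean
#' duration, and the total number of segmented heartbeat cycles.
#'
#' @return list with `total_recordings`, `weighted_mean_duration_s`,
#'   `total_cycles`, and `cycles_per_class` (named vector).
#' @export
heartwave_summary <- function() {
  rec <- heartwave_composition("recordings")
  cyc <- heartwave_composition("cycles")
  list(total_recordings = sum(rec$n_recordings),
       weighted_mean_duration_s =
         sum(rec$n_recordings * rec$mean_duration_s) / sum(rec$n_recordings),
       total_cycles = sum(cyc$n_cycles),
       cycles_per_class = stats::setNames(cyc$n_cycles, cyc$class))
}
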