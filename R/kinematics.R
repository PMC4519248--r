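#' Inter-frame step distances
#'
#' Straight-line (Euclidean) distance between each pair of consecutive frame
#' coordinates — the per-frame "triangulation" distance. A pair in which
#' either frame is untracked, or whose frame indices are not consecutive
#' (an excluded gap), yields `NA`.
#'
#' @param traj `fq_trajectory` with at least 2 frames.
#' @return numeric vector of length `nrow(frames) - 1` (cm, `NA` across
#'   gaps).
#' @export
step_distances <- function(traj) {
  stopifnot(inherits(traj, "fq_trajectory"))
  fr <- traj$frames
  n <- nrow(fr)
  if (n < 2L) stop("step distances need at least 2 frames")
  d <- sqrt(diff(fr$x)^2 + diff(fr$y)^2)
  d[diff(fr$frame) != 1L] <- NA_real_
  d
}

#' Total distance swum
#'
#' Sum of all non-missing inter-frame step distances. The effective observed
#' time (number of measurable steps over the frame rate) is attached so a
#' partially tracked recording is never mistaken for a fully observed one.
#'
#' @param traj `fq_trajectory`.
#' @return total distance in cm, with attribute `effective_time_s`.
#' @export
total_distance <- function(traj) {
  d <- step_distances(traj)
  out <- sum(d, na.rm = TRUE)
  attr(out, "effective_time_s") <- sum(!is.na(d)) / traj$fps
  out
}

#' Per-second instantaneous velocity
#'
#' Instantaneous velocity of second `k` is the sum of the `fps` inter-frame
#' distances inside the k-th non-overlapping window of `fps` frames, aligned
#' to the first frame; since windows are 1 s long the sum is already in
#' cm/s. A trailing partial window is discarded; a window overlapping an
#' excluded gap is `NA`.
#'
#' @param traj `fq_trajectory` covering at least one full window.
#' @return `fq_speed_series`: list with `fish_id`, `window_s = 1`, `values`
#'   (cm/s, `NA` for excluded windows) and `effective_time_s`.
#' @export
instantaneous_velocity <- function(traj) {
  stopifnot(inherits(traj, "fq_trajectory"))
  fps <- traj$fps
  if (fps != round(fps)) stop("windowing requires an integer frame rate")
  d <- step_distances(traj)
  n_win <- length(d) %/% fps
  if (n_win < 1L) stop("recording shorter than one 1-s window")
  m <- matrix(d[seq_len(n_win * fps)], nrow = fps)
  vals <- colSums(m)  # NA propagates: any missing step excludes the window
  structure(list(fish_id = traj$fish_id, window_s = 1,
                 values = as.numeric(vals),
                 effective_time_s = sum(!is.na(vals))),
            class = "fq_speed_series")
}

#' @export
print.fq_speed_series <- function(x, ...) {
  cat(sprintf(
    "<fq_speed_series> %s: %d windows of %g s, %d valid; mean %.2f, max %.2f cm/s\n",
    x$fish_id, length(x$values), x$window_s, x$effective_time_s,
    mean(x$values, na.rm = TRUE), suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Maximum instantaneous speed
#'
#' @param series `fq_speed_series` with at least one valid window.
#' @return maximum per-second speed in cm/s.
#' @export
max_speed <- function(series) {
  stopifnot(inherits(series, "fq_speed_series"))
  v <- series$values[!is.na(series$values)]
  if (!length(v)) stop("no valid windows: maximum speed undefined")
  max(v)
}

#' Cumulated-time speed histogram
#'
#' Cumulated time (s) swum at each speed, in 1 cm/s increments: every valid
#' 1-s window contributes 1 s to the half-open bin `[floor(v), floor(v)+1)`;
#' speeds at or above `cap_cm_s` fall in a single overflow bin.
#'
#' @param series `fq_speed_series`.
#' @param cap_cm_s lower edge of the overflow bin (default 21 cm/s).
#' @return `fq_speed_histogram`: data.frame `bin_lo,bin_hi,seconds` with the
#'   source series' `fish_id` and `effective_time_s` as attributes.
#' @export
speed_histogram <- function(series, cap_cm_s = 21) {
  stopifnot(inherits(series, "fq_speed_series"), cap_cm_s >= 1)
  v <- series$values[!is.na(series$values)]
  idx <- pmin(floor(v), cap_cm_s)  # overflow collapses to index cap
  counts <- tabulate(idx + 1L, nbins = cap_cm_s + 1L)
  out <- data.frame(bin_lo = c(0:(cap_cm_s - 1), cap_cm_s),
                    bin_hi = c(1:cap_cm_s, Inf),
                    seconds = counts * series$window_s)
  attr(out, "fish_id") <- series$fish_id
  attr(out, "effective_time_s") <- series$effective_time_s
  class(out) <- c("fq_speed_histogram", "data.frame")
  out
}

#' Per-fish kinematics summary table
#'
#' Convenience wrapper running [total_distance()], [instantaneous_velocity()]
#' and [max_speed()] over a list of trajectories.
#'
#' @param trajectories list of `fq_trajectory`.
#' @return data.frame
#'   `fish_id,genotype,total_distance_cm,max_speed_cm_s,effective_time_s`.
#' @export
kinematics_table <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    s <- instantaneous_velocity(tr)
    data.frame(fish_id = tr$fish_id, genotype = tr$genotype,
               total_distance_cm = as.numeric(total_distance(tr)),
               max_speed_cm_s = max_speed(s),
               effective_time_s = s$effective_time_s)
  })
  do.call(rbind, rows)
}
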