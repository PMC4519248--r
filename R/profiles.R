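#' Speed-activity-profile thresholds from body length
#'
#' The three speed activity profiles (SAP) are defined relative to fish body
#' length (bl): rest below 0.5 bl/s, fast at or above 3 bl/s, moderate in
#' between. For a ~2 cm fish (3 mpf) that is 1 and 6 cm/s; for a ~4 cm fish
#' (9 mpf), 2 and 12 cm/s.
#'
#' @param body_length_cm positive body length in cm.
#' @return named numeric vector `c(rest_upper, fast_lower)` in cm/s.
#' @export
resolve_sap_thresholds <- function(body_length_cm) {
  if (!is.numeric(body_length_cm) || body_length_cm <= 0)
    stop("body_length_cm must be positive")
  c(rest_upper = 0.5 * body_length_cm, fast_lower = 3 * body_length_cm)
}

#' Classify per-second speeds into the three SAP classes
#'
#' Each valid 1-s window is assigned to exactly one of three half-open
#' body-length-normalized speed bands — rest `[0, 0.5 bl)`, moderate
#' `[0.5 bl, 3 bl)`, fast `[3 bl, Inf)` cm/s — so the classes partition all
#' speeds and the class times sum to the effective observed time.
#'
#' @param series `fq_speed_series`.
#' @param body_length_cm fish body length in cm.
#' @return `fq_sap_profile`: list with `fish_id`, `thresholds_cm_s`,
#'   `seconds` and `fractions` (%) named rest/moderate/fast, and
#'   `effective_time_s`.
#' @export
classify_sap <- function(series, body_length_cm) {
  stopifnot(inherits(series, "fq_speed_series"))
  th <- resolve_sap_thresholds(body_length_cm)
  v <- series$values[!is.na(series$values)]
  secs <- c(rest = sum(v < th[1]),
            moderate = sum(v >= th[1] & v < th[2]),
            fast = sum(v >= th[2])) * series$window_s
  total <- sum(secs)
  frac <- if (total > 0) 100 * secs / total else c(rest = NA_real_,
                                                   moderate = NA_real_,
                                                   fast = NA_real_)
  structure(list(fish_id = series$fish_id, thresholds_cm_s = th,
                 seconds = secs, fractions = frac,
                 effective_time_s = series$effective_time_s),
            class = "fq_sap_profile")
}

#' @export
print.fq_sap_profile <- function(x, ...) {
  cat(sprintf(
    "<fq_sap_profile> %s (thresholds %.3g / %.3g cm/s)\n  rest/moderate/fast: %s s = %s\n",
    x$fish_id, x$thresholds_cm_s[1], x$thresholds_cm_s[2],
    paste(x$seconds, collapse = "/"),
    paste(sprintf("%.1f%%", x$fractions), collapse = "/")))
  invisible(x)
}

#' SAP summary table for a cohort
#'
#' @param trajectories list of `fq_trajectory`.
#' @return data.frame
#'   `fish_id,genotype,rest_s,moderate_s,fast_s,rest_pct,moderate_pct,fast_pct`.
#' @export
sap_table <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    p <- classify_sap(instantaneous_velocity(tr), tr$body_length_cm)
    data.frame(fish_id = tr$fish_id, genotype = tr$genotype,
               rest_s = p$seconds[["rest"]], moderate_s = p$seconds[["moderate"]],
               fast_s = p$seconds[["fast"]], rest_pct = p$fractions[["rest"]],
               moderate_pct = p$fractions[["moderate"]],
               fast_pct = p$fractions[["fast"]])
  })
  do.call(rbind, rows)
}

.zone_occupancy <- function(traj, inside, zone) {
  fr <- traj$frames
  ok <- !is.na(fr$x)
  n_in <- sum(inside & ok)
  structure(list(fish_id = traj$fish_id, zone = zone,
                 seconds_in_zone = n_in / traj$fps,
                 fraction = if (any(ok)) n_in / sum(ok) else NA_real_,
                 total_observed_s = sum(ok) / traj$fps),
            class = "fq_zone_occupancy")
}

#' @export
print.fq_zone_occupancy <- function(x, ...) {
  cat(sprintf("<fq_zone_occupancy> %s in %s: %.1f / %.1f s (%.1f%%)\n",
              x$fish_id, x$zone, x$seconds_in_zone, x$total_observed_s,
              100 * x$fraction))
  invisible(x)
}

#' Time spent in the upper quarter of the water column
#'
#' For a vertical-plane recording, every tracked frame with
#' `y >= (1 - upper_fraction) * tank_height_cm` contributes `1/fps` s.
#' Elevated upper-quarter occupancy is the aquatic-surface-respiration proxy:
#' dissolved oxygen is highest near the surface.
#'
#' @param traj `fq_trajectory` recorded in the vertical plane.
#' @param upper_fraction fraction of the column counted as "upper" (0.25).
#' @return `fq_zone_occupancy`.
#' @export
upper_quarter_time <- function(traj, upper_fraction = 0.25) {
  stopifnot(inherits(traj, "fq_trajectory"),
            upper_fraction > 0, upper_fraction < 1)
  if (is.null(traj$tank_height_cm) || !is.finite(traj$tank_height_cm))
    stop("vertical extent (tank_height_cm) is required")
  if (traj$plane != "vertical")
    warning("upper-quarter time computed on a non-vertical recording")
  cut <- (1 - upper_fraction) * traj$tank_height_cm
  .zone_occupancy(traj, traj$frames$y >= cut, "upper_quarter")
}

#' Time spent in the center zone (centrophobia assay)
#'
#' The center is the concentric rectangle homothetic to the tank footprint
#' (same center, same aspect ratio) covering `center_area` of the total
#' surface, i.e. each side scaled by `sqrt(center_area)`; the boundary
#' counts as inside. Avoidance of this open center (thigmotaxis) is a stress
#' index.
#'
#' @param traj `fq_trajectory` recorded in the horizontal plane.
#' @param center_area fraction of the tank surface covered by the zone
#'   (default 0.5).
#' @return `fq_zone_occupancy`.
#' @export
center_zone_time <- function(traj, center_area = 0.5) {
  stopifnot(inherits(traj, "fq_trajectory"),
            center_area > 0, center_area <= 1)
  W <- traj$tank_width_cm
  H <- traj$tank_height_cm
  if (!is.finite(W) || !is.finite(H)) stop("both tank dimensions required")
  s <- sqrt(center_area)
  inside <- abs(traj$frames$x - W / 2) <= s * W / 2 &
    abs(traj$frames$y - H / 2) <= s * H / 2
  .zone_occupancy(traj, inside, "center_50pct")
}

#' Subsample trajectory positions for plotting
#'
#' Keeps every `stride_frames`-th recorded frame starting from the first
#' (at 25 fps the default stride of 150 frames is one position every 6 s),
#' the convention used for occupancy trajectory diagrams.
#'
#' @param traj `fq_trajectory`.
#' @param stride_frames positive integer stride (default 150).
#' @return data.frame `frame,x,y`.
#' @export
subsample_positions <- function(traj, stride_frames = 150) {
  stopifnot(inherits(traj, "fq_trajectory"),
            stride_frames >= 1, stride_frames == round(stride_frames))
  traj$frames[seq(1L, nrow(traj$frames), by = stride_frames), , drop = FALSE]
}
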