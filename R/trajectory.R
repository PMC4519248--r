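#' Construct a fish trajectory
#'
#' A trajectory is the time-indexed 2-D position record of one fish in one
#' recording, together with the metadata every downstream stage needs: frame
#' rate, tank extent of the recorded plane, fish body length, genotype and
#' age group. Coordinates are in cm with the origin at the bottom-left corner
#' of the recorded plane; for vertical-plane recordings `y` increases upward,
#' so the water surface is at `y = tank_height_cm`.
#'
#' Missing coordinates (tracking losses) are kept as `NA` and are excluded
#' from every downstream numerator *and* denominator; all summaries report
#' the effective observed time instead of silently assuming a full recording.
#'
#' @param frames data.frame with columns `frame` (non-negative integer,
#'   strictly increasing), `x`, `y` (cm, `NA` allowed).
#' @param fps frames per second (positive; windowing requires an integer).
#' @param tank_width_cm,tank_height_cm extent of the recorded plane in cm.
#'   For vertical recordings `tank_height_cm` is the water-column height.
#' @param body_length_cm fish standard length in cm (~2 at 3 mpf, ~4 at
#'   9 mpf); used to resolve speed-class thresholds.
#' @param fish_id identifier string.
#' @param genotype one of `"WT"`, `"HT"`, `"HM"` (or another label).
#' @param age_group e.g. `"3mpf"`, `"9mpf"`.
#' @param plane `"horizontal"` (top view) or `"vertical"` (side view).
#' @param tolerance_cm coordinates may exceed the tank extent by at most this
#'   much (digitisation jitter) and are clamped; beyond it is an error.
#' @return An object of class `fq_trajectory`.
#' @export
trajectory <- function(frames, fps = 25, tank_width_cm, tank_height_cm,
                       body_length_cm, fish_id = "fish1", genotype = "WT",
                       age_group = "9mpf", plane = c("horizontal", "vertical"),
                       tolerance_cm = 0.05) {
  plane <- match.arg(plane)
  stopifnot(is.data.frame(frames))
  need <- c("frame", "x", "y")
  if (!all(need %in% names(frames)))
    stop("`frames` must have columns frame, x, y")
  frames <- frames[need]
  if (nrow(frames) == 0L) stop("trajectory has no frames")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!is.numeric(body_length_cm) || body_length_cm <= 0)
    stop("body_length_cm must be positive")
  if (tank_width_cm <= 0 || tank_height_cm <= 0)
    stop("tank dimensions must be positive")
  fr <- frames$frame
  if (anyNA(fr) || any(fr < 0) || any(fr != round(fr)))
    stop("frame indices must be non-negative integers")
  if (is.unsorted(fr, strictly = TRUE))
    stop("frame index must be strictly increasing")
  frames$x <- .check_coord(frames$x, tank_width_cm, tolerance_cm, "x")
  frames$y <- .check_coord(frames$y, tank_height_cm, tolerance_cm, "y")
  # a frame with one missing coordinate is unusable: mark both missing
  miss <- is.na(frames$x) | is.na(frames$y)
  frames$x[miss] <- NA_real_
  frames$y[miss] <- NA_real_
  structure(
    list(fish_id = as.character(fish_id), genotype = as.character(genotype),
         age_group = as.character(age_group), fps = fps,
         body_length_cm = body_length_cm, tank_width_cm = tank_width_cm,
         tank_height_cm = tank_height_cm, plane = plane, frames = frames),
    class = "fq_trajectory")
}

.check_coord <- function(v, extent, tol, what) {
  if (!is.numeric(v)) stop(what, " must be numeric")
  bad <- !is.na(v) & (v < -tol | v > extent + tol)
  if (any(bad))
    stop(sprintf("%d %s coordinate(s) outside [0, %g] (first at row %d)",
                 sum(bad), what, extent, which(bad)[1]))
  pmin(pmax(v, 0), extent)
}

#' @export
print.fq_trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  ok <- sum(!is.na(x$frames$x))
  cat(sprintf(
    "<fq_trajectory> %s (%s, %s) %s plane\n  %d frames at %g fps (%.1f s), %d tracked (%.1f%%)\n  tank %g x %g cm, body length %g cm\n",
    x$fish_id, x$genotype, x$age_group, x$plane, n, x$fps, n / x$fps, ok,
    100 * ok / n, x$tank_width_cm, x$tank_height_cm, x$body_length_cm))
  invisible(x)
}

#' Read a trajectory from a CSV file
#'
#' The file contract is a delimited table with header `frame,x,y`; an empty
#' field is a missing (untracked) coordinate. Recording metadata (frame rate,
#' tank extent, body length, genotype, age group) comes from `metadata`,
#' either a named list or a path to a DCF key-value file (see
#' [read_cohort_metadata()]).
#'
#' @param path CSV file path.
#' @param metadata named list or path to a metadata file. Recognised keys:
#'   `fps`, `tank_width_cm`, `tank_height_cm`, `body_length_cm`, `genotype`,
#'   `age_group`, `plane`, `fish_id`.
#' @return `fq_trajectory`.
#' @export
read_trajectory <- function(path, metadata) {
  if (is.character(metadata)) metadata <- read_cohort_metadata(metadata)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, na.strings = c("", "NA"))
  if (!all(c("frame", "x", "y") %in% names(raw)))
    stop("file ", path, " lacks the frame,x,y header")
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("%s: malformed %s at data line %d (%s)",
                   path, what, bad[1], raw[[col]][bad[1]]))
    v
  }
  frames <- data.frame(frame = num("frame", "frame index"),
                       x = num("x", "x coordinate"),
                       y = num("y", "y coordinate"))
  if (anyNA(frames$frame)) stop(path, ": missing frame index")
  args <- metadata
  args$frames <- frames
  if (is.null(args$fish_id))
    args$fish_id <- sub("\\.[^.]*$", "", basename(path))
  do.call(trajectory, args)
}

#' Write a trajectory to a CSV file
#'
#' Inverse of [read_trajectory()]: writes the `frame,x,y` table with empty
#' fields for missing coordinates, so that a read round-trip reproduces the
#' coordinates exactly.
#'
#' @param traj `fq_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fq_trajectory"))
  df <- traj$frames
  df$x <- ifelse(is.na(df$x), "", formatC(df$x, digits = 17, format = "g"))
  df$y <- ifelse(is.na(df$y), "", formatC(df$y, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata from a key-value file
#'
#' Metadata files use the Debian-control (DCF) flat key-value format read by
#' [read.dcf()], e.g. `fps: 25`. Numeric-looking values are converted.
#'
#' @param path file path.
#' @return named list.
#' @export
read_cohort_metadata <- function(path) {
  m <- read.dcf(path)
  if (nrow(m) != 1L) stop("metadata file must contain exactly one record")
  out <- as.list(m[1, ])
  lapply(out, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
}

#' Interpolate short tracking gaps
#'
#' Runs of at most `max_gap_frames` consecutive missing coordinates are
#' filled by linear interpolation between the flanking tracked positions;
#' longer runs (and runs touching either end of the recording, which have no
#' flank) are left missing and flagged as excluded. The gap report partitions
#' the missing frames, so downstream effective-time accounting is auditable.
#'
#' @param traj `fq_trajectory`.
#' @param max_gap_frames longest run length that is interpolated (default 5,
#'   i.e. 0.2 s at 25 fps).
#' @return `fq_trajectory` with a `gap_report` attribute: data.frame
#'   `start_frame,end_frame,n_frames,action` with action `interpolated` or
#'   `excluded`.
#' @export
fill_gaps <- function(traj, max_gap_frames = 5) {
  stopifnot(inherits(traj, "fq_trajectory"), max_gap_frames >= 0)
  fr <- traj$frames
  miss <- is.na(fr$x)
  rep_rows <- list()
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      has_flank <- i0 > 1L && i1 < nrow(fr)
      # only frame-contiguous runs are interpolable: dropped rows are a gap too
      contiguous <- has_flank &&
        (fr$frame[i1 + 1L] - fr$frame[i0 - 1L]) == (i1 - i0 + 2L)
      if (r$lengths[k] <= max_gap_frames && contiguous) {
        w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1L)
        fr$x[i0:i1] <- fr$x[i0 - 1L] + w * (fr$x[i1 + 1L] - fr$x[i0 - 1L])
        fr$y[i0:i1] <- fr$y[i0 - 1L] + w * (fr$y[i1 + 1L] - fr$y[i0 - 1L])
        act <- "interpolated"
      } else {
        act <- "excluded"
      }
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(start_frame = fr$frame[i0], end_frame = fr$frame[i1],
                   n_frames = i1 - i0 + 1L, action = act)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(start_frame = integer(), end_frame = integer(),
               n_frames = integer(), action = character())
  traj$frames <- fr
  attr(traj, "gap_report") <- report
  traj
}
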