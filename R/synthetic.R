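#' Cohort simulator configuration (one genotype block)
#'
#' Describes the stochastic behavioral model used to emulate one genotype
#' group: a three-state (rest / moderate / fast) semi-Markov process drives
#' per-second swimming speed; positions are realised as a correlated random
#' walk in a bounded tank. Long-run state occupancy is controlled exactly:
#' after each exponential holding time (mean `state_mean_dwell_s[i]` in state
#' i) the next state is drawn independently with probability proportional to
#' `state_occupancy[i] / state_mean_dwell_s[i]`, which makes the long-run
#' time fraction in state i equal to `state_occupancy[i]` for any target.
#'
#' Per-second speeds are drawn from a per-state distribution truncated to the
#' state's body-length-normalized speed band (rest `[0, 0.5 bl)`, moderate
#' `[0.5 bl, 3 bl)`, fast `[3 bl, cap]` in cm/s), so that the hidden state is
#' recoverable downstream by [classify_sap()].
#'
#' @param genotype,age_group labels carried into every simulated fish.
#' @param n_fish number of fish in the cohort.
#' @param duration_s recording length in seconds.
#' @param fps frames per second (integer).
#' @param body_length_cm fish standard length (cm).
#' @param tank_width_cm,tank_height_cm recorded-plane extent (cm).
#' @param plane `"horizontal"` or `"vertical"`.
#' @param state_occupancy length-3 non-negative vector summing to 1: target
#'   long-run time fractions in (rest, moderate, fast).
#' @param state_mean_dwell_s length-3 positive vector: mean holding time per
#'   state, seconds. Default 0.3 s throughout: zebrafish locomotion switches
#'   at the sub-second beat-and-glide bout scale, so successive 1-s analysis
#'   windows are approximately independent.
#' @param state_speed list of 3 lists (rest, moderate, fast), each with
#'   `family` (`"truncnorm"` or `"gamma"`), `mean` (cm/s) and `sd` (cm/s);
#'   the distribution is truncated to the state's band. `mean` must lie
#'   strictly inside the band unless `sd = 0` (degenerate point mass).
#' @param speed_cap_cm_s upper truncation of the fast band (default 21 cm/s,
#'   the ceiling of the speed histogram).
#' @param turning_concentration heading-persistence parameter kappa of the
#'   correlated random walk; per-frame heading increments are
#'   `Normal(0, 1/sqrt(kappa))` radians.
#' @param vertical_preference vertical recordings only: target long-run
#'   fraction of time in the upper quarter of the water column, strictly
#'   inside (0, 1).
#' @param surface_mean_dwell_s vertical recordings only: mean duration of a
#'   surface (upper-quarter) bout, seconds.
#' @param respiration_rate_per_min mean opercular movement count per minute.
#' @param between_fish_cv coefficient of variation of the mean-preserving
#'   lognormal between-fish scatter applied to respiration rates.
#' @param seed integer seed making [simulate_cohort()] deterministic.
#' @return `fq_cohort_config`.
#' @export
cohort_config <- function(genotype = "WT", age_group = "9mpf", n_fish = 10,
                          duration_s = 3600, fps = 25, body_length_cm = 4,
                          tank_width_cm = 18, tank_height_cm = 24,
                          plane = c("horizontal", "vertical"),
                          state_occupancy = c(rest = 0.70, moderate = 0.25,
                                              fast = 0.05),
                          state_mean_dwell_s = c(0.3, 0.3, 0.3),
                          state_speed = NULL,
                          speed_cap_cm_s = 21,
                          turning_concentration = 4,
                          vertical_preference = 0.25,
                          surface_mean_dwell_s = 20,
                          respiration_rate_per_min = 110,
                          between_fish_cv = 0.1,
                          seed = 1L) {
  plane <- match.arg(plane)
  occ <- unname(state_occupancy)
  if (length(occ) != 3 || any(occ < 0) || abs(sum(occ) - 1) > 1e-9)
    stop("state_occupancy must be 3 non-negative fractions summing to 1")
  if (length(state_mean_dwell_s) != 3 || any(state_mean_dwell_s <= 0))
    stop("state_mean_dwell_s must be 3 positive values")
  if (n_fish < 1 || duration_s <= 0 || fps <= 0 || fps != round(fps))
    stop("n_fish, duration_s must be positive; fps a positive integer")
  if (body_length_cm <= 0) stop("body_length_cm must be positive")
  if (plane == "vertical" &&
      (vertical_preference <= 0 || vertical_preference >= 1))
    stop("vertical_preference must lie strictly inside (0, 1): ",
         "a target of 0 or 1 is unreachable with finite bout durations")
  if (respiration_rate_per_min <= 0)
    stop("respiration_rate_per_min must be positive")
  if (is.null(state_speed))
    state_speed <- default_state_speed(body_length_cm, speed_cap_cm_s)
  bands <- sap_bands(body_length_cm, speed_cap_cm_s)
  for (i in 1:3) {
    sp <- state_speed[[i]]
    if (!sp$family %in% c("truncnorm", "gamma"))
      stop("state_speed family must be 'truncnorm' or 'gamma'")
    if (sp$sd < 0) stop("state_speed sd must be non-negative")
    inside <- sp$mean > bands[i] && sp$mean < bands[i + 1]
    at_edge <- sp$mean >= bands[i] && sp$mean <= bands[i + 1]
    if (!(inside || (sp$sd == 0 && at_edge)))
      stop(sprintf(
        "state %d speed mean %.3g not strictly inside its band [%.3g, %.3g)",
        i, sp$mean, bands[i], bands[i + 1]))
  }
  structure(
    list(genotype = genotype, age_group = age_group, n_fish = as.integer(n_fish),
         duration_s = duration_s, fps = as.integer(fps),
         body_length_cm = body_length_cm, tank_width_cm = tank_width_cm,
         tank_height_cm = tank_height_cm, plane = plane,
         state_occupancy = occ, state_mean_dwell_s = state_mean_dwell_s,
         state_speed = state_speed, speed_cap_cm_s = speed_cap_cm_s,
         turning_concentration = turning_concentration,
         vertical_preference = vertical_preference,
         surface_mean_dwell_s = surface_mean_dwell_s,
         respiration_rate_per_min = respiration_rate_per_min,
         between_fish_cv = between_fish_cv, seed = as.integer(seed)),
    class = "fq_cohort_config")
}

#' @export
print.fq_cohort_config <- function(x, ...) {
  cat(sprintf(
    "<fq_cohort_config> %s %s: %d fish x %g s, %s plane\n  occupancy rest/moderate/fast = %s, bl %g cm, respiration %g/min, seed %d\n",
    x$genotype, x$age_group, x$n_fish, x$duration_s, x$plane,
    paste(sprintf("%.0f%%", 100 * x$state_occupancy), collapse = "/"),
    x$body_length_cm, x$respiration_rate_per_min, x$seed))
  invisible(x)
}

# speed band edges (cm/s) for the three states: rest / moderate / fast
sap_bands <- function(body_length_cm, cap = Inf) {
  c(0, 0.5 * body_length_cm, 3 * body_length_cm, cap)
}

default_state_speed <- function(bl, cap) {
  b <- sap_bands(bl, cap)
  list(
    rest     = list(family = "truncnorm", mean = 0.4 * b[2], sd = 0.3 * b[2]),
    moderate = list(family = "truncnorm", mean = b[2] + 0.3 * (b[3] - b[2]),
                    sd = 0.25 * (b[3] - b[2])),
    fast     = list(family = "truncnorm", mean = b[3] + 0.2 * (b[4] - b[3]),
                    sd = 0.2 * (b[4] - b[3]))
  )
}

#' Preset cohort configurations
#'
#' Illustrative genotype presets shipping the qualitative behavioral pattern
#' of the assay this package models: at 9 mpf, wild-type (WT) and
#' heterozygous (HT) fish rest ~70% of the time, swim at moderate speed ~25%
#' and fast ~5%, while homozygous (HM) fish rest ~5% and swim at moderate
#' speed ~75%; HT and HM show elevated upper-quarter (surface) preference
#' and HM roughly doubled respiration. At 3 mpf all genotypes share one
#' profile (~15/70/15). These are qualitative fixtures for testing and
#' simulation studies, not estimates fitted to any real recording.
#'
#' @param name one of `"wt_9mpf"`, `"ht_9mpf"`, `"hm_9mpf"`, `"wt_3mpf"`,
#'   `"ht_3mpf"`, `"hm_3mpf"`, `"all_3mpf"` (alias of `"wt_3mpf"`).
#' @param ... overrides passed on to [cohort_config()].
#' @return `fq_cohort_config`.
#' @export
cohort_preset <- function(name = c("wt_9mpf", "ht_9mpf", "hm_9mpf",
                                   "wt_3mpf", "ht_3mpf", "hm_3mpf",
                                   "all_3mpf"), ...) {
  name <- match.arg(name)
  if (name == "all_3mpf") name <- "wt_3mpf"
  base9 <- list(age_group = "9mpf", body_length_cm = 4,
                tank_width_cm = 18, tank_height_cm = 24, duration_s = 3600)
  base3 <- list(age_group = "3mpf", body_length_cm = 2,
                tank_width_cm = 8.8, tank_height_cm = 11.8,
                duration_s = 3600,
                state_occupancy = c(0.15, 0.70, 0.15),
                vertical_preference = 0.25,
                respiration_rate_per_min = 140)
  args <- switch(name,
    wt_9mpf = c(base9, list(genotype = "WT", n_fish = 15,
                            state_occupancy = c(0.70, 0.25, 0.05),
                            vertical_preference = 0.25,
                            respiration_rate_per_min = 110)),
    ht_9mpf = c(base9, list(genotype = "HT", n_fish = 19,
                            state_occupancy = c(0.70, 0.25, 0.05),
                            vertical_preference = 0.65,
                            respiration_rate_per_min = 115)),
    hm_9mpf = c(base9, list(genotype = "HM", n_fish = 7,
                            state_occupancy = c(0.05, 0.75, 0.20),
                            vertical_preference = 0.50,
                            respiration_rate_per_min = 220)),
    wt_3mpf = c(base3, list(genotype = "WT", n_fish = 12)),
    ht_3mpf = c(base3, list(genotype = "HT", n_fish = 16)),
    hm_3mpf = c(base3, list(genotype = "HM", n_fish = 11)))
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# draw n per-second speeds from one state's truncated distribution
.draw_speeds <- function(n, sp, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sp$sd == 0) return(rep(sp$mean, n))
  if (sp$family == "truncnorm") {
    plo <- stats::pnorm(lo, sp$mean, sp$sd)
    phi <- stats::pnorm(hi, sp$mean, sp$sd)
    stats::qnorm(stats::runif(n, plo, phi), sp$mean, sp$sd)
  } else {
    shape <- (sp$mean / sp$sd)^2
    rate <- shape / sp$mean
    plo <- stats::pgamma(lo, shape, rate)
    phi <- stats::pgamma(hi, shape, rate)
    stats::qgamma(stats::runif(n, plo, phi), shape, rate)
  }
}

# sample the renewal state process at 1-s midpoints over duration_s seconds.
# nu_i  propto occupancy_i / dwell_i; long-run time share of state i is then
# nu_i * dwell_i / sum(nu * dwell) = occupancy_i exactly. A burn-in absorbs
# the non-length-biased start.
.sample_states <- function(occ, dwell, duration_s) {
  live <- which(occ > 0)
  if (length(live) == 1L) return(rep(live, duration_s))
  nu <- occ[live] / dwell[live]
  nu <- nu / sum(nu)
  burn <- 20 * max(dwell)
  total <- duration_s + burn
  mean_seg <- sum(nu * dwell[live])
  states <- integer(0)
  times <- numeric(0)
  t_end <- 0
  while (t_end < total) {
    k <- max(64L, ceiling(1.3 * (total - t_end) / mean_seg))
    s <- sample(live, k, replace = TRUE, prob = nu)
    d <- stats::rexp(k, rate = 1 / dwell[s])
    states <- c(states, s)
    times <- c(times, d)
    t_end <- t_end + sum(d)
  }
  bounds <- cumsum(times)
  mid <- burn + seq_len(duration_s) - 0.5
  states[findInterval(mid, bounds) + 1L]
}

#' Simulate the hidden per-second behavioral process of one fish
#'
#' Returns the semi-Markov state and the drawn speed for each 1-s window —
#' the simulator's ground truth ("sidecar"). [simulate_fish()] realises these
#' speeds as positions; the analysis stages never read this table, it exists
#' so tests can check exact recovery.
#'
#' @param config `fq_cohort_config`.
#' @param duration_s recording length, default from `config`.
#' @param seed optional integer seed (`NULL` = use the current RNG stream).
#' @return data.frame `second,state,speed_cm_s` with state in
#'   `rest|moderate|fast`.
#' @export
simulate_speed_process <- function(config, duration_s = config$duration_s,
                                   seed = NULL) {
  stopifnot(inherits(config, "fq_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  duration_s <- as.integer(duration_s)
  st <- .sample_states(config$state_occupancy, config$state_mean_dwell_s,
                       duration_s)
  bands <- sap_bands(config$body_length_cm, config$speed_cap_cm_s)
  speed <- numeric(duration_s)
  for (i in 1:3) {
    idx <- which(st == i)
    speed[idx] <- .draw_speeds(length(idx), config$state_speed[[i]],
                               bands[i], bands[i + 1])
  }
  data.frame(second = seq_len(duration_s),
             state = c("rest", "moderate", "fast")[st],
             speed_cm_s = speed)
}

# surface/column bout indicator per second for vertical recordings
.sample_surface_bouts <- function(p, surface_dwell, duration_s) {
  column_dwell <- surface_dwell * (1 - p) / p
  st <- .sample_states(c(p, 1 - p, 0),
                       c(surface_dwell, column_dwell, 1), duration_s)
  st == 1L
}

#' Simulate one fish trajectory
#'
#' Realises the hidden per-second speed process as a correlated random walk:
#' within each 1-s window the drawn speed is laid down as `fps` inter-frame
#' steps of equal length along a persistent heading; a step that would leave
#' the tank has the offending velocity component reflected, so every
#' inter-frame step keeps its exact length and the per-second sum of step
#' distances equals the drawn speed exactly. For vertical-plane recordings a
#' hidden surface/column bout process (mean surface bout
#' `surface_mean_dwell_s`, long-run surface share `vertical_preference`)
#' confines the vertical coordinate to the upper quarter during surface
#' bouts.
#'
#' @param config `fq_cohort_config`.
#' @param fish_id identifier for the simulated fish.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @param duration_s recording length, default from `config`.
#' @return `fq_trajectory` with `duration_s * fps + 1` frames and a `truth`
#'   attribute holding the sidecar of [simulate_speed_process()] (plus a
#'   `surface` column for vertical recordings).
#' @export
simulate_fish <- function(config, fish_id = "sim1", seed = NULL,
                          duration_s = config$duration_s) {
  stopifnot(inherits(config, "fq_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  duration_s <- as.integer(duration_s)
  fps <- config$fps
  W <- config$tank_width_cm
  H <- config$tank_height_cm
  truth <- simulate_speed_process(config, duration_s)
  vertical <- config$plane == "vertical"
  if (vertical) {
    surf <- .sample_surface_bouts(config$vertical_preference,
                                  config$surface_mean_dwell_s, duration_s)
    truth$surface <- surf
    y_split <- 0.75 * H
  }
  n_steps <- duration_s * fps
  step_len <- rep(truth$speed_cm_s / fps, each = fps)
  dtheta <- stats::rnorm(n_steps, 0, 1 / sqrt(config$turning_concentration))
  x <- numeric(n_steps + 1L)
  y <- numeric(n_steps + 1L)
  x[1] <- stats::runif(1, 0.1 * W, 0.9 * W)
  y[1] <- stats::runif(1, 0.1 * H, 0.9 * H)
  theta <- stats::runif(1, -pi, pi)
  for (i in seq_len(n_steps)) {
    theta <- theta + dtheta[i]
    len <- step_len[i]
    dx <- len * cos(theta)
    dy <- len * sin(theta)
    xi <- x[i]
    yi <- y[i]
    if (xi + dx < 0 || xi + dx > W) dx <- -dx
    if (vertical) {
      # confine y to the current bout's band once inside it; outside, head
      # toward the band at full vertical component
      in_surf <- surf[(i - 1L) %/% fps + 1L]
      lo <- if (in_surf) y_split else 0
      hi <- if (in_surf) H else y_split
      if (yi >= lo && yi <= hi) {
        if (yi + dy < lo || yi + dy > hi) dy <- -dy
        if (yi + dy < lo || yi + dy > hi) dy <- 0  # band thinner than step
      } else {
        dy <- abs(dy) * sign((lo + hi) / 2 - yi)
        if (yi + dy < 0 || yi + dy > H) dy <- -dy
      }
    } else {
      if (yi + dy < 0 || yi + dy > H) dy <- -dy
    }
    x[i + 1L] <- xi + dx
    y[i + 1L] <- yi + dy
    theta <- atan2(dy, dx)
  }
  traj <- trajectory(
    data.frame(frame = 0:n_steps, x = x, y = y),
    fps = fps, tank_width_cm = W, tank_height_cm = H,
    body_length_cm = config$body_length_cm, fish_id = fish_id,
    genotype = config$genotype, age_group = config$age_group,
    plane = config$plane)
  attr(traj, "truth") <- truth
  traj
}

#' Simulate respiration counts
#'
#' Opercular movement counts per minute: per-fish mean rates get a
#' mean-preserving lognormal scatter (`cv` between fish), counts are Poisson
#' around the per-fish rate.
#'
#' @param rate_per_min positive mean rate (movements per minute).
#' @param n_fish number of fish.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @param cv between-fish coefficient of variation (0 disables scatter).
#' @param genotype label attached to each record.
#' @return data.frame `fish_id,genotype,counts_per_minute`.
#' @export
simulate_respiration <- function(rate_per_min, n_fish, seed = NULL,
                                 cv = 0.1, genotype = "WT") {
  stopifnot(rate_per_min > 0, n_fish >= 1, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  rates <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    rate_per_min * stats::rlnorm(n_fish, -sdlog^2 / 2, sdlog)
  } else rep(rate_per_min, n_fish)
  data.frame(fish_id = sprintf("%s_f%02d", tolower(genotype), seq_len(n_fish)),
             genotype = genotype,
             counts_per_minute = stats::rpois(n_fish, rates))
}

#' Simulate a full cohort
#'
#' Draws `config$n_fish` trajectories and matching respiration counts from a
#' single seeded RNG stream, so the whole cohort is reproducible from
#' `config$seed`.
#'
#' @param config `fq_cohort_config`.
#' @return list with `trajectories` (list of `fq_trajectory`), `respiration`
#'   (data.frame) and `config`; class `fq_cohort`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fq_cohort_config"))
  set.seed(config$seed)
  ids <- sprintf("%s_f%02d", tolower(config$genotype),
                 seq_len(config$n_fish))
  trajs <- lapply(ids, function(id) simulate_fish(config, fish_id = id))
  resp <- simulate_respiration(config$respiration_rate_per_min,
                               config$n_fish, cv = config$between_fish_cv,
                               genotype = config$genotype)
  resp$fish_id <- ids
  structure(list(trajectories = trajs, respiration = resp, config = config),
            class = "fq_cohort")
}

#' Write a simulator ground-truth sidecar
#'
#' @param traj a trajectory produced by [simulate_fish()].
#' @param path output CSV path (`second,state,speed_cm_s`).
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(traj, path) {
  truth <- attr(traj, "truth")
  if (is.null(truth)) stop("trajectory has no simulator ground truth")
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
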