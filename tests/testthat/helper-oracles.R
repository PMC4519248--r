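# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (explicit loops, string surgery) so it shares no code
# path with the package implementation it checks.

random_trajectory <- function(n_frames, fps = 25, W = 18, H = 24,
                              miss_prob = 0, bl = 4) {
  x <- runif(n_frames, 0, W)
  y <- runif(n_frames, 0, H)
  if (miss_prob > 0) {
    drop <- runif(n_frames) < miss_prob
    x[drop] <- NA
    y[drop] <- NA
  }
  trajectory(data.frame(frame = seq_len(n_frames) - 1L, x = x, y = y),
             fps = fps, tank_width_cm = W, tank_height_cm = H,
             body_length_cm = bl)
}

oracle_step_distances <- function(traj) {
  fr <- traj$frames
  out <- rep(NA_real_, nrow(fr) - 1L)
  for (i in seq_len(nrow(fr) - 1L)) {
    if (fr$frame[i + 1] - fr$frame[i] == 1 &&
        !is.na(fr$x[i]) && !is.na(fr$x[i + 1]))
      out[i] <- sqrt((fr$x[i + 1] - fr$x[i])^2 + (fr$y[i + 1] - fr$y[i])^2)
  }
  out
}

oracle_velocity <- function(traj) {
  d <- oracle_step_distances(traj)
  fps <- traj$fps
  n_win <- length(d) %/% fps
  vals <- numeric(n_win)
  for (k in seq_len(n_win)) {
    w <- d[((k - 1) * fps + 1):(k * fps)]
    vals[k] <- if (any(is.na(w))) NA_real_ else sum(w)
  }
  vals
}

oracle_histogram <- function(values, cap = 21) {
  counts <- numeric(cap + 1)
  for (v in values) {
    if (is.na(v)) next
    b <- if (v >= cap) cap else floor(v)
    counts[b + 1] <- counts[b + 1] + 1
  }
  counts
}

oracle_sap_seconds <- function(values, bl) {
  lo <- 0.5 * bl
  hi <- 3 * bl
  out <- c(rest = 0, moderate = 0, fast = 0)
  for (v in values) {
    if (is.na(v)) next
    if (v < lo) out["rest"] <- out["rest"] + 1
    else if (v < hi) out["moderate"] <- out["moderate"] + 1
    else out["fast"] <- out["fast"] + 1
  }
  out
}

# exhaustive-permutation two-sided Mann-Whitney p (equal-tail doubling)
oracle_mw_permutation_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pool), na)
  us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
  p_le <- mean(us <= u_obs + 1e-12)
  p_ge <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

oracle_chisq_stat <- function(tab) {
  N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / N
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# classical 2x2 two-tailed Fisher by direct hypergeometric summation
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# leftmost equivalent placement of a planted indel, by direct string logic
oracle_leftmost_deletion <- function(ref, mutseq, len) {
  n <- nchar(ref)
  for (q in 1:(n - len + 1)) {
    if (substr(ref, 1, q - 1) == substr(mutseq, 1, q - 1) &&
        substr(ref, q + len, n) == substr(mutseq, q, n - len))
      return(q)
  }
  NA_integer_
}

oracle_leftmost_insertion <- function(ref, mutseq, len) {
  n <- nchar(ref)
  for (q in 0:n) {
    if (substr(ref, 1, q) == substr(mutseq, 1, q) &&
        substr(ref, q + 1, n) == substr(mutseq, q + len + 1, n + len))
      return(q)
  }
  NA_integer_
}
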