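#' Mann-Whitney pairwise comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the workhorse pairwise
#' comparison for per-fish scalars (total distance, maximum speed, SAP class
#' seconds, zone seconds, respiration counts). The exact null distribution is
#' used when the smaller group has at most 8 observations and the pooled
#' sample has no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b non-empty numeric vectors of per-fish values.
#' @return list `U` (Mann-Whitney U for group `a`), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`), `n` (group sizes).
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal",
       n = c(length(a), length(b)))
}

#' Chi-square comparison of SAP distributions between two cohorts
#'
#' Builds a 2 x 3 contingency table of cumulated seconds per SAP class
#' (rest, moderate, fast), summed over the fish of each cohort and rounded
#' to integer seconds, then applies Pearson's chi-square test (df = 2,
#' no continuity correction).
#'
#' Note this pools seconds across fish, so the test treats every observed
#' second as independent: seconds within one fish are pseudo-replicates, and
#' the resulting p-values overstate certainty whenever fish differ
#' systematically within a cohort. It is the construction matching a pooled
#' per-genotype SAP pie chart; per-fish Mann-Whitney comparisons of class
#' seconds are the complementary fish-level analysis.
#'
#' @param profiles_a,profiles_b non-empty lists of `fq_sap_profile`.
#' @return list `statistic`, `df`, `p`, `table` (2 x 3 integer seconds),
#'   `low_expected_flag` (TRUE if any expected cell < 5).
#' @export
chi_square_sap <- function(profiles_a, profiles_b) {
  pool <- function(ps) {
    stopifnot(length(ps) > 0)
    colSums(do.call(rbind, lapply(ps, function(p) {
      stopifnot(inherits(p, "fq_sap_profile"))
      p$seconds
    })))
  }
  tab <- round(rbind(a = pool(profiles_a), b = pool(profiles_b)))
  colnames(tab) <- c("rest", "moderate", "fast")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab,
       low_expected_flag = any(ct$expected < 5))
}

# log probability of one table under the fixed-margins null:
# P = prod(r_i!) prod(c_j!) / (N! prod(n_ij!))
.log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, calling fun(tab, logp)
.enumerate_tables <- function(row_margins, col_margins, fun) {
  r <- length(row_margins)
  tab <- matrix(0L, r, length(col_margins))
  rec_row <- function(i, col_left) {
    if (i == r) {                       # last row forced by column margins
      if (any(col_left < 0)) return(invisible())
      tab[r, ] <<- col_left
      fun(tab, .log_table_prob(tab))
      return(invisible())
    }
    fill <- function(j, left, acc) {
      cl <- length(col_left)
      if (j == cl) {                    # last cell of the row forced
        if (left > col_left[cl]) return(invisible())
        acc[cl] <- left
        tab[i, ] <<- acc
        rec_row(i + 1L, col_left - acc)
        return(invisible())
      }
      for (v in 0:min(left, col_left[j])) {
        acc[j] <- v
        fill(j + 1L, left - v, acc)
      }
    }
    fill(1L, row_margins[i], integer(length(col_left)))
  }
  rec_row(1L, col_margins)
}

#' Exact two-tailed Fisher test for r x c tables (Freeman-Halton)
#'
#' Enumerates every table sharing the observed row and column margins,
#' computes its exact probability under the fixed-margins null, and sums the
#' probabilities of all tables no more probable than the observed one
#' (probability-ordering two-tail, with a small relative tolerance for
#' floating-point equality). Intended for small count tables such as
#' dose x outcome screens; larger tables should use a chi-square test.
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @param max_total enumeration guard: error if `sum(table)` exceeds this
#'   (default 500).
#' @param tail `"probability"` (default Freeman-Halton ordering) or
#'   `"observed_only"` (one-tail: probability of the observed table alone,
#'   exposed for diagnostics).
#' @return list `p`, `n_tables` enumerated, `prob_total` (sum of all
#'   enumerated table probabilities, equal to 1 up to rounding).
#' @export
fisher_exact_rxc <- function(table, max_total = 500,
                             tail = c("probability", "observed_only")) {
  tail <- match.arg(tail)
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  n <- sum(tab)
  if (n > max_total)
    stop("table total ", n, " exceeds the enumeration guard (", max_total,
         "); use a chi-square test instead")
  lp_obs <- .log_table_prob(tab)
  p_sum <- 0
  total <- 0
  count <- 0L
  .enumerate_tables(rowSums(tab), colSums(tab), function(t2, lp) {
    count <<- count + 1L
    pr <- exp(lp)
    total <<- total + pr
    if (lp <= lp_obs + 1e-9) p_sum <<- p_sum + pr
  })
  p <- if (tail == "probability") min(1, p_sum) else exp(lp_obs)
  list(p = p, n_tables = count, prob_total = total)
}

#' Type-I error simulation study for the statistical layer
#'
#' Simulates cohorts under the null (both groups drawn from the same
#' configuration), runs the requested test on each replicate, and reports
#' the fraction rejected at `alpha`. For `"mann_whitney"` the per-fish scalar
#' is the simulated respiration count; for `"chi_square_sap"` each replicate
#' draws per-second speed processes and classifies them.
#'
#' @param test `"mann_whitney"` or `"chi_square_sap"`.
#' @param n_per_group fish per group.
#' @param n_reps number of replicates (>= 100).
#' @param alpha nominal level in `[0, 1]`.
#' @param seed integer seed.
#' @param config `fq_cohort_config` shared by both groups (defaults to the
#'   WT 9 mpf preset).
#' @param duration_s seconds of speed process per fish for the chi-square
#'   variant.
#' @return rejection rate in `[0, 1]`, with attribute `n_reps`.
#' @export
type_i_error_study <- function(test = c("mann_whitney", "chi_square_sap"),
                               n_per_group = 12, n_reps = 1000,
                               alpha = 0.05, seed = 1,
                               config = cohort_preset("wt_9mpf"),
                               duration_s = 600) {
  test <- match.arg(test)
  stopifnot(n_reps >= 100, alpha >= 0, alpha <= 1)
  set.seed(seed)
  reject <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    p <- if (test == "mann_whitney") {
      a <- simulate_respiration(config$respiration_rate_per_min, n_per_group,
                                cv = config$between_fish_cv)$counts_per_minute
      b <- simulate_respiration(config$respiration_rate_per_min, n_per_group,
                                cv = config$between_fish_cv)$counts_per_minute
      mann_whitney(a, b)$p
    } else {
      pa <- .simulate_sap_profiles(config, n_per_group, duration_s)
      pb <- .simulate_sap_profiles(config, n_per_group, duration_s)
      chi_square_sap(pa, pb)$p
    }
    reject[r] <- p <= alpha
  }
  structure(mean(reject), n_reps = n_reps)
}

# SAP profiles straight from the hidden speed process (no positional
# realisation): the per-second speeds are exactly what the kinematics stage
# recovers from a simulated trajectory, so classification is identical.
.simulate_sap_profiles <- function(config, n_fish, duration_s) {
  lapply(seq_len(n_fish), function(i) {
    sp <- simulate_speed_process(config, duration_s)
    series <- structure(list(fish_id = sprintf("f%02d", i), window_s = 1,
                             values = sp$speed_cm_s,
                             effective_time_s = nrow(sp)),
                        class = "fq_speed_series")
    classify_sap(series, config$body_length_cm)
  })
}

#' Separation study: chi-square on SAP between two simulated cohorts
#'
#' Repeatedly simulates one cohort from each configuration (group sizes
#' drawn uniformly from `n_fish_range` per replicate), compares them with
#' [chi_square_sap()], and reports the rejection fraction at `alpha`. With
#' two identical configurations this measures the pooled test's null
#' rejection rate; with distinct configurations, its power.
#'
#' @param config_a,config_b `fq_cohort_config`.
#' @param n_reps replicates.
#' @param alpha nominal level.
#' @param n_fish_range integer range for per-group fish counts.
#' @param duration_s seconds of speed process per fish.
#' @param seed integer seed.
#' @return rejection rate in `[0, 1]`, with attribute `n_reps`.
#' @export
sap_separation_study <- function(config_a, config_b, n_reps = 200,
                                 alpha = 0.01, n_fish_range = c(7, 15),
                                 duration_s = 3600, seed = 1) {
  set.seed(seed)
  reject <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    na <- sample(n_fish_range[1]:n_fish_range[2], 1)
    nb <- sample(n_fish_range[1]:n_fish_range[2], 1)
    pa <- .simulate_sap_profiles(config_a, na, duration_s)
    pb <- .simulate_sap_profiles(config_b, nb, duration_s)
    reject[r] <- chi_square_sap(pa, pb)$p <= alpha
  }
  structure(mean(reject), n_reps = n_reps)
}

#' Pairwise statistics report for a multi-group metric table
#'
#' Runs [mann_whitney()] on every pair of groups for each per-fish metric
#' column, mirroring the pairwise p-value tables of a behavioral figure.
#'
#' @param df data.frame with a `genotype` column and numeric metric columns.
#' @param metrics character vector of metric column names (default: all
#'   numeric columns).
#' @return data.frame `comparison,metric,test,statistic,p_value,flag`.
#' @export
pairwise_stats <- function(df, metrics = NULL) {
  stopifnot("genotype" %in% names(df))
  if (is.null(metrics))
    metrics <- names(df)[vapply(df, is.numeric, logical(1))]
  groups <- unique(df$genotype)
  rows <- list()
  if (length(groups) >= 2) {
    for (pair in utils::combn(groups, 2, simplify = FALSE)) {
      for (m in metrics) {
        a <- df[[m]][df$genotype == pair[1]]
        b <- df[[m]][df$genotype == pair[2]]
        mw <- mann_whitney(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = paste(pair, collapse = "_vs_"), metric = m,
          test = "mann_whitney", statistic = mw$U, p_value = mw$p,
          flag = mw$method)
      }
    }
  }
  do.call(rbind, rows)
}
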