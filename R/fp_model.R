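# Analytic false-positive machinery: per-experiment alien false-positive
# probability, whole-index alien recognition probability, and the exact
# binomial sequence-error tail.

#' Per-experiment false-positive probability of one bucket
#'
#' For an alien k-mer routed into bucket `b`, the probability that the
#' returned slot's occurrence map marks experiment `e` present is
#' `P_b(e) = sum_{x in V_b} p_x W_{x,e}`, with `p_x` the bucket Othello's
#' alien-value distribution and `W_{x,e}` the bit for experiment `e` in
#' stored map `x`. The exact convolution is used for bucket value widths
#' `l < 12`; wider buckets use the flat approximation
#' `(1 - p_0)/(2^l - 1) * sum_x W_{x,e}`.
#'
#' @param index a `kothello_index`.
#' @param b bucket number.
#' @param exact passed to [alien_value_distribution()] (`NULL` = switch on
#'   `l < 12`).
#' @return numeric vector over experiments (named).
#' @export
bucket_false_positive <- function(index, b, exact = NULL) {
  bk <- index$buckets[[b]]
  prof <- alien_value_distribution(bk$oth, exact = exact)
  W <- bucket_slot_matrix(index, b)
  p_slots <- prof$p[seq_len(bk$oth$v) + 1L]  # p_x for x in V_b = 1..v_b
  out <- as.vector(p_slots %*% W)
  names(out) <- index$exp_names
  out
}

# Alien-recognition probability of a bucket Othello.
bucket_alien_recognition <- function(index, b, exact = NULL) {
  alien_value_distribution(index$buckets[[b]]$oth, exact = exact)$p_alien
}

#' Whole-index per-experiment false-positive probabilities
#'
#' Combines the root Othello's alien-value distribution with the bucket
#' terms: `P(e) = p_e^root + sum_b p_(|E|+b)^root * P_b(e)`.
#'
#' @param index a `kothello_index`.
#' @param exact passed to the alien-profile computations.
#' @return numeric vector of probabilities, one per experiment.
#' @export
index_false_positive <- function(index, exact = NULL) {
  mE <- length(index$exp_names)
  prof <- alien_value_distribution(index$root, exact = exact)
  out <- prof$p[seq_len(mE) + 1L]
  for (b in seq_along(index$buckets)) {
    out <- out + prof$p[mE + b + 1L] * bucket_false_positive(index, b, exact)
  }
  names(out) <- index$exp_names
  out
}

#' Whole-index alien recognition probability
#'
#' `P_Alien = P_Alien^root + sum_b p_(|E|+b)^root * P_Alien^b`: the
#' probability that a uniformly random alien k-mer is reported absent
#' everywhere. Exceeds `exp(-1.5) ~ 0.223` for large builds.
#'
#' @inheritParams index_false_positive
#' @return a probability.
#' @export
index_alien_recognition <- function(index, exact = NULL) {
  mE <- length(index$exp_names)
  prof <- alien_value_distribution(index$root, exact = exact)
  out <- prof$p_alien
  for (b in seq_along(index$buckets))
    out <- out + prof$p[mE + b + 1L] * bucket_alien_recognition(index, b, exact)
  out
}

#' Exact binomial upper tail for sequence-query errors
#'
#' Over `w` alien k-mer queries the false-positive count for an experiment
#' is `X(e) ~ Binomial(w, P(e))`; this returns `P[X > c]` by direct
#' term-by-term summation in log space (no normal approximation).
#'
#' @param w number of query k-mers.
#' @param p per-experiment false-positive probability.
#' @param c hit threshold.
#' @return `P[X > c]`.
#' @export
sequence_error_tail <- function(w, p, c) {
  stopifnot(w >= 1L, p >= 0, p <= 1, c >= 0)
  if (p == 0 || c >= w) return(0)
  if (p == 1) return(1)
  i <- seq.int(floor(c) + 1L, w)
  lt <- lchoose(w, i) + i * log(p) + (w - i) * log1p(-p)
  mx <- max(lt)
  exp(mx + log(sum(exp(lt - mx))))
}

#' Measure empirical alien false-positive rates
#'
#' Routes alien probe k-mers through the index and tabulates, per
#' experiment, the fraction reported present, plus the fraction recognized
#' as alien. The probes must be known to be absent from every indexed
#' experiment (e.g. from [sample_alien_kmers()] against the generator
#' truth).
#'
#' @param index a `kothello_index`.
#' @param probes character vector of alien k-mers.
#' @return list with `per_experiment` (fraction of probes falsely present
#'   in each experiment), `alien` (fraction recognized alien), and `n`.
#' @export
empirical_false_positive <- function(index, probes) {
  routes <- query_kmer_routes(index, probes)
  mE <- length(index$exp_names)
  counts <- numeric(mE)
  sing <- routes$status == 1L
  if (any(sing))
    counts <- counts + tabulate(routes$exp[sing], nbins = mE)
  stored <- routes$status == 2L
  if (any(stored)) {
    for (b in unique(routes$bucket[stored])) {
      W <- bucket_slot_matrix(index, b)
      slot_counts <- tabulate(routes$slot[stored & routes$bucket == b],
                              nbins = nrow(W))
      counts <- counts + as.vector(slot_counts %*% W)
    }
  }
  freq <- counts / length(probes)
  names(freq) <- index$exp_names
  list(per_experiment = freq,
       alien = mean(routes$status == 0L),
       n = length(probes))
}

#' Predicted and empirical false-positive report
#'
#' @param index a `kothello_index`.
#' @param probes optional alien probe k-mers for the empirical columns.
#' @return data.frame with one row per experiment.
#' @export
fp_report <- function(index, probes = NULL) {
  pred <- index_false_positive(index)
  df <- data.frame(experiment = index$exp_names, predicted = unname(pred))
  if (!is.null(probes)) {
    emp <- empirical_false_positive(index, probes)
    df$empirical <- unname(emp$per_experiment)
  }
  attr(df, "p_alien") <- index_alien_recognition(index)
  df
}
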