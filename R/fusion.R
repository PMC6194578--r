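# Noise-aware fusion-occurrence calling from junction-spanning k-mer hits:
# junction query construction, background-noise percentile estimation,
# mu-threshold calling, and the theta-containment alternative.

#' Build a junction-spanning fusion query sequence
#'
#' Joins the last `k - 1` bases of the donor exon to the first `k - 1`
#' bases of the acceptor exon (20 + 20 for k = 21), so every constituent
#' k-mer of the assembled sequence spans the fusion breakpoint.
#'
#' @param donor donor-side bases (length `k - 1`, ACGT).
#' @param acceptor acceptor-side bases (length `k - 1`, ACGT).
#' @param k k-mer length.
#' @param fusion_id identifier carried into reports.
#' @return object of class `fusion_query`: `fusion_id`, `donor`,
#'   `acceptor`, `seq` (assembled junction sequence), `k`, `n_kmers`.
#' @export
build_junction_sequence <- function(donor, acceptor, k = 21L,
                                    fusion_id = "fusion") {
  side <- k - 1L
  ok <- function(s) nchar(s) == side && grepl("^[ACGTacgt]+$", s)
  if (!ok(donor))
    stop("donor side must be ", side, " unambiguous ACGT bases")
  if (!ok(acceptor))
    stop("acceptor side must be ", side, " unambiguous ACGT bases")
  seq <- paste0(toupper(donor), toupper(acceptor))
  structure(list(fusion_id = fusion_id, donor = toupper(donor),
                 acceptor = toupper(acceptor), seq = seq, k = as.integer(k),
                 n_kmers = nchar(seq) - k + 1L),
            class = "fusion_query")
}

#' Estimate background noise from a hit-count distribution
#'
#' Nearest-rank percentile of the per-sample k-mer hit counts: the value
#' at rank `ceiling(percentile/100 * N)` of the ascending sort. With true
#' fusion prevalence below 2% of samples, the 98th percentile captures the
#' hits produced by repetitive k-mers rather than by the fusion itself.
#'
#' @param hits integer vector of per-sample k-mer hit counts.
#' @param percentile percentile in (0, 100].
#' @return integer noise level `delta`.
#' @export
estimate_noise_threshold <- function(hits, percentile = 98) {
  if (length(hits) == 0L) stop("empty hit vector")
  stopifnot(percentile > 0, percentile <= 100)
  sorted <- sort(hits)
  unname(sorted[ceiling(percentile / 100 * length(sorted))])
}

#' Noise-aware fusion occurrence calling
#'
#' A sample is called when its hit count reaches `delta + mu`: at least
#' `mu` k-mer hits beyond the estimated background noise. `strict = TRUE`
#' switches the comparison to a strict inequality.
#'
#' @param hits per-sample hit counts (named or not).
#' @param delta background noise level (from
#'   [estimate_noise_threshold()]).
#' @param mu required hits beyond noise (`>= 1`).
#' @param strict use `hits > delta + mu` instead of `>=`.
#' @return integer indices of called samples.
#' @export
call_noise_aware <- function(hits, delta, mu, strict = FALSE) {
  stopifnot(mu >= 1, delta >= 0)
  if (strict) which(hits > delta + mu) else which(hits >= delta + mu)
}

#' Theta-containment calling (fixed hit-ratio threshold)
#'
#' The SBT-style rule: a sample is called when its hit ratio `hits / w`
#' reaches `theta`.
#'
#' @param hits per-sample hit counts.
#' @param w total query k-mers.
#' @param theta minimum hit fraction in (0, 1].
#' @return integer indices of called samples.
#' @export
call_theta <- function(hits, w, theta) {
  stopifnot(theta > 0, theta <= 1, w >= 1)
  which(hits / w >= theta)
}

#' Survey a table of fusion junctions against an index
#'
#' For each junction row (`fusion_id`, `donor`, `acceptor`): assemble the
#' junction sequence, query it, estimate the background noise `delta`,
#' and call occurrences with the noise-aware rule (and optionally with
#' theta containment for comparison). Malformed rows are skipped with a
#' message.
#'
#' @param index a `kothello_index`.
#' @param junctions data.frame with columns `fusion_id`, `donor`,
#'   `acceptor`, or a TSV path with those columns.
#' @param mu noise-aware margin.
#' @param theta optional numeric vector of containment thresholds.
#' @param percentile noise percentile.
#' @param strict passed to [call_noise_aware()].
#' @param out optional TSV path for the per-call report.
#' @return list of per-junction results (`fusion_query`, `hits`, `delta`,
#'   `called`, `theta_called`), with a `calls` data.frame attribute
#'   row-binding every call.
#' @export
fusion_survey <- function(index, junctions, mu = 7L, theta = NULL,
                          percentile = 98, strict = FALSE, out = NULL) {
  if (is.character(junctions))
    junctions <- read.table(junctions, sep = "\t", header = TRUE,
                            colClasses = "character")
  stopifnot(all(c("fusion_id", "donor", "acceptor") %in% names(junctions)))
  results <- list()
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    fq <- tryCatch(
      build_junction_sequence(junctions$donor[i], junctions$acceptor[i],
                              k = index$k,
                              fusion_id = junctions$fusion_id[i]),
      error = function(e) {
        message("fusion_survey: skipping row ", i, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(fq)) next
    q <- query_sequence(index, fq$seq, name = fq$fusion_id)
    delta <- estimate_noise_threshold(q$hits, percentile)
    called <- call_noise_aware(q$hits, delta, mu, strict)
    theta_called <- if (!is.null(theta)) {
      stats::setNames(lapply(theta, function(th) call_theta(q$hits, q$w, th)),
                      paste0("theta_", theta))
    }
    results[[fq$fusion_id]] <- list(query = fq, hits = q$hits, w = q$w,
                                    delta = delta, mu = mu,
                                    called = called,
                                    theta_called = theta_called)
    if (length(called))
      rows[[length(rows) + 1L]] <- data.frame(
        fusion_id = fq$fusion_id,
        sample = index$exp_names[called],
        hits = unname(q$hits[called]),
        total_kmers = q$w,
        delta = delta, mu = mu)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fusion_id = character(0), sample = character(0),
               hits = integer(0), total_kmers = integer(0),
               delta = integer(0), mu = integer(0))
  rownames(calls) <- NULL
  attr(results, "calls") <- calls
  if (!is.null(out))
    write.table(calls, out, sep = "\t", quote = FALSE, row.names = FALSE)
  results
}
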