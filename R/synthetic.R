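# Synthetic cohort generators with exact ground truth. They emulate the
# U/L-shaped k-mer occurrence-frequency structure of real RNA-seq
# collections: a large mass of experiment-private k-mers (frequency 1), a
# core of ubiquitous k-mers (frequency |E|), and accessory transcripts at
# intermediate prevalence.

random_sequences <- function(n, lengths) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Simulate a cohort of k-mer experiments with known truth
#'
#' Generates per-experiment k-mer files (Jellyfish-dump dialect) from a
#' shared transcript pool: `n_private` private transcripts per experiment,
#' `n_core` transcripts present in every experiment, and `n_accessory`
#' transcripts whose prevalence is drawn from a Beta distribution. The
#' exact occurrence matrix is computed brute-force from the emitted
#' per-experiment k-mer sets and returned as the truth table all oracle
#' tests consume. Deterministic under `seed`.
#'
#' @param n_experiments number of experiments `|E|`.
#' @param out_dir directory for the k-mer files and manifest.
#' @param seed integer seed.
#' @param k k-mer length.
#' @param n_private private transcripts per experiment.
#' @param n_core transcripts present in all experiments.
#' @param n_accessory transcripts at intermediate prevalence.
#' @param len_range transcript length range (bases).
#' @param accessory_shape `c(alpha, beta)` of the prevalence Beta draw.
#' @return list: `manifest` (data.frame `name`, `path`), `truth` (the
#'   occurrence stream: `kmers`, `map_id`, `maps`, `m`), `k`, `seed`,
#'   `dir`, and `transcripts` (the generating pool, for queries whose
#'   k-mers are guaranteed indexed).
#' @export
simulate_experiments <- function(n_experiments = 100L, out_dir = tempfile("cohort"),
                                 seed = 1L, k = 21L,
                                 n_private = 2L, n_core = 55L,
                                 n_accessory = 250L,
                                 len_range = c(900L, 1100L),
                                 accessory_shape = c(0.6, 1.8)) {
  stopifnot(n_experiments >= 1L, n_private + n_core + n_accessory >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- as.integer(n_experiments)
  with_seed(seed, {
    rlen <- function(n) sample(len_range[1L]:len_range[2L], n, replace = TRUE)
    core <- if (n_core > 0L) random_sequences(n_core, rlen(n_core)) else character(0)
    accessory <- if (n_accessory > 0L)
      random_sequences(n_accessory, rlen(n_accessory)) else character(0)
    prevalence <- if (n_accessory > 0L)
      pmax(1L, pmin(m, round(rbeta(n_accessory, accessory_shape[1L],
                                   accessory_shape[2L]) * m)))
    else integer(0)
    members <- lapply(prevalence, function(p) sample.int(m, p))
    private <- lapply(seq_len(m), function(e) {
      if (n_private > 0L) random_sequences(n_private, rlen(n_private))
      else character(0)
    })

    core_kmers <- if (length(core)) kmer_set(core, k) else character(0)
    accessory_kmers <- lapply(accessory, kmer_set, k = k)
    exp_sets <- vector("list", m)
    for (e in seq_len(m)) {
      acc <- which(vapply(members, function(mm) e %in% mm, logical(1)))
      exp_sets[[e]] <- sort(unique(c(
        core_kmers,
        unlist(accessory_kmers[acc], use.names = FALSE),
        if (n_private > 0L) kmer_set(private[[e]], k)
      )), method = "radix")
    }
  })
  names <- sprintf("exp%03d", seq_len(m))
  paths <- file.path(out_dir, paste0(names, ".kmers"))
  for (e in seq_len(m))
    write_kmer_file(exp_sets[[e]], paths[e], format = "jellyfish")
  manifest <- data.frame(name = names, path = paths)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- occurrence_truth(exp_sets)
  list(manifest = manifest, truth = truth, k = as.integer(k),
       seed = as.integer(seed), dir = out_dir,
       transcripts = list(core = core, accessory = accessory,
                          members = members, private = private))
}

# Brute-force occurrence stream from per-experiment k-mer sets: the oracle
# every index/query test compares against.
occurrence_truth <- function(exp_sets) {
  union_kmers <- sort(unique(unlist(exp_sets, use.names = FALSE)),
                      method = "radix")
  cols <- lapply(exp_sets, function(s) {
    c("0", "1")[(union_kmers %in% s) + 1L]
  })
  strings <- do.call(paste0, cols)
  maps <- unique(strings)
  list(kmers = union_kmers, map_id = match(strings, maps), maps = maps,
       m = length(exp_sets))
}

# Occurrence-frequency histogram (t = 1..m) of a truth stream.
truth_frequency_histogram <- function(truth) {
  tt <- vapply(truth$maps, function(s) sum(bitstring_to_bits(s)),
               integer(1), USE.NAMES = FALSE)
  tabulate(tt[truth$map_id], nbins = truth$m)
}

#' Generate a spiked fusion cohort with truth calls
#'
#' Emulates the hit-count structure of a junction query against a large
#' cohort: a random 40-base junction whose `k`-mers all span the
#' breakpoint, a subset of "repetitive" junction k-mers injected into a
#' large fraction of samples (background noise), and a small set of spiked
#' samples carrying every junction k-mer (true fusion occurrences). Each
#' sample additionally receives private filler k-mers. The expected noise
#' level is `delta = n_background` and spiked samples reach
#' `n_kmers >= delta + mu` hits; the generator refuses infeasible margins.
#'
#' @param n_samples cohort size.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param k k-mer length.
#' @param n_spiked number of true fusion samples (must stay below 2% of
#'   the cohort).
#' @param n_background junction k-mers injected as repetitive background.
#' @param background_fraction fraction of samples carrying the background.
#' @param n_filler private filler k-mers per sample.
#' @param mu intended calling margin (feasibility check only).
#' @return list: `manifest`, `junctions` (data.frame for
#'   [fusion_survey()]), `truth` (`spiked` sample names, `background_kmers`,
#'   `expected_delta`), `k`, `seed`.
#' @export
spike_fusion_cohort <- function(n_samples = 2000L, out_dir = tempfile("fusion"),
                                seed = 1L, k = 21L, n_spiked = 10L,
                                n_background = 10L,
                                background_fraction = 0.99,
                                n_filler = 50L, mu = 7L) {
  stopifnot(n_samples >= 10L)
  if (n_spiked / n_samples >= 0.02)
    stop("spiked fraction must stay below 2% of samples")
  n_junction_kmers <- 2L * (k - 1L) - k + 1L  # = k - 1
  margin <- n_junction_kmers - n_background - mu
  if (margin < 1L)
    stop("infeasible spike margin: junction yields ", n_junction_kmers,
         " k-mers but background + mu = ", n_background + mu)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    junction <- random_sequences(1L, 2L * (k - 1L))
    jk <- kmer_set(junction, k)
    while (length(jk) < n_junction_kmers) {  # regenerate on rare palindromic collapse
      junction <- random_sequences(1L, 2L * (k - 1L))
      jk <- kmer_set(junction, k)
    }
    background <- sample(jk, n_background)
    spiked <- sort(sample.int(n_samples, n_spiked))
    with_background <- sort(sample.int(n_samples,
                                       ceiling(background_fraction * n_samples)))
    filler_seed <- sample.int(2^30, 1L)
  })
  filler <- random_kmers(n_filler * n_samples, k, seed = filler_seed,
                         canonical = TRUE, distinct = TRUE)
  names <- sprintf("sample%04d", seq_len(n_samples))
  paths <- file.path(out_dir, paste0(names, ".kmers"))
  exp_sets <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    s <- filler[((i - 1L) * n_filler + 1L):(i * n_filler)]
    if (i %in% with_background) s <- c(s, background)
    if (i %in% spiked) s <- c(s, jk)
    exp_sets[[i]] <- sort(unique(s), method = "radix")
    write_kmer_file(exp_sets[[i]], paths[i], format = "plain")
  }
  manifest <- data.frame(name = names, path = paths)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  donor <- substr(junction, 1L, k - 1L)
  acceptor <- substr(junction, k, 2L * (k - 1L))
  list(manifest = manifest,
       junctions = data.frame(fusion_id = "spike1", donor = donor,
                              acceptor = acceptor),
       truth = list(spiked = names[spiked],
                    background_kmers = background,
                    background_samples = names[with_background],
                    expected_delta = if (background_fraction >= 0.98)
                      as.integer(n_background) else 0L,
                    junction_kmers = jk,
                    exp_sets = exp_sets),
       k = as.integer(k), seed = as.integer(seed), dir = out_dir)
}
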