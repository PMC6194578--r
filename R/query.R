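# Sequence-to-k-mer decomposition and index lookup: per-experiment hit
# counts, hit ratios, and optional k-mer hit maps along the query.

#' Decompose a sequence into query k-mers
#'
#' Slides a window of width `k` over the sequence; windows containing a
#' non-ACGT character are marked invalid (`NA`), excluded from the valid
#' k-mer total `w`, and reported as gaps in hit maps. k-mers are
#' canonicalized exactly as at build time.
#'
#' @param seq a single sequence string (IUPAC alphabet).
#' @param k k-mer length.
#' @return object of class `decomposition`: `kmers` (character, `NA` at
#'   invalid windows, one per 1-based start position), `w` (valid count).
#' @export
decompose_sequence <- function(seq, k) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  if (nchar(seq) < k) {
    warning("sequence shorter than k; empty decomposition (w = 0)")
    kmers <- character(0)
  } else {
    kmers <- cpp_decompose(seq, as.integer(k), TRUE)
  }
  structure(list(kmers = kmers, w = sum(!is.na(kmers))),
            class = "decomposition")
}

# Vectorized routing of k-mers through root and bucket Othellos.
# status: 0 = absent, 1 = single experiment (value = exp id),
#         2 = stored map (value = bucket, slot).
query_kmer_routes <- function(index, kmers) {
  mE <- length(index$exp_names)
  nB <- length(index$buckets)
  tau <- query_othello(index$root, kmers)
  status <- integer(length(kmers))
  exp <- integer(length(kmers))
  bucket <- integer(length(kmers))
  slot <- integer(length(kmers))
  is_single <- tau >= 1L & tau <= mE
  status[is_single] <- 1L
  exp[is_single] <- tau[is_single]
  is_bucket <- tau > mE & tau <= mE + nB
  if (any(is_bucket)) {
    bs <- tau[is_bucket] - mE
    idx_all <- which(is_bucket)
    for (b in unique(bs)) {
      idx <- idx_all[bs == b]
      sl <- query_othello(index$buckets[[b]]$oth, kmers[idx])
      ok <- sl >= 1L & sl <= index$buckets[[b]]$oth$v
      status[idx[ok]] <- 2L
      bucket[idx[ok]] <- b
      slot[idx[ok]] <- sl[ok]
    }
  }
  list(status = status, exp = exp, bucket = bucket, slot = slot)
}

# Resolve routes to occurrence-map bitstrings over all experiments.
route_map_strings <- function(index, routes) {
  mE <- length(index$exp_names)
  zero <- strrep("0", mE)
  out <- rep.int(zero, length(routes$status))
  sing <- routes$status == 1L
  if (any(sing)) {
    units <- vapply(seq_len(mE), function(e) {
      b <- integer(mE); b[e] <- 1L; bits_to_bitstring(b)
    }, character(1))
    out[sing] <- units[routes$exp[sing]]
  }
  stored <- routes$status == 2L
  if (any(stored)) {
    for (b in unique(routes$bucket[stored])) {
      sel <- stored & routes$bucket == b
      out[sel] <- bucket_slot_strings(index, b)[routes$slot[sel]]
    }
  }
  out
}

#' Query a single k-mer
#'
#' Three-way outcome following the root Othello value `tau`: a value in
#' `1..|E|` reports presence only in that experiment; a bucket value
#' continues into the bucket Othello and decodes the stored occurrence
#' map; any value outside the valid set (at either level) reports the
#' k-mer absent everywhere.
#'
#' @param index a `kothello_index`.
#' @param kmer one k-mer (canonicalized internally).
#' @return list with `status` (`"absent"`, `"single"` or `"map"`),
#'   `experiment` (for single hits) and `map` (an `occurrence_map` for
#'   stored maps).
#' @export
query_kmer <- function(index, kmer) {
  kmer <- cpp_canonical_kmers(kmer, index$k)
  if (is.na(kmer)) stop("invalid k-mer")
  r <- query_kmer_routes(index, kmer)
  if (r$status == 0L) {
    list(status = "absent", experiment = NA_integer_, map = NULL)
  } else if (r$status == 1L) {
    list(status = "single", experiment = r$exp, map = NULL)
  } else {
    s <- bucket_slot_strings(index, r$bucket)[r$slot]
    list(status = "map", experiment = NA_integer_, map = occurrence_map(s))
  }
}

# Bulk form used by tests and the false-positive machinery: occurrence-map
# bitstrings for a vector of (already canonical) k-mers.
query_kmer_maps <- function(index, kmers) {
  route_map_strings(index, query_kmer_routes(index, kmers))
}

#' Query a sequence for per-experiment hits
#'
#' Decomposes the sequence, looks up every valid k-mer, and aggregates the
#' retrieved occurrence maps into per-experiment hit counts and hit ratios
#' (`hits / w`). Hit maps (presence flags per window position) are emitted
#' only on request.
#'
#' @param index a `kothello_index`.
#' @param seq query sequence.
#' @param name query name carried into reports.
#' @param emit_hit_maps also return the per-experiment hit maps.
#' @return object of class `sequence_query`: `name`, `w`, `hits` (named
#'   integer vector), `ratio`, and optionally `hit_maps` (character, one
#'   "0"/"1"/"." string per experiment, "." at invalid windows).
#' @export
query_sequence <- function(index, seq, name = "query",
                           emit_hit_maps = FALSE) {
  dec <- decompose_sequence(seq, index$k)
  mE <- length(index$exp_names)
  hits <- integer(mE)
  names(hits) <- index$exp_names
  hit_maps <- NULL
  if (dec$w > 0L) {
    valid <- !is.na(dec$kmers)
    strings <- query_kmer_maps(index, dec$kmers[valid])
    bm <- matrix(unlist(lapply(strings, bitstring_to_bits)),
                 ncol = mE, byrow = TRUE)
    hits <- as.integer(colSums(bm))
    names(hits) <- index$exp_names
    if (emit_hit_maps) {
      full <- matrix(".", nrow = length(dec$kmers), ncol = mE)
      full[valid, ] <- as.character(bm)
      hit_maps <- apply(full, 2L, paste, collapse = "")
      names(hit_maps) <- index$exp_names
    }
  }
  structure(list(name = name, w = dec$w,
                 available = dec$w > 0L,
                 hits = hits,
                 ratio = if (dec$w > 0L) hits / dec$w else rep(NA_real_, mE),
                 hit_maps = hit_maps),
            class = "sequence_query")
}

#' @export
print.sequence_query <- function(x, ...) {
  cat(sprintf("sequence_query '%s': w=%d valid k-mers; max hits %s\n",
              x$name, x$w,
              if (x$available) max(x$hits) else "n/a"))
  invisible(x)
}

#' Batch-query a FASTA file
#'
#' One result per record, order-preserving. With `threads > 1` queries run
#' in parallel workers with output identical to serial execution.
#'
#' @param index a `kothello_index`.
#' @param fasta path to a query FASTA.
#' @param out optional TSV output path (columns `query`, `experiment`,
#'   `hits`, `total_kmers`, `ratio`).
#' @param threads worker count.
#' @return the report data.frame, invisibly when `out` is given.
#' @export
batch_query <- function(index, fasta, out = NULL, threads = 1L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) {
    warning("empty query FASTA: ", fasta)
    df <- data.frame(query = character(0), experiment = character(0),
                     hits = integer(0), total_kmers = integer(0),
                     ratio = numeric(0))
  } else {
    qnames <- sub("\\s.*$", "", names(seqs))
    run_one <- function(i) {
      q <- query_sequence(index, as.character(seqs[[i]]), name = qnames[i])
      data.frame(query = q$name, experiment = index$exp_names,
                 hits = unname(q$hits), total_kmers = q$w,
                 ratio = unname(q$ratio))
    }
    res <- if (threads > 1L)
      parallel::mclapply(seq_along(seqs), run_one, mc.cores = threads)
    else lapply(seq_along(seqs), run_one)
    df <- do.call(rbind, res)
    rownames(df) <- NULL
  }
  if (!is.null(out)) {
    write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
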