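# Two-level index construction: group-merge of per-experiment k-mer files,
# sampling-based bucket range estimation, the single-occurrence root
# optimization, and per-bucket Othello construction.
#
# Occurrence maps travel through the pipeline as "0"/"1" bitstrings with a
# per-k-mer index into the distinct strings, so identical maps are encoded
# and stored once.

#' Read an experiment manifest
#'
#' A manifest is a TSV with two columns, experiment name and k-mer file
#' path. Row order defines experiment IDs `1..|E|`.
#'
#' @param path manifest TSV (no header).
#' @return data.frame with columns `name`, `path`.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("name", "path"),
                   colClasses = "character", quote = "")
  validate_manifest(df)
  df
}

validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("name", "path") %in% names(manifest)),
            nrow(manifest) >= 1L)
  if (anyDuplicated(manifest$name))
    stop("duplicate experiment names in manifest: ",
         paste(unique(manifest$name[duplicated(manifest$name)]),
               collapse = ", "))
  invisible(manifest)
}

#' Build a group file from a small set of experiments
#'
#' Merges the sorted k-mer sets of up to `group_size` member experiments
#' into one record per k-mer carrying its group-local occurrence map
#' (delta-list encoded when written to disk). The result is independent of
#' merge interleaving.
#'
#' @param kmer_sets list of sorted unique canonical k-mer vectors, one per
#'   member experiment.
#' @param member_ids global experiment IDs of the members (ascending).
#' @param group_id integer group identifier.
#' @return object of class `kmer_group`: `id`, `member_ids`, `m`, `kmers`
#'   (sorted union), `map_id`, `maps` (distinct group-local bitstrings).
#' @export
build_group_file <- function(kmer_sets, member_ids, group_id = 1L) {
  stopifnot(length(kmer_sets) >= 1L,
            length(member_ids) == length(kmer_sets))
  union_kmers <- sort(unique(unlist(kmer_sets, use.names = FALSE)),
                      method = "radix")
  cols <- lapply(kmer_sets, function(s) {
    ifelse(union_kmers %in% s, "1", "0")
  })
  strings <- do.call(paste0, cols)
  maps <- unique(strings)
  map_id <- match(strings, maps)
  structure(list(id = as.integer(group_id),
                 member_ids = as.integer(member_ids),
                 m = length(kmer_sets),
                 kmers = union_kmers, map_id = map_id, maps = maps),
            class = "kmer_group")
}

#' Merge group files into the global occurrence stream
#'
#' Concatenates group-local occurrence maps into global experiment order.
#' Groups must partition experiments `1..|E|` contiguously in ID order.
#'
#' @param groups list of `kmer_group` objects.
#' @return the occurrence stream: a list with `kmers` (sorted union over
#'   all experiments), `map_id`, `maps` (distinct global bitstrings) and
#'   `m`.
#' @export
merge_group_files <- function(groups) {
  stopifnot(length(groups) >= 1L)
  ids <- unlist(lapply(groups, `[[`, "member_ids"))
  if (anyDuplicated(ids))
    stop("experiment IDs overlap across groups")
  if (!identical(sort(ids), seq_along(ids)))
    stop("groups must cover experiments 1..|E| exactly")
  groups <- groups[order(vapply(groups, function(g) g$member_ids[1L],
                                integer(1)))]
  union_kmers <- sort(unique(unlist(lapply(groups, `[[`, "kmers"),
                                    use.names = FALSE)), method = "radix")
  n <- length(union_kmers)
  cols <- lapply(groups, function(g) {
    zero <- strrep("0", g$m)
    out <- rep.int(zero, n)
    out[match(g$kmers, union_kmers)] <- g$maps[g$map_id]
    out
  })
  strings <- do.call(paste0, cols)
  maps <- unique(strings)
  list(kmers = union_kmers, map_id = match(strings, maps),
       maps = maps, m = length(ids))
}

#' Estimate bucket encoding-length ranges from a length sample
#'
#' `L_i`, the estimated number of k-mers whose chosen encoding is `i` bits
#' long, is the sampled count scaled by the inverse sampling fraction.
#' Starting from `n_1 = 1`, each bucket greedily takes the maximal
#' contiguous length range whose estimated payload
#' `sum_i i * L_i` stays within the capacity; the final range is
#' open-ended.
#'
#' @param sample_lengths integer vector of chosen-encoding bit lengths for
#'   a deterministic sample of k-mers.
#' @param total total number of k-mers the sample represents.
#' @param cap_bytes per-bucket payload capacity in bytes (compared against
#'   the estimate converted to bits).
#' @return data.frame with columns `bucket`, `min_bits` (closed),
#'   `max_bits` (open; `Inf` for the last bucket).
#' @export
estimate_bucket_ranges <- function(sample_lengths, total = length(sample_lengths),
                                   cap_bytes = 128 * 2^20) {
  if (length(sample_lengths) == 0L) stop("empty encoding-length sample")
  scale <- total / length(sample_lengths)
  L <- tabulate(sample_lengths) * scale
  cap_bits <- cap_bytes * 8
  starts <- integer(0)
  cur_start <- 1L
  acc <- 0
  for (i in seq_along(L)) {
    add <- i * L[i]
    if (acc + add > cap_bits && acc > 0) {
      starts <- c(starts, cur_start)
      cur_start <- i
      acc <- 0
    }
    acc <- acc + add
  }
  starts <- c(starts, cur_start)
  data.frame(bucket = seq_along(starts),
             min_bits = starts,
             max_bits = c(starts[-1L], Inf))
}

#' Assign encoded occurrence maps to buckets
#'
#' k-mers present in exactly one experiment are diverted to the root-direct
#' list; all others go to the bucket whose length range contains their
#' chosen encoding's bit length. Realized bucket payloads may exceed the
#' sampled estimate; a message is emitted but assignment proceeds.
#'
#' @param bit_lengths chosen-encoding bit lengths of the bucketed k-mers.
#' @param specs bucket ranges from [estimate_bucket_ranges()].
#' @param cap_bytes capacity used only for the overflow message.
#' @return integer bucket index per k-mer.
#' @export
assign_to_buckets <- function(bit_lengths, specs, cap_bytes = NULL) {
  idx <- findInterval(bit_lengths, specs$min_bits)
  idx[idx < 1L] <- 1L
  if (!is.null(cap_bytes)) {
    payload <- tapply(bit_lengths, factor(idx, levels = specs$bucket), sum)
    over <- which(!is.na(payload) & payload > cap_bytes * 8)
    if (length(over))
      message("bucket payload exceeds the sampled estimate for bucket(s) ",
              paste(over, collapse = ", "), "; assignment proceeds")
  }
  idx
}

# Shared back half of construction (steps 2-3), also used by insertion:
# from the merged occurrence stream to a built index.
index_from_stream <- function(stream, exp_names, k, cap_bytes, seed,
                              group_size, groups = NULL, keep_kmers = FALSE,
                              max_retries = 100L) {
  mE <- length(exp_names)
  stopifnot(stream$m == mE)
  maps <- stream$maps
  tt <- vapply(maps, function(s) sum(bitstring_to_bits(s)), integer(1),
               USE.NAMES = FALSE)
  if (any(tt == 0L)) stop("all-absent occurrence map in merged stream")
  kmer_t <- tt[stream$map_id]
  single <- kmer_t == 1L
  single_exp_of_map <- ifelse(tt == 1L,
                              vapply(maps, function(s) {
                                as.integer(regexpr("1", s, fixed = TRUE))
                              }, integer(1), USE.NAMES = FALSE),
                              NA_integer_)

  # chosen encoding per distinct bucketed map
  enc <- vector("list", length(maps))
  multi <- which(tt >= 2L)
  for (i in multi) enc[[i]] <- choose_encoding(maps[i])
  enc_len <- rep(NA_integer_, length(maps))
  enc_len[multi] <- vapply(enc[multi], `[[`, integer(1), "bit_length")

  n_bucketed <- sum(!single)
  buckets <- list()
  specs <- NULL
  bucket_of <- integer(0)
  if (n_bucketed > 0L) {
    kmer_len <- enc_len[stream$map_id[!single]]
    sample_size <- min(1e7, max(ceiling(0.001 * n_bucketed), 1e4), n_bucketed)
    samp <- with_seed(seed, sample.int(n_bucketed, sample_size))
    specs <- estimate_bucket_ranges(kmer_len[samp], n_bucketed, cap_bytes)
    bucket_of <- assign_to_buckets(kmer_len, specs, cap_bytes)
    used <- sort(unique(bucket_of))
    specs <- specs[specs$bucket %in% used, , drop = FALSE]
    specs$bucket <- seq_len(nrow(specs))
    rownames(specs) <- NULL
    bucket_of <- match(bucket_of, used)

    bk_kmers <- split(stream$kmers[!single], bucket_of)
    bk_mapid <- split(stream$map_id[!single], bucket_of)
    buckets <- lapply(seq_len(nrow(specs)), function(b) {
      mids <- bk_mapid[[b]]
      local <- unique(mids)
      slot <- match(mids, local)
      oth <- build_othello(bk_kmers[[b]], slot, v = length(local),
                           seed = seed + b, max_retries = max_retries)
      list(id = b,
           oth = oth,
           kinds = vapply(enc[local], `[[`, integer(1), "kind"),
           bit_lengths = vapply(enc[local], `[[`, integer(1), "bit_length"),
           payloads = lapply(enc[local], `[[`, "payload"))
    })
  }

  root_values <- integer(length(stream$kmers))
  root_values[single] <- single_exp_of_map[stream$map_id[single]]
  root_values[!single] <- mE + bucket_of
  root <- build_othello(stream$kmers, root_values, v = mE + length(buckets),
                        seed = seed, max_retries = max_retries)

  structure(list(k = as.integer(k),
                 exp_names = exp_names,
                 n_kmers = length(stream$kmers),
                 seed = as.integer(seed),
                 group_size = as.integer(group_size),
                 cap_bytes = cap_bytes,
                 root = root,
                 bucket_specs = specs,
                 buckets = buckets,
                 groups = groups,
                 kmers = if (keep_kmers) stream$kmers else NULL,
                 cache = new.env(parent = emptyenv()),
                 dir = NULL),
            class = "kothello_index")
}

#' Build the two-level k-mer occurrence index
#'
#' Runs the full construction: per-experiment k-mer files are merged in
#' groups of `group_size`, the groups are merged into the global occurrence
#' stream, bucket length ranges are estimated from a seeded sample,
#' identical encoded maps are deduplicated into shared slots, a per-bucket
#' Othello maps each k-mer to its slot, and the root Othello maps every
#' indexed k-mer to either its single experiment (t = 1) or its bucket.
#'
#' @param manifest data.frame with columns `name`, `path`, or a manifest
#'   TSV path.
#' @param k odd k-mer length in 15..31.
#' @param group_size experiments per group file.
#' @param cap_bytes per-bucket payload capacity in bytes.
#' @param seed integer seed driving sampling and all hash seeds.
#' @param keep_groups retain group objects in the index (needed for later
#'   [insert_experiments()]; they are also written by [save_index()]).
#' @param keep_kmers retain the indexed k-mer set (the index itself stores
#'   no keys).
#' @param max_retries Othello reseed cap.
#' @return object of class `kothello_index`.
#' @export
build_index <- function(manifest, k = 21L, group_size = 50L,
                        cap_bytes = 128 * 2^20, seed = 1L,
                        keep_groups = FALSE, keep_kmers = FALSE,
                        max_retries = 100L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  validate_manifest(manifest)
  k <- as.integer(k)
  if (k < 15L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and in 15..31 (even k admits palindromic k-mers)")
  kmer_sets <- lapply(manifest$path, read_kmer_file, k = k)
  groups <- build_groups(kmer_sets, group_size)
  stream <- merge_group_files(groups)
  index_from_stream(stream, manifest$name, k, cap_bytes, seed, group_size,
                    groups = if (keep_groups) groups else NULL,
                    keep_kmers = keep_kmers, max_retries = max_retries)
}

build_groups <- function(kmer_sets, group_size, first_id = 1L,
                         first_group = 1L) {
  n <- length(kmer_sets)
  starts <- seq(1L, n, by = group_size)
  lapply(seq_along(starts), function(g) {
    i <- starts[g]:min(starts[g] + group_size - 1L, n)
    build_group_file(kmer_sets[i], member_ids = first_id + i - 1L,
                     group_id = first_group + g - 1L)
  })
}

#' Insert new experiments into an existing index
#'
#' Requires the group files retained from a previous build (via
#' `keep_groups = TRUE` or an index directory saved with groups). New
#' experiments are appended as new groups with IDs `|E|+1..`, and steps
#' 2-3 of construction are repeated; the result answers every query
#' identically to a from-scratch build on the union.
#'
#' @param index a `kothello_index` carrying groups, or a directory saved
#'   with [save_index()] including groups.
#' @param manifest new experiments (data.frame `name`,`path` or TSV path).
#' @param ... passed through to the rebuild (e.g. `keep_kmers`).
#' @export
insert_experiments <- function(index, manifest, ...) {
  if (is.character(index)) index <- load_index(index, preload = TRUE)
  stopifnot(inherits(index, "kothello_index"))
  if (is.null(index$groups))
    stop("group files were not retained; rebuild with keep_groups = TRUE")
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0L) {
    new_names <- index$exp_names
    groups <- index$groups
  } else {
    validate_manifest(manifest)
    if (any(manifest$name %in% index$exp_names))
      stop("duplicate experiment names: ",
           paste(intersect(manifest$name, index$exp_names), collapse = ", "))
    kmer_sets <- lapply(manifest$path, read_kmer_file, k = index$k)
    old_groups <- index$groups
    new_groups <- build_groups(kmer_sets, index$group_size,
                               first_id = length(index$exp_names) + 1L,
                               first_group = length(old_groups) + 1L)
    groups <- c(old_groups, new_groups)
    new_names <- c(index$exp_names, manifest$name)
  }
  stream <- merge_group_files(groups)
  index_from_stream(stream, new_names, index$k, index$cap_bytes,
                    index$seed, index$group_size, groups = groups, ...)
}

#' @export
print.kothello_index <- function(x, ...) {
  cat(sprintf("kothello_index: %d experiments, %d indexed %d-mers, %d bucket(s)\n",
              length(x$exp_names), x$n_kmers, x$k, length(x$buckets)))
  invisible(x)
}

# ---- slot access (supports lazy on-disk buckets) ---------------------------

bucket_payloads <- function(index, b) {
  bk <- index$buckets[[b]]
  if (!is.null(bk$payloads)) return(bk$payloads)
  key <- paste0("payloads_", b)
  cached <- index$cache[[key]]
  if (!is.null(cached)) return(cached)
  path <- file.path(index$dir, sprintf("bucket_%d.maps.gz", b))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  blob <- readBin(con, "raw", n = sum(ceiling(bk$bit_lengths / 8)) + 8L)
  sizes <- as.integer(ceiling(bk$bit_lengths / 8))
  ends <- cumsum(sizes)
  payloads <- lapply(seq_along(sizes), function(i) {
    if (sizes[i] == 0L) raw(0)
    else blob[(ends[i] - sizes[i] + 1L):ends[i]]
  })
  index$cache[[key]] <- payloads
  payloads
}

# decoded slot maps of a bucket, as bitstrings (cached)
bucket_slot_strings <- function(index, b) {
  key <- paste0("slots_", b)
  cached <- index$cache[[key]]
  if (!is.null(cached)) return(cached)
  bk <- index$buckets[[b]]
  payloads <- bucket_payloads(index, b)
  m <- length(index$exp_names)
  out <- vapply(seq_along(payloads), function(i) {
    map <- decode_occurrence(new_encoded(bk$kinds[i], payloads[[i]],
                                         bk$bit_lengths[i], m), m)
    bits_to_bitstring(map$bits)
  }, character(1))
  index$cache[[key]] <- out
  out
}

# decoded slot maps as a v_b x m 0/1 matrix
bucket_slot_matrix <- function(index, b) {
  s <- bucket_slot_strings(index, b)
  matrix(unlist(lapply(s, bitstring_to_bits)), nrow = length(s),
         byrow = TRUE)
}

# ---- persistence -----------------------------------------------------------

#' Save / load an index directory
#'
#' Layout: `meta.xml` (experiment names, k, parameters, bucket table with
#' per-slot encoding kind and bit length), `root.oth`, `bucket_<b>.oth`,
#' gzip-compressed `bucket_<b>.maps.gz`, and optionally `groups/` for later
#' insertion.
#'
#' @param index a `kothello_index`.
#' @param dir target directory (created if needed).
#' @param keep_groups write retained group files under `groups/`.
#' @return `dir` invisibly.
#' @export
save_index <- function(index, dir, keep_groups = !is.null(index$groups)) {
  stopifnot(inherits(index, "kothello_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- xml2::xml_new_root("kothello", version = "1")
  xml2::xml_add_child(doc, "k", as.character(index$k))
  xml2::xml_add_child(doc, "seed", as.character(index$seed))
  xml2::xml_add_child(doc, "group_size", as.character(index$group_size))
  xml2::xml_add_child(doc, "cap_bytes", format(index$cap_bytes, scientific = FALSE))
  xml2::xml_add_child(doc, "n_kmers", as.character(index$n_kmers))
  exps <- xml2::xml_add_child(doc, "experiments",
                              count = as.character(length(index$exp_names)))
  for (i in seq_along(index$exp_names))
    xml2::xml_add_child(exps, "experiment", index$exp_names[i],
                        id = as.character(i))
  bks <- xml2::xml_add_child(doc, "buckets",
                             count = as.character(length(index$buckets)))
  for (b in seq_along(index$buckets)) {
    bk <- index$buckets[[b]]
    spec <- index$bucket_specs[b, ]
    node <- xml2::xml_add_child(bks, "bucket", id = as.character(b),
                                min_bits = as.character(spec$min_bits),
                                max_bits = as.character(spec$max_bits),
                                v = as.character(bk$oth$v))
    for (s in seq_along(bk$kinds))
      xml2::xml_add_child(node, "slot", id = as.character(s),
                          kind = as.character(bk$kinds[s]),
                          bits = as.character(bk$bit_lengths[s]))
    payloads <- bucket_payloads(index, b)
    con <- gzfile(file.path(dir, sprintf("bucket_%d.maps.gz", b)), "wb")
    writeBin(do.call(c, payloads), con)
    close(con)
    write_othello(bk$oth, file.path(dir, sprintf("bucket_%d.oth", b)))
  }
  write_othello(index$root, file.path(dir, "root.oth"))
  xml2::write_xml(doc, file.path(dir, "meta.xml"))
  if (keep_groups && !is.null(index$groups)) {
    gdir <- file.path(dir, "groups")
    dir.create(gdir, showWarnings = FALSE)
    for (g in index$groups)
      write_group_file(g, file.path(gdir, sprintf("group_%d.tsv.gz", g$id)),
                       k = index$k)
  }
  invisible(dir)
}

#' @param dir index directory produced by `save_index`.
#' @param preload decompress all bucket payloads up front (online mode);
#'   with `preload = FALSE` bucket payloads load lazily on first access.
#'   Both modes answer identically.
#' @rdname save_index
#' @export
load_index <- function(dir, preload = TRUE) {
  meta_path <- file.path(dir, "meta.xml")
  if (!file.exists(meta_path)) stop("missing meta.xml in ", dir)
  doc <- xml2::read_xml(meta_path)
  if (xml2::xml_attr(doc, "version") != "1")
    stop("unsupported index format version")
  getnum <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(doc, tag)))
  k <- as.integer(getnum("./k"))
  exp_nodes <- xml2::xml_find_all(doc, "./experiments/experiment")
  exp_names <- xml2::xml_text(exp_nodes)
  bucket_nodes <- xml2::xml_find_all(doc, "./buckets/bucket")
  specs <- NULL
  buckets <- list()
  if (length(bucket_nodes)) {
    specs <- data.frame(
      bucket = as.integer(xml2::xml_attr(bucket_nodes, "id")),
      min_bits = as.numeric(xml2::xml_attr(bucket_nodes, "min_bits")),
      max_bits = as.numeric(xml2::xml_attr(bucket_nodes, "max_bits")))
    buckets <- lapply(seq_along(bucket_nodes), function(b) {
      slots <- xml2::xml_find_all(bucket_nodes[[b]], "./slot")
      list(id = b,
           oth = read_othello(file.path(dir, sprintf("bucket_%d.oth", b))),
           kinds = as.integer(xml2::xml_attr(slots, "kind")),
           bit_lengths = as.integer(xml2::xml_attr(slots, "bits")),
           payloads = NULL)
    })
  }
  idx <- structure(list(k = k,
                        exp_names = exp_names,
                        n_kmers = as.integer(getnum("./n_kmers")),
                        seed = as.integer(getnum("./seed")),
                        group_size = as.integer(getnum("./group_size")),
                        cap_bytes = getnum("./cap_bytes"),
                        root = read_othello(file.path(dir, "root.oth")),
                        bucket_specs = specs,
                        buckets = buckets,
                        groups = NULL,
                        kmers = NULL,
                        cache = new.env(parent = emptyenv()),
                        dir = dir),
                   class = "kothello_index")
  gdir <- file.path(dir, "groups")
  if (dir.exists(gdir)) {
    paths <- list.files(gdir, pattern = "^group_\\d+\\.tsv", full.names = TRUE)
    ord <- order(as.integer(sub(".*group_(\\d+)\\..*", "\\1", paths)))
    idx$groups <- lapply(paths[ord], read_group_file)
  }
  if (preload)
    for (b in seq_along(idx$buckets)) bucket_payloads(idx, b)
  idx
}

# ---- group file persistence ------------------------------------------------

raw_to_hexstr <- function(bytes, nibbles) {
  substr(paste(format(bytes), collapse = ""), 1L, nibbles)
}

hexstr_to_raw <- function(s) {
  if (nchar(s) %% 2L == 1L) s <- paste0(s, "0")
  n <- nchar(s) / 2L
  as.raw(strtoi(substring(s, 2L * seq_len(n) - 1L, 2L * seq_len(n)), 16L))
}

#' Write / read a group file
#'
#' Text format (gzip-transparent): header lines `#kothello-group`, `#k`,
#' `#members`, then one `k-mer<TAB>hex` record per k-mer, where `hex` is
#' the group-local delta-list hexadecimal stream.
#'
#' @param group a `kmer_group`.
#' @param path output path (`.gz` for compression).
#' @param k k-mer length recorded in the header.
#' @export
write_group_file <- function(group, path, k) {
  stopifnot(inherits(group, "kmer_group"))
  hexes <- vapply(group$maps, function(s) {
    enc <- hex_encode_delta_list(encode_delta_list(s), group$m)
    raw_to_hexstr(enc$payload, enc$bit_length / 4L)
  }, character(1), USE.NAMES = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0("#kothello-group\t", group$id),
               paste0("#k\t", k),
               paste0("#members\t", paste(group$member_ids, collapse = ","))),
             con)
  writeLines(paste0(group$kmers, "\t", hexes[group$map_id]), con)
  invisible(path)
}

#' @param path group file path.
#' @rdname write_group_file
#' @export
read_group_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "#kothello-group"))
    stop("not a kothello group file: ", path)
  group_id <- as.integer(sub("^#kothello-group\t", "", lines[1L]))
  member_ids <- as.integer(strsplit(sub("^#members\t", "", lines[3L]),
                                    ",", fixed = TRUE)[[1L]])
  m <- length(member_ids)
  body <- lines[-(1:3)]
  kmers <- sub("\t.*$", "", body)
  hexes <- sub("^[^\t]*\t", "", body)
  uh <- unique(hexes)
  maps <- vapply(uh, function(h) {
    runs <- hex_decode_stream(hexstr_to_raw(h), m)
    bits_to_bitstring(decode_delta_list(runs, m)$bits)
  }, character(1), USE.NAMES = FALSE)
  structure(list(id = group_id, member_ids = member_ids, m = m,
                 kmers = kmers, map_id = match(hexes, uh), maps = maps),
            class = "kmer_group")
}
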