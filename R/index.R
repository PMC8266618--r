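# Sorted (k-mer, taxon) index with depth-6 prefix trie, memory-budgeted
# construction (chunked sort + k-way merge), binary persistence, updating and
# shrinking.
#
# On-disk layout (little-endian):
#   <path>        magic "AAKX", int32 version, k_max, width_bits, frames,
#                 shrunken flag, n_entries; then n fixed-width records.
#                 Full record: k_max key bytes + int32 content line.
#                 Lossless-shrunken record: (k_max-6) suffix bytes +
#                 uint16 content line.
#   <path>.trie   magic "AAKT", int32 version, n_leaves; then n*6 prefix
#                 bytes, int32 lower[n], int32 upper[n] (0-based, half-open).
#   <path>.meta.json  level, frames, checksum binding the content file,
#                 per-taxon k-mer frequencies, the codon table.

INDEX_MAGIC <- "AAKX"
TRIE_MAGIC <- "AAKT"
INDEX_VERSION <- 1L
MIN_CHUNK_ENTRIES <- 100L
LOSSLESS_MAX_LINES <- 65535L

record_bytes <- function(k_max, shrunken = FALSE) {
  if (shrunken) (k_max - TRIE_DEPTH) + 2L else k_max + 4L
}

new_index <- function(entries, content, table, meta) {
  meta$n_entries <- nrow(entries)
  structure(
    list(
      entries = entries,
      trie = build_trie(entries$key),
      freq = tabulate(entries$line, nbins = nrow(content)),
      content = content,
      table = table,
      meta = meta
    ),
    class = "aak_index"
  )
}

#' Build the sorted k-mer index from reference FASTA files
#'
#' Every reference sequence is translated in `frames` reading frames, its
#' full-length k-mer windows are paired with the content-file line number of
#' the record's taxon, and the pairs are sorted and deduplicated. The build
#' honours a soft memory budget: pairs accumulate in a buffer sized from
#' `mem_mb`; a full buffer is sorted, deduplicated and spilled to a temporary
#' sorted chunk, and all chunks are k-way merged (with cross-chunk
#' deduplication of identical pairs) at the end. The same k-mer may carry
#' several taxa; identical (k-mer, taxon) pairs are stored once. The final
#' index is independent of the budget, byte for byte.
#'
#' @param fasta_paths Character vector of reference FASTA files.
#' @param content The [build_content()] registry for these references; every
#'   record's accession must be present in it.
#' @param k_max Letters per k-mer: 12 (64-bit words) or 25 (128-bit words).
#' @param frames Reading frames per reference sequence: 1, 3 or 6 (default 6,
#'   so that reverse-strand reads are matched without translating them).
#' @param mem_mb Soft memory budget in MiB for the pair buffer.
#' @param table The [translation_table()] defining the encoding.
#' @param path If non-`NULL`, the index is also persisted here with
#'   [save_index()].
#' @return An object of class `aak_index`.
#' @export
build_index <- function(fasta_paths, content, k_max = 12L, frames = 6L,
                        mem_mb = 512, table = translation_table(),
                        path = NULL) {
  k_max <- check_k_max(k_max)
  if (!frames %in% c(1L, 3L, 6L)) abort("`frames` must be 1, 3 or 6")
  cap <- chunk_capacity(mem_mb, k_max)
  acc2line <- content_acc2line(content)

  chunks <- list()
  buf_keys <- character(0)
  buf_lines <- integer(0)
  for (p in fasta_paths) {
    seqs <- Biostrings::readDNAStringSet(p)
    accs <- parse_accession(names(seqs))
    lines <- acc2line[accs]
    if (anyNA(lines)) {
      abort(paste0("accession(s) not in content file: ",
                   paste(accs[is.na(lines)], collapse = ", "),
                   " (build the content file first)"))
    }
    for (i in seq_along(seqs)) {
      lets <- frames_of(as.character(seqs[[i]]), frames, table)
      for (fr in lets) {
        km <- kmers_of(fr, k_max, table = table, emit_padded = FALSE)
        if (nrow(km) == 0) next
        buf_keys <- c(buf_keys, km$key)
        buf_lines <- c(buf_lines, rep(unname(lines[i]), nrow(km)))
        if (length(buf_keys) >= cap) {
          chunks <- c(chunks, list(spill_chunk(buf_keys, buf_lines, k_max)))
          buf_keys <- character(0)
          buf_lines <- integer(0)
        }
      }
    }
  }
  if (length(buf_keys) > 0) {
    chunks <- c(chunks, list(spill_chunk(buf_keys, buf_lines, k_max)))
  }
  merged <- merge_chunks(chunks, k_max, cap)
  for (ch in chunks) unlink(ch$path)

  meta <- list(
    k_max = k_max,
    width_bits = if (k_max == 12L) 64L else 128L,
    frames = as.integer(frames),
    level = attr(content, "level") %||% "lowest",
    shrunken_lossless = FALSE,
    lossy_seed = NA_integer_,
    content_checksum = attr(content, "md5") %||% NA_character_
  )
  idx <- new_index(merged, content, table, meta)
  if (!is.null(path)) save_index(idx, path)
  idx
}

chunk_capacity <- function(mem_mb, k_max) {
  # documented accounting: ~(k_max + 60) bytes per buffered pair in R
  cap <- floor(mem_mb * 2^20 / (k_max + 60))
  if (cap < MIN_CHUNK_ENTRIES) {
    abort(paste0("memory budget below floor: need room for at least ",
                 MIN_CHUNK_ENTRIES, " pairs"))
  }
  as.integer(cap)
}

sort_dedup <- function(keys, lines) {
  o <- key_order(keys, lines)
  keys <- keys[o]
  lines <- lines[o]
  keep <- c(TRUE, keys[-1] != keys[-length(keys)] | lines[-1] != lines[-length(lines)])
  list(keys = keys[keep], lines = lines[keep])
}

# columnar sorted chunk: [int32 n][keys raw n*k_max][lines int32 n]
spill_chunk <- function(keys, lines, k_max) {
  sd <- sort_dedup(keys, lines)
  path <- tempfile("aak_chunk_")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(sd$keys)
  writeBin(n, con, size = 4L, endian = "little")
  writeBin(charToRaw(paste(sd$keys, collapse = "")), con)
  writeBin(sd$lines, con, size = 4L, endian = "little")
  list(path = path, n = n)
}

read_chunk_records <- function(chunk, from, n_read, k_max) {
  con <- file(chunk$path, "rb")
  on.exit(close(con))
  seek(con, 4 + (from - 1) * k_max)
  keys_raw <- readBin(con, "raw", n_read * k_max)
  seek(con, 4 + chunk$n * k_max + (from - 1) * 4)
  lines <- readBin(con, "integer", n_read, size = 4L, endian = "little")
  keys <- substring(rawToChar(keys_raw),
                    seq(1L, by = k_max, length.out = n_read),
                    seq(k_max, by = k_max, length.out = n_read))
  list(keys = keys, lines = lines)
}

# number of elements of `keys` strictly below `thr` in packed order
n_below <- function(keys, thr) {
  o <- order(c(thr, keys), method = "radix")
  which(o == 1L) - 1L
}

# k-way merge of sorted, deduplicated chunks with cross-chunk deduplication.
# Block merge: each round emits every loaded pair whose key is strictly below
# the smallest last-loaded key over chunks that still have unread data, so a
# key can never straddle two rounds and within-round sort + dedup is global.
merge_chunks <- function(chunks, k_max, cap) {
  empty <- tibble(key = character(), line = integer())
  if (length(chunks) == 0) return(empty)
  block <- max(MIN_CHUNK_ENTRIES, cap %/% max(1L, length(chunks)))
  st <- lapply(chunks, function(ch) {
    list(chunk = ch, pos = 1L, keys = character(0), lines = integer(0))
  })
  out_keys <- list()
  out_lines <- list()
  repeat {
    for (j in seq_along(st)) {
      s <- st[[j]]
      if (length(s$keys) == 0 && s$pos <= s$chunk$n) {
        nr <- min(block, s$chunk$n - s$pos + 1L)
        rec <- read_chunk_records(s$chunk, s$pos, nr, k_max)
        st[[j]]$keys <- rec$keys
        st[[j]]$lines <- rec$lines
        st[[j]]$pos <- s$pos + nr
      }
    }
    has_unread <- vapply(st, function(s) s$pos <= s$chunk$n, logical(1))
    if (!any(has_unread)) {
      keys <- unlist(lapply(st, `[[`, "keys"))
      lines <- unlist(lapply(st, `[[`, "lines"))
      if (length(keys) > 0) {
        sd <- sort_dedup(keys, lines)
        out_keys <- c(out_keys, list(sd$keys))
        out_lines <- c(out_lines, list(sd$lines))
      }
      break
    }
    last_loaded <- vapply(st[has_unread], function(s) s$keys[length(s$keys)],
                          character(1))
    thr <- last_loaded[key_order(last_loaded)[1]]
    emit_keys <- list()
    emit_lines <- list()
    for (j in seq_along(st)) {
      s <- st[[j]]
      if (length(s$keys) == 0) next
      nb <- n_below(s$keys, thr)
      if (nb > 0) {
        emit_keys <- c(emit_keys, list(s$keys[seq_len(nb)]))
        emit_lines <- c(emit_lines, list(s$lines[seq_len(nb)]))
        st[[j]]$keys <- s$keys[-seq_len(nb)]
        st[[j]]$lines <- s$lines[-seq_len(nb)]
      }
    }
    keys <- unlist(emit_keys)
    if (length(keys) > 0) {
      sd <- sort_dedup(keys, unlist(emit_lines))
      out_keys <- c(out_keys, list(sd$keys))
      out_lines <- c(out_lines, list(sd$lines))
    } else {
      # all loaded keys equal the threshold: force more data in
      for (j in seq_along(st)) {
        s <- st[[j]]
        if (s$pos <= s$chunk$n) {
          nr <- min(block, s$chunk$n - s$pos + 1L)
          rec <- read_chunk_records(s$chunk, s$pos, nr, k_max)
          st[[j]]$keys <- c(s$keys, rec$keys)
          st[[j]]$lines <- c(s$lines, rec$lines)
          st[[j]]$pos <- s$pos + nr
        }
      }
    }
  }
  tibble(key = unlist(out_keys) %||% character(0),
         line = unlist(out_lines) %||% integer(0))
}

# depth-6 prefix trie over sorted keys: each leaf maps a 6-letter prefix to
# the 0-based half-open range of index positions sharing it
build_trie <- function(keys) {
  if (length(keys) == 0) {
    return(list(prefix = character(0), lower = integer(0), upper = integer(0)))
  }
  pre <- substr(keys, 1L, TRIE_DEPTH)
  r <- rle(pre)
  upper <- cumsum(r$lengths)
  list(prefix = r$values,
       lower = as.integer(upper - r$lengths),
       upper = as.integer(upper))
}

#' Look up the index range sharing a k-mer's 6-letter prefix
#'
#' @param index An `aak_index` (or a bare trie from its `$trie` field).
#' @param kmer A `packed_kmer` with at least 6 valid letters, or its key
#'   string.
#' @return Integer vector `c(lower, upper)`: the 0-based half-open range of
#'   entry positions whose first six letters match; `c(0, 0)` when absent.
#' @export
trie_lookup <- function(index, kmer) {
  trie <- if (inherits(index, "aak_index")) index$trie else index
  if (inherits(kmer, "packed_kmer")) {
    if (kmer$valid_len < TRIE_DEPTH) {
      abort("trie lookup needs at least 6 valid letters")
    }
    kmer <- kmer$key
  }
  i <- match(substr(kmer, 1L, TRIE_DEPTH), trie$prefix)
  if (is.na(i)) c(lower = 0L, upper = 0L)
  else c(lower = trie$lower[i], upper = trie$upper[i])
}

#' Persist an index to disk
#'
#' Writes the flat fixed-width record file, the `.trie` sidecar and the
#' `.meta.json` sidecar (see the package vignette for the layout). A
#' lossless-shrunken index stores only the 6-letter suffix of each k-mer (the
#' prefix lives in the trie) plus a 16-bit content line number, halving every
#' record.
#'
#' @param index An `aak_index`.
#' @param path Output path for the record file.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  k_max <- index$meta$k_max
  shrunken <- isTRUE(index$meta$shrunken_lossless)
  n <- nrow(index$entries)
  con <- file(path, "wb")
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(c(INDEX_VERSION, k_max, index$meta$width_bits, index$meta$frames,
             as.integer(shrunken), n),
           con, size = 4L, endian = "little")
  if (n > 0) {
    if (shrunken) {
      suffix <- substr(index$entries$key, TRIE_DEPTH + 1L, k_max)
      key_raw <- matrix(charToRaw(paste(suffix, collapse = "")),
                        nrow = k_max - TRIE_DEPTH)
      line_raw <- rbind(as.raw(index$entries$line %% 256L),
                        as.raw(index$entries$line %/% 256L))
    } else {
      key_raw <- matrix(charToRaw(paste(index$entries$key, collapse = "")),
                        nrow = k_max)
      line_raw <- matrix(writeBin(index$entries$line, raw(), size = 4L,
                                  endian = "little"), nrow = 4L)
    }
    writeBin(as.vector(rbind(key_raw, line_raw)), con)
  }
  close(con)

  tcon <- file(paste0(path, ".trie"), "wb")
  writeBin(charToRaw(TRIE_MAGIC), tcon)
  writeBin(c(INDEX_VERSION, length(index$trie$prefix)), tcon,
           size = 4L, endian = "little")
  if (length(index$trie$prefix) > 0) {
    writeBin(charToRaw(paste(index$trie$prefix, collapse = "")), tcon)
    writeBin(index$trie$lower, tcon, size = 4L, endian = "little")
    writeBin(index$trie$upper, tcon, size = 4L, endian = "little")
  }
  close(tcon)

  meta <- index$meta
  meta$frequencies <- as.integer(index$freq)
  meta$table <- list(name = index$table$name,
                     codon_map = as.list(unclass(index$table$codon_map)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Load an index from disk
#'
#' The content file is re-bound by checksum: a lossless-shrunken index
#' refuses to load against a content file other than the one it was saved
#' with (the trie plus content line numbers are what make its records
#' recoverable); a mismatch on a full index only warns.
#'
#' @param path Path given to [save_index()].
#' @param content The matching `aak_content` object, or a path to the
#'   content file.
#' @return An `aak_index`.
#' @export
load_index <- function(path, content) {
  if (is.character(content)) content <- read_content(content)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, INDEX_MAGIC)) abort("not an index file")
  hdr <- readBin(con, "integer", 6L, size = 4L, endian = "little")
  version <- hdr[1]; k_max <- hdr[2]; width_bits <- hdr[3]
  frames <- hdr[4]; shrunken <- hdr[5] == 1L; n <- hdr[6]

  trie <- read_trie(paste0(path, ".trie"))
  meta_json <- jsonlite::read_json(paste0(path, ".meta.json"))
  table <- translation_table(
    setNames(unlist(meta_json$table$codon_map), names(meta_json$table$codon_map)),
    name = meta_json$table$name %||% "standard"
  )

  checksum <- meta_json$content_checksum
  checksum <- if (is.null(checksum)) NA_character_ else checksum
  content_md5 <- attr(content, "md5") %||% NA_character_
  if (shrunken) {
    if (is.na(checksum) || is.na(content_md5) || !identical(checksum, content_md5)) {
      abort("content file does not match this lossless-shrunken index (checksum mismatch)")
    }
  } else if (!is.na(checksum) && !is.na(content_md5) &&
             !identical(checksum, content_md5)) {
    warn("content file differs from the one the index was built with")
  }

  rb <- record_bytes(k_max, shrunken)
  if (n > 0) {
    payload <- matrix(readBin(con, "raw", n * rb), nrow = rb)
    if (shrunken) {
      suffixes <- substring(rawToChar(as.vector(payload[seq_len(k_max - TRIE_DEPTH), ,
                                                        drop = FALSE])),
                            seq(1L, by = k_max - TRIE_DEPTH, length.out = n),
                            seq(k_max - TRIE_DEPTH, by = k_max - TRIE_DEPTH,
                                length.out = n))
      lines <- as.integer(payload[k_max - TRIE_DEPTH + 1L, ]) +
        256L * as.integer(payload[k_max - TRIE_DEPTH + 2L, ])
      # recover each record's prefix from the trie leaf owning its position
      prefixes <- rep(trie$prefix, times = trie$upper - trie$lower)
      keys <- paste0(prefixes, suffixes)
    } else {
      keys <- substring(rawToChar(as.vector(payload[seq_len(k_max), , drop = FALSE])),
                        seq(1L, by = k_max, length.out = n),
                        seq(k_max, by = k_max, length.out = n))
      lines <- readBin(as.vector(payload[k_max + (1:4), , drop = FALSE]),
                       "integer", n, size = 4L, endian = "little")
    }
    entries <- tibble(key = keys, line = lines)
  } else {
    entries <- tibble(key = character(), line = integer())
  }

  meta <- list(
    k_max = k_max,
    width_bits = width_bits,
    frames = frames,
    level = meta_json$level %||% "lowest",
    shrunken_lossless = shrunken,
    lossy_seed = meta_json$lossy_seed %||% NA_integer_,
    content_checksum = checksum
  )
  idx <- new_index(entries, content, table, meta)
  idx$trie <- trie
  idx
}

read_trie <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, TRIE_MAGIC)) abort("not a trie file")
  hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n <- hdr[2]
  if (n == 0) {
    return(list(prefix = character(0), lower = integer(0), upper = integer(0)))
  }
  pre_raw <- readBin(con, "raw", n * TRIE_DEPTH)
  prefix <- substring(rawToChar(pre_raw),
                      seq(1L, by = TRIE_DEPTH, length.out = n),
                      seq(TRIE_DEPTH, by = TRIE_DEPTH, length.out = n))
  lower <- readBin(con, "integer", n, size = 4L, endian = "little")
  upper <- readBin(con, "integer", n, size = 4L, endian = "little")
  list(prefix = prefix, lower = lower, upper = upper)
}

#' Add new reference sequences to an existing index
#'
#' Builds sorted pairs from the new sequences only and merges them with the
#' existing entries (same deduplication rule as the build), then rebuilds the
#' trie and frequencies. The content file may only have gained appended
#' lines; existing line numbers must be unchanged. A lossless-shrunken index
#' is static and cannot be updated.
#'
#' @param index An `aak_index`.
#' @param fasta_paths FASTA files with the new sequences (may be empty).
#' @param content The updated content registry (old entries first, new
#'   entries appended).
#' @param mem_mb Soft memory budget in MiB.
#' @return The updated `aak_index`.
#' @export
update_index <- function(index, fasta_paths, content, mem_mb = 512) {
  if (isTRUE(index$meta$shrunken_lossless)) {
    abort("index is static: a lossless-shrunken index cannot be updated")
  }
  old <- index$content
  if (nrow(content) < nrow(old) ||
      !identical(old$tax_id, content$tax_id[seq_len(nrow(old))])) {
    abort("content entries may only be appended; existing line numbers must not change")
  }
  k_max <- index$meta$k_max
  cap <- chunk_capacity(mem_mb, k_max)
  acc2line <- content_acc2line(content)
  keys <- list(); lines <- list()
  for (p in fasta_paths) {
    seqs <- Biostrings::readDNAStringSet(p)
    accs <- parse_accession(names(seqs))
    ln <- acc2line[accs]
    if (anyNA(ln)) {
      abort(paste0("accession(s) not in content file: ",
                   paste(accs[is.na(ln)], collapse = ", ")))
    }
    for (i in seq_along(seqs)) {
      lets <- frames_of(as.character(seqs[[i]]), index$meta$frames, index$table)
      for (fr in lets) {
        km <- kmers_of(fr, k_max, table = index$table, emit_padded = FALSE)
        if (nrow(km) > 0) {
          keys <- c(keys, list(km$key))
          lines <- c(lines, list(rep(unname(ln[i]), nrow(km))))
        }
      }
    }
  }
  all_keys <- c(index$entries$key, unlist(keys) %||% character(0))
  all_lines <- c(index$entries$line, unlist(lines) %||% integer(0))
  sd <- sort_dedup(all_keys, all_lines)
  meta <- index$meta
  meta$content_checksum <- attr(content, "md5") %||% NA_character_
  new_index(tibble(key = sd$keys, line = sd$lines), content, index$table, meta)
}

#' Shrink an index losslessly to half its record width
#'
#' Marks the index so that [save_index()] stores, per entry, only the low
#' 30-bit suffix (letters 7..12) — the 6-letter prefix is recoverable from
#' the trie leaf owning the entry's position — and a 16-bit content line
#' number instead of the taxon ID. Requires a 64-bit (`k_max = 12`) index
#' and a content file with at most 65535 entries; the result is static
#' (no updates) and identification must use `k_lower >= 7`. Identification
#' output is unchanged.
#'
#' @param index An `aak_index`.
#' @return The shrunken `aak_index`.
#' @export
shrink_lossless <- function(index) {
  if (isTRUE(index$meta$shrunken_lossless)) return(index)
  if (index$meta$k_max != 12L) {
    abort("lossless shrink requires a 64-bit index (k_max = 12)")
  }
  if (nrow(index$content) > LOSSLESS_MAX_LINES) {
    abort(paste0("lossless shrink requires at most ", LOSSLESS_MAX_LINES,
                 " content entries"))
  }
  index$meta$shrunken_lossless <- TRUE
  index
}

#' Shrink an index by deleting k-mers per taxon
#'
#' Deletes `round(percent * n_t / 100)` entries per taxon `t`, uniformly at
#' random with a recorded seed, so taxa with more k-mers lose more in
#' absolute terms. A taxon with a single entry keeps it unless
#' `percent = 100`. Alternatively a target size in GB is converted to the
#' percentage between the current and target size. The trie and frequencies
#' are rebuilt.
#'
#' @param index An `aak_index`.
#' @param percent Percentage of each taxon's entries to delete, in (0, 100].
#' @param target_gb Desired on-disk size in GB (alternative to `percent`).
#' @param seed Integer seed recorded in the index metadata.
#' @return The shrunken `aak_index`.
#' @export
shrink_lossy <- function(index, percent = NULL, target_gb = NULL, seed = 1L) {
  n <- nrow(index$entries)
  rb <- record_bytes(index$meta$k_max, isTRUE(index$meta$shrunken_lossless))
  if (is.null(percent)) {
    if (is.null(target_gb)) abort("supply `percent` or `target_gb`")
    current <- n * rb
    target <- target_gb * 2^30
    if (target >= current) {
      warn("target size is not below the current size; index left unchanged")
      return(index)
    }
    percent <- (1 - target / current) * 100
  }
  if (percent < 0 || percent > 100) abort("`percent` must be in [0, 100]")
  if (percent == 0) return(index)
  del <- integer(0)
  with_seed(seed, {
    for (t in which(index$freq > 0)) {
      rows <- which(index$entries$line == t)
      n_t <- length(rows)
      n_del <- floor(percent * n_t / 100 + 0.5)  # round half up
      if (n_t == 1L && percent < 100) n_del <- 0L
      n_del <- min(n_del, n_t)
      if (n_del > 0) del <- c(del, sample(rows, n_del))
    }
  })
  entries <- if (length(del) > 0) index$entries[-del, ] else index$entries
  meta <- index$meta
  meta$lossy_seed <- as.integer(seed)
  new_index(entries, index$content, index$table, meta)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' @export
print.aak_index <- function(x, ...) {
  cat("<aak_index> ", nrow(x$entries), " entries | k_max=", x$meta$k_max,
      " (", x$meta$width_bits, "-bit) | frames=", x$meta$frames,
      " | level=", x$meta$level,
      if (isTRUE(x$meta$shrunken_lossless)) " | lossless-shrunken" else "",
      "\n", sep = "")
  cat("  ", nrow(x$content), " taxa | ", length(x$trie$prefix),
      " trie leaves (depth ", TRIE_DEPTH, ")\n", sep = "")
  invisible(x)
}

#' Per-taxon k-mer frequencies of an index
#'
#' @param x An `aak_index`.
#' @param ... Unused.
#' @return A tibble with one row per content entry: `line`, `tax_id`,
#'   `name`, `n_kmers` (the taxon's frequency: its total entry count).
#' @export
#' @exportS3Method generics::tidy
tidy.aak_index <- function(x, ...) {
  tibble(line = x$content$line,
         tax_id = x$content$tax_id,
         name = x$content$name,
         n_kmers = as.integer(x$freq))
}

#' One-row summary of an index
#'
#' @param x An `aak_index`.
#' @param ... Unused.
#' @return A one-row tibble with entry/taxon counts, the k-mer geometry and
#'   the ambiguity value (share of entries whose k-mer is also carried by
#'   another taxon).
#' @export
#' @exportS3Method generics::glance
glance.aak_index <- function(x, ...) {
  tibble(
    n_entries = nrow(x$entries),
    n_taxa = nrow(x$content),
    k_max = x$meta$k_max,
    width_bits = x$meta$width_bits,
    frames = x$meta$frames,
    level = x$meta$level,
    shrunken_lossless = isTRUE(x$meta$shrunken_lossless),
    ambiguity = ambiguity_value(x)
  )
}
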