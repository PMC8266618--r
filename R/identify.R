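# Read identification: reads -> sorted (k-mer, read) pairs -> variable-k
# matching against the index -> k-mer Score and Relative Score per
# (read, taxon).

#' Quadratic k-mer weights
#'
#' Weights are `k^2 / 625`, the values of `k^2` normalized to (0, 1] for
#' k = 1, ..., 25, so `w(25) = 1`. The same normalization is used for 64-bit
#' (`k_max = 12`) indices.
#'
#' @param k Integer vector of word lengths.
#' @return Numeric weights in (0, 1].
#' @export
kmer_weights <- function(k) {
  k^2 / 625
}

#' Read sequences from a FASTA or FASTQ file
#'
#' The format is taken from the file extension unless given; FASTQ quality
#' strings are ignored.
#'
#' @param path Input file.
#' @param format `"fasta"`, `"fastq"` or `NULL` (auto-detect).
#' @return A tibble with columns `read_id` (first header token) and `seq`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1L)
  tibble(read_id = ids, seq = as.character(x))
}

# all k-mer windows of one translated frame of many reads, in one pass:
# full-length windows for frames of >= k_max letters, a single sentinel-padded
# window for frames in [k_lower, k_max)
batch_windows <- function(lets, read_ids, k_max, k_lower, table) {
  keystr <- encode_letters(lets, table)
  len <- nchar(keystr)
  out <- list()
  full <- which(len >= k_max)
  if (length(full) > 0) {
    n_win <- len[full] - k_max + 1L
    starts <- sequence(n_win)
    out[[1]] <- tibble(
      key = substring(rep(keystr[full], n_win), starts, starts + k_max - 1L),
      valid_len = k_max,
      read_id = rep(read_ids[full], n_win)
    )
  }
  padded <- which(len < k_max & len >= k_lower)
  if (length(padded) > 0) {
    out[[2]] <- tibble(
      key = paste0(keystr[padded],
                   strrep(KMER_SENTINEL_CHAR, k_max - len[padded])),
      valid_len = len[padded],
      read_id = read_ids[padded]
    )
  }
  bind_rows(out)
}

as_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      is.null(names(reads))) {
    reads <- read_sequences(reads)
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% paste0("read_", seq_along(reads))
    reads <- tibble(read_id = ids, seq = unname(reads))
  }
  reads <- as_tibble(reads)
  if (!all(c("read_id", "seq") %in% names(reads))) {
    abort("reads must have `read_id` and `seq` columns")
  }
  if (anyDuplicated(reads$read_id)) abort("read_ids must be unique")
  reads
}

#' Convert reads into sorted (k-mer, read) pairs
#'
#' Each read is translated in `frames` reading frames (3 by default: the
#' forward frames — reverse-strand hits are already covered by a six-frame
#' index) and every frame contributes its full-length k-mer windows, plus a
#' single sentinel-padded window when a whole translated frame is shorter
#' than `k_max` but at least `k_lower` letters, so short reads remain
#' classifiable. Duplicate k-mers are kept: every occurrence counts. The
#' pair list is sorted by packed k-mer value, then read.
#'
#' @param reads A tibble with `read_id` and `seq` columns, a named character
#'   vector, or a FASTA/FASTQ path.
#' @param k_max Letters per k-mer of the target index (12 or 25).
#' @param k_lower Smallest k that will be queried (default 7).
#' @param frames 1, 3 or 6 (6 additionally translates the reverse
#'   complement of each read).
#' @param table The index's [translation_table()].
#' @param is_protein Reads are already letter strings; translation and
#'   frames are skipped.
#' @return A tibble of class `aak_pairs` with columns `key`, `valid_len`,
#'   `read_id`, carrying a `read_info` attribute (per-read lengths; reads
#'   too short to yield any pair are counted as unclassified).
#' @export
reads_to_pairs <- function(reads, k_max = 12L, k_lower = 7L, frames = 3L,
                           table = translation_table(), is_protein = FALSE) {
  k_max <- check_k_max(k_max)
  if (!frames %in% c(1L, 3L, 6L)) abort("`frames` must be 1, 3 or 6")
  reads <- as_reads(reads)
  # translate all reads per frame at once; loops over frames, not reads
  frame_lets <- if (is_protein) {
    list(reads$seq)
  } else {
    fwd <- lapply(0:2, function(f) translate_frame(reads$seq, f, table))
    if (frames == 1L) {
      fwd[1]
    } else if (frames == 3L) {
      fwd
    } else {
      rc <- reverse_complement(reads$seq)
      c(fwd, lapply(0:2, function(f) translate_frame(rc, f, table)))
    }
  }
  pieces <- lapply(frame_lets, function(lets) {
    batch_windows(lets, reads$read_id, k_max, k_lower, table)
  })
  pairs <- bind_rows(pieces)
  if (nrow(pairs) == 0) {
    pairs <- tibble(key = character(), valid_len = integer(),
                    read_id = character())
  }
  pairs <- pairs[key_order(pairs$key, pairs$read_id), ]
  read_info <- tibble(read_id = reads$read_id,
                      read_len = nchar(reads$seq),
                      n_pairs = tabulate(match(pairs$read_id, reads$read_id),
                                         nbins = nrow(reads)))
  if (any(read_info$n_pairs == 0)) {
    inform(paste0(sum(read_info$n_pairs == 0),
                  " read(s) too short to yield k-mers; counted as unclassified"))
  }
  structure(pairs, class = c("aak_pairs", class(pairs)),
            read_info = read_info, k_max = k_max, k_lower = k_lower,
            frames = as.integer(frames))
}

#' Match read k-mer pairs against an index over a range of k
#'
#' For every k from `k_lower` to `k_upper`, an input k-mer occurrence
#' matches taxon `t` when its k-letter prefix equals the k-letter prefix of
#' one of `t`'s index entries; a maximal match of length `m` therefore
#' contributes a match at every k in `[k_lower, m]`. The 6-letter prefix
#' trie restricts the candidate range first (which is why a
#' lossless-shrunken index requires `k_lower >= 7`). Padded input k-mers can
#' only match up to their valid length.
#'
#' @param pairs An `aak_pairs` object from [reads_to_pairs()].
#' @param index An `aak_index`.
#' @param k_lower,k_upper The k range; `k_upper` defaults to the index
#'   `k_max`.
#' @return An object of class `aak_matches`: per-(k, read, prefix, taxon)
#'   hit table with occurrence counts and per-prefix matched-taxa counts,
#'   plus per-k input occurrence totals.
#' @export
match_pairs <- function(pairs, index, k_lower = 7L, k_upper = NULL) {
  k_max <- index$meta$k_max
  k_upper <- as.integer(k_upper %||% k_max)
  k_lower <- as.integer(k_lower)
  if (k_lower < 1L || k_lower > k_upper) {
    abort("need 1 <= k_lower <= k_upper")
  }
  if (k_upper > k_max) abort("`k_upper` cannot exceed the index k_max")
  if (isTRUE(index$meta$shrunken_lossless) && k_lower < 7L) {
    abort("a lossless-shrunken index requires k_lower >= 7 (the trie must resolve the prefix)")
  }
  ks <- k_lower:k_upper
  input_totals <- tibble(
    k = ks,
    n_input = vapply(ks, function(k) sum(pairs$valid_len >= k), integer(1))
  )

  # trie range reduction: pairs whose 6-letter prefix is absent can never
  # match at any k >= 6
  q <- tibble(key = pairs$key, valid_len = pairs$valid_len,
              read_id = pairs$read_id)
  if (k_lower >= TRIE_DEPTH && nrow(q) > 0) {
    q <- q[!is.na(match(substr(q$key, 1L, TRIE_DEPTH), index$trie$prefix)), ]
  }

  hits <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    qk <- q[q$valid_len >= k, ]
    if (nrow(qk) == 0) next
    idx_k <- distinct(tibble(prefix = substr(index$entries$key, 1L, k),
                             line = index$entries$line))
    taxa_per_prefix <- count(idx_k, .data$prefix, name = "n_taxa")
    occ <- count(tibble(read_id = qk$read_id,
                        prefix = substr(qk$key, 1L, k)),
                 .data$read_id, .data$prefix, name = "occ")
    # many-to-many by design: several reads and several taxa share a prefix
    m <- inner_join(occ, idx_k, by = "prefix", relationship = "many-to-many")
    if (nrow(m) == 0) next
    m <- inner_join(m, taxa_per_prefix, by = "prefix")
    m$k <- k
    hits[[j]] <- m
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    hits <- tibble(read_id = character(), prefix = character(),
                   occ = integer(), line = integer(), n_taxa = integer(),
                   k = integer())
  }
  structure(
    list(hits = as_tibble(hits), input_totals = input_totals,
         k_lower = k_lower, k_upper = k_upper,
         read_info = attr(pairs, "read_info")),
    class = "aak_matches"
  )
}

#' @export
print.aak_matches <- function(x, ...) {
  cat("<aak_matches> k in [", x$k_lower, ", ", x$k_upper, "] | ",
      nrow(x$hits), " hit rows | ",
      dplyr::n_distinct(x$hits$read_id), " matched reads\n", sep = "")
  invisible(x)
}

# per-(read, taxon, k) match counts: number of input k-mer occurrences of the
# read whose k-prefix matches an index entry of the taxon
match_counts <- function(matches) {
  if (nrow(matches$hits) == 0) {
    return(tibble(read_id = character(), line = integer(), k = integer(),
                  n = integer()))
  }
  matches$hits |>
    group_by(.data$read_id, .data$line, .data$k) |>
    summarise(n = sum(.data$occ), .groups = "drop")
}

#' k-mer Scores for every matched (read, taxon) pair
#'
#' The score of taxon `t` and read `r` is the weighted sum, over the read's
#' k-mer occurrences `x` and over k in the match range, of
#' `w(k) / |T(x, k)|` for every occurrence that matches `t` at length k,
#' where `T(x, k)` is the set of taxa matched by that k-mer at that k (so an
#' occurrence shared between several taxa is split between them).
#'
#' @param matches An `aak_matches` object.
#' @return A tibble `read_id`, `line`, `kmer_score`.
#' @export
kmer_scores <- function(matches) {
  if (nrow(matches$hits) == 0) {
    return(tibble(read_id = character(), line = integer(),
                  kmer_score = double()))
  }
  matches$hits |>
    mutate(contrib = kmer_weights(.data$k) * .data$occ / .data$n_taxa) |>
    group_by(.data$read_id, .data$line) |>
    summarise(kmer_score = sum(.data$contrib), .groups = "drop")
}

#' Relative Score of a (read, taxon) pair
#'
#' Puts the k-mer Score in relation to the read length and the taxon's index
#' frequency (its total k-mer count in the index):
#' `kmer_score / (1 + log2(read_len_nt * frequency))`. Higher is better.
#'
#' @param kmer_score Numeric k-mer Scores.
#' @param read_len_nt Read length in nucleotides (>= 1).
#' @param frequency Taxon frequency in the index (>= 1).
#' @return Numeric Relative Scores.
#' @export
relative_score <- function(kmer_score, read_len_nt, frequency) {
  if (any(read_len_nt < 1) || any(frequency < 1)) {
    abort("`read_len_nt` and `frequency` must be >= 1")
  }
  kmer_score / (1 + log2(read_len_nt * frequency))
}

#' Identify reads against an index
#'
#' Runs [reads_to_pairs()], [match_pairs()] and the two scores, returning
#' per-read taxon calls ranked by Relative Score (ties broken by ascending
#' tax_id).
#'
#' @param index An `aak_index`.
#' @param reads Reads as accepted by [reads_to_pairs()].
#' @param k Integer vector `c(k_lower, k_upper)`; `NA` upper means the index
#'   `k_max`. Default `c(7, k_max)`.
#' @param frames Reading frames for the reads (default 3).
#' @param is_protein Reads are already amino-acid-like letter strings.
#' @return An object of class `aak_identification` with fields `results`
#'   (tibble: `read_id`, `tax_id`, `name`, `relative_score`, `kmer_score`),
#'   `matches`, `read_info` and `params`.
#' @export
identify_reads <- function(index, reads, k = c(7L, NA), frames = 3L,
                           is_protein = FALSE) {
  k_lower <- as.integer(k[1])
  k_upper <- if (length(k) < 2L || is.na(k[2])) index$meta$k_max else as.integer(k[2])
  pairs <- reads_to_pairs(reads, k_max = index$meta$k_max, k_lower = k_lower,
                          frames = frames, table = index$table,
                          is_protein = is_protein)
  matches <- match_pairs(pairs, index, k_lower = k_lower, k_upper = k_upper)
  scores <- kmer_scores(matches)
  read_info <- matches$read_info
  results <- scores |>
    left_join(read_info[, c("read_id", "read_len")], by = "read_id") |>
    mutate(tax_id = index$content$tax_id[.data$line],
           name = index$content$name[.data$line],
           relative_score = relative_score(.data$kmer_score, .data$read_len,
                                           index$freq[.data$line]))
  # rank within read: Relative Score descending, ties by ascending tax_id
  results <- results[order(match(results$read_id, read_info$read_id),
                           -results$relative_score, results$tax_id), ]
  results <- results[, c("read_id", "tax_id", "name", "relative_score",
                         "kmer_score")]
  structure(
    list(results = as_tibble(results), matches = matches,
         read_info = read_info,
         params = list(k_lower = k_lower, k_upper = k_upper,
                       frames = as.integer(frames))),
    class = "aak_identification"
  )
}

#' @export
print.aak_identification <- function(x, ...) {
  n_reads <- nrow(x$read_info)
  n_cls <- dplyr::n_distinct(x$results$read_id)
  cat("<aak_identification> ", n_reads, " reads, ", n_cls, " classified (k in [",
      x$params$k_lower, ", ", x$params$k_upper, "], ", x$params$frames,
      " frame(s))\n", sep = "")
  invisible(x)
}

#' @describeIn identify_reads Tidy accessor: the per-read results tibble.
#' @param x An `aak_identification`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.aak_identification <- function(x, ...) {
  x$results
}

#' @describeIn identify_reads One-row run summary (read counts, k range).
#' @export
#' @exportS3Method generics::glance
glance.aak_identification <- function(x, ...) {
  tibble(n_reads = nrow(x$read_info),
         n_classified = dplyr::n_distinct(x$results$read_id),
         n_unclassified = nrow(x$read_info) -
           dplyr::n_distinct(x$results$read_id),
         k_lower = x$params$k_lower,
         k_upper = x$params$k_upper,
         frames = x$params$frames)
}

#' Top-ranked taxon call per read
#'
#' @param ident An `aak_identification`.
#' @return A tibble `read_id`, `tax_id` (NA for unclassified reads).
#' @export
top_calls <- function(ident) {
  top <- ident$results |>
    group_by(.data$read_id) |>
    slice(1L) |>
    ungroup() |>
    select("read_id", "tax_id")
  ident$read_info |>
    select("read_id") |>
    left_join(top, by = "read_id")
}

#' Write identification results to a file
#'
#' One record per read listing its matched taxa in decreasing Relative Score
#' order; reads with no match are emitted with an empty taxon list. The
#' optional significance filter drops taxa whose Relative Score falls below
#' the cutoff (0.4 is the conventional threshold for reads of length 100);
#' it is never applied unless requested.
#'
#' @param ident An `aak_identification`.
#' @param path Output file.
#' @param format `"tsv"` (columns `read_id`, `tax_id`, `name`,
#'   `relative_score`, `kmer_score`) or `"json"`.
#' @param filter `NULL` (off) or a Relative Score cutoff.
#' @return `path`, invisibly.
#' @export
write_identification <- function(ident, path, format = c("tsv", "json"),
                                 filter = NULL) {
  format <- match.arg(format)
  res <- ident$results
  if (!is.null(filter)) res <- res[res$relative_score >= filter, ]
  all_reads <- ident$read_info$read_id
  if (format == "tsv") {
    matched <- unique(res$read_id)
    unmatched <- setdiff(all_reads, matched)
    body <- res |>
      mutate(relative_score = formatC(.data$relative_score, digits = 6,
                                      format = "f"),
             kmer_score = formatC(.data$kmer_score, digits = 6, format = "f"))
    lines_m <- paste(body$read_id, body$tax_id, body$name,
                     body$relative_score, body$kmer_score, sep = "\t")
    lines_u <- if (length(unmatched) > 0) paste0(unmatched, "\t\t\t\t") else character(0)
    header <- "read_id\ttax_id\tname\trelative_score\tkmer_score"
    ord <- c(lines_m, lines_u)
    # keep the input read order
    ids <- c(body$read_id, unmatched)
    writeLines(c(header, ord[order(match(ids, all_reads))]), path,
               useBytes = TRUE)
  } else {
    recs <- lapply(all_reads, function(r) {
      rows <- res[res$read_id == r, ]
      list(read_id = r,
           taxa = lapply(seq_len(nrow(rows)), function(i) {
             list(tax_id = rows$tax_id[i], name = rows$name[i],
                  relative_score = rows$relative_score[i],
                  kmer_score = rows$kmer_score[i])
           }))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
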