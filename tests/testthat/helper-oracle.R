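# Brute-force matching oracle. Works entirely on plain letter strings:
# reference k-prefix sets are enumerated directly from the translated frames
# (prefixes of full-length windows only, mirroring an index that stores only
# maximum-length k-mers), and read occurrences are compared by substring
# membership. Shares no code with the packed index, trie or join machinery.

oracle_ref_sets <- function(ref, table, k_max, ks, frames = 6) {
  sets <- list()
  for (i in seq_len(nrow(ref))) {
    for (lets in frames_of(ref$seq[i], frames, table)) {
      L <- nchar(lets)
      if (L < k_max) next
      starts <- seq_len(L - k_max + 1L)
      for (k in ks) {
        id <- paste(k, ref$line[i])
        sets[[id]] <- union(sets[[id]] %||% character(0),
                            substring(lets, starts, starts + k - 1L))
      }
    }
  }
  sets
}

# per-(read, taxon line, k) match counts, counting every input occurrence
oracle_match_counts <- function(ref, reads, table, k_max, k_lower, k_upper,
                                index_frames = 6, read_frames = 3) {
  ks <- k_lower:k_upper
  sets <- oracle_ref_sets(ref, table, k_max, ks, index_frames)
  occ <- list()
  for (i in seq_len(nrow(reads))) {
    for (lets in frames_of(reads$seq[i], read_frames, table)) {
      L <- nchar(lets)
      if (L >= k_max) {
        starts <- seq_len(L - k_max + 1L)
        occ[[length(occ) + 1L]] <- tibble::tibble(
          read_id = reads$read_id[i],
          word = substring(lets, starts, starts + k_max - 1L),
          vlen = k_max
        )
      } else if (L >= k_lower) {
        occ[[length(occ) + 1L]] <- tibble::tibble(
          read_id = reads$read_id[i], word = lets, vlen = L
        )
      }
    }
  }
  occ <- dplyr::bind_rows(occ)
  res <- list()
  for (k in ks) {
    ok <- occ[occ$vlen >= k, ]
    if (nrow(ok) == 0) next
    pre <- substr(ok$word, 1L, k)
    for (ln in unique(ref$line)) {
      set <- sets[[paste(k, ln)]]
      if (is.null(set)) next
      sel <- pre %in% set
      if (any(sel)) {
        tb <- table(ok$read_id[sel])
        res[[length(res) + 1L]] <- tibble::tibble(
          read_id = names(tb), line = as.integer(ln), k = as.integer(k),
          n = as.integer(tb)
        )
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(read_id = character(), line = integer(),
                          k = integer(), n = integer())
  }
  dplyr::arrange(out, read_id, line, k)
}

# the implementation's counts in the oracle's shape
impl_match_counts <- function(matches) {
  dplyr::arrange(aakmer:::match_counts(matches),
                 read_id, line, k) |>
    dplyr::mutate(n = as.integer(n))
}
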