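# Amino-acid-like encoding of DNA: triplet translation over reading frames and
# packing of fixed-length k-mers into order-preserving 5-bit-per-letter words.
#
# A packed k-mer is realized as a fixed-width byte string with one byte per
# letter: byte value 0x40 + code, where codes 1..31 are assigned to letters in
# ascending lexicographic order and code 0 is the padding sentinel ('@').
# Byte-wise (radix) order of these strings is exactly the integer order of the
# conceptual 5-bit packed word, and prefix extraction is substr().

KMER_SENTINEL_CHAR <- "@"
TRIE_DEPTH <- 6L

#' Number of payload bits in a packed k-mer
#'
#' Each letter occupies five bits, so a full-length k-mer of `k_max` letters
#' consumes `5 * k_max` bits (60 for `k_max = 12`, 125 for `k_max = 25`).
#'
#' @param k_max Letters per k-mer (12 or 25).
#' @return Integer number of bits.
#' @export
payload_bits <- function(k_max) {
  check_k_max(k_max)
  5L * as.integer(k_max)
}

check_k_max <- function(k_max) {
  if (!k_max %in% c(12L, 25L)) {
    abort("`k_max` must be 12 (64-bit words) or 25 (128-bit words)")
  }
  invisible(as.integer(k_max))
}

#' Build a translation table for the amino-acid-like encoding
#'
#' The table maps every ACGT triplet to one letter of an alphabet of at most
#' 31 letters, and assigns each letter a 5-bit code in `[1, 31]` in ascending
#' lexicographic order (so code order equals letter order). Code 0 is reserved
#' for the padding sentinel. The default is the standard genetic code
#' ([Biostrings::GENETIC_CODE]) extended with a dedicated ambiguity letter
#' `"X"` (any codon containing a non-ACGT base) and the stop letter `"*"`;
#' translation continues through stop codons because non-coding sequence is
#' encoded as well.
#'
#' @param codon_map Named character vector of length 64 mapping codons (names)
#'   to single letters. Defaults to the standard genetic code.
#' @param name Identifier for the table.
#' @return An object of class `aak_table`.
#' @export
translation_table <- function(codon_map = NULL, name = "standard") {
  gc_skeleton <- Biostrings::GENETIC_CODE
  if (is.null(codon_map)) {
    codon_map <- gc_skeleton
  } else {
    if (is.null(names(codon_map)) || length(codon_map) != 64L) {
      abort("`codon_map` must be a named character vector of 64 codons")
    }
    names(codon_map) <- toupper(names(codon_map))
    if (!setequal(names(codon_map), names(gc_skeleton))) {
      abort("`codon_map` must cover exactly the 64 ACGT triplets")
    }
    if (any(nchar(codon_map) != 1L)) {
      abort("every codon must map to a single letter")
    }
    # keep Biostrings codon order and attributes so translate() accepts it
    tmp <- gc_skeleton
    tmp[names(codon_map)] <- unname(codon_map)
    codon_map <- tmp
  }
  attr(codon_map, "alt_init_codons") <- character(0)

  letters <- sort(unique(c(unname(codon_map), "X")), method = "radix")
  if (length(letters) > 31L) {
    abort("alphabet too large: at most 31 letters fit in 5 bits")
  }
  bad <- setdiff(letters, Biostrings::AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("letters outside the amino-acid alphabet: ",
                 paste(bad, collapse = ", ")))
  }
  codes <- seq_along(letters)
  code_chars <- vapply(codes, function(i) rawToChar(as.raw(0x40L + i)), character(1))

  structure(
    list(
      codon_map = codon_map,
      letters = letters,
      letter_codes = setNames(as.integer(codes), letters),
      code_chars = code_chars,
      chartr_from = paste(letters, collapse = ""),
      chartr_to = paste(code_chars, collapse = ""),
      name = name
    ),
    class = "aak_table"
  )
}

#' Read a custom translation table from a TSV file
#'
#' Expects 64 rows `codon<TAB>letter` (no header).
#'
#' @param path Path to the TSV file.
#' @param name Identifier for the table; defaults to the file name.
#' @return An object of class `aak_table`.
#' @export
read_translation_table <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) abort("translation table TSV must have two columns")
  translation_table(setNames(df[[2]], df[[1]]), name = name)
}

#' @export
print.aak_table <- function(x, ...) {
  cat("<aak_table> ", x$name, ": ", length(x$letters),
      " letters (5-bit codes 1..", length(x$letters), ")\n", sep = "")
  invisible(x)
}

#' Reverse complement of a nucleotide sequence
#'
#' A maps to T, C to G (and vice versa); every other letter, including IUPAC
#' ambiguity codes such as N, maps to itself and is only reversed in place.
#' Ambiguity is resolved at translation time, not at complementation.
#'
#' @param seq Character vector of nucleotide sequences (case-insensitive).
#' @return Character vector of reverse complements, lengths preserved.
#' @export
reverse_complement <- function(seq) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", seq))
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Drops the first `frame` bases, groups the remainder into non-overlapping
#' triplets (discarding any trailing 1-2 bases) and maps each triplet through
#' the table. Codons containing a non-ACGT base become the ambiguity letter
#' `"X"`; stop codons become `"*"` and translation continues through them.
#' Lowercase input is uppercased first.
#'
#' @param seq Character vector of nucleotide sequences.
#' @param frame Integer offset 0, 1 or 2.
#' @param table An [translation_table()] object.
#' @return Character vector of letter strings.
#' @export
translate_frame <- function(seq, frame = 0L, table = translation_table()) {
  if (!frame %in% 0:2) abort("`frame` must be 0, 1 or 2")
  seq <- toupper(seq)
  w <- nchar(seq)
  ncod <- pmax((w - frame) %/% 3L, 0L)
  out <- character(length(seq))
  has <- ncod > 0L
  if (any(has)) {
    x <- Biostrings::DNAStringSet(substr(seq[has], frame + 1L, frame + 3L * ncod[has]))
    aa <- Biostrings::translate(x, genetic.code = table$codon_map,
                                no.init.codon = TRUE, if.fuzzy.codon = "X")
    out[has] <- as.character(aa)
  }
  out
}

#' Translate a sequence in one, three or six reading frames
#'
#' One frame: frame 0 only. Three frames: frames 0, 1, 2 of the forward
#' strand. Six frames: the three forward frames followed by frames 0, 1, 2 of
#' the reverse complement, in that fixed order.
#'
#' @param seq A single nucleotide sequence.
#' @param n_frames 1, 3 or 6.
#' @param table An [translation_table()] object.
#' @return Character vector of `n_frames` letter strings.
#' @export
frames_of <- function(seq, n_frames = 6L, table = translation_table()) {
  if (!n_frames %in% c(1L, 3L, 6L)) abort("`n_frames` must be 1, 3 or 6")
  fwd <- vapply(0:2, function(f) translate_frame(seq, f, table), character(length(seq)))
  if (length(seq) == 1L) fwd <- matrix(fwd, nrow = 1L)
  if (n_frames == 1L) return(fwd[1, 1])
  if (n_frames == 3L) return(fwd[1, ])
  rc <- reverse_complement(seq)
  rev3 <- vapply(0:2, function(f) translate_frame(rc, f, table), character(length(seq)))
  if (length(seq) == 1L) rev3 <- matrix(rev3, nrow = 1L)
  c(fwd[1, ], rev3[1, ])
}

# letter string -> sortable code-byte key (vectorized)
encode_letters <- function(letters, table) {
  chartr(table$chartr_from, table$chartr_to, letters)
}

decode_key <- function(key, table) {
  chartr(table$chartr_to, table$chartr_from, gsub(KMER_SENTINEL_CHAR, "", key, fixed = TRUE))
}

#' Pack a letter string into a fixed-width k-mer word
#'
#' Letters are placed most-significant-first; unused trailing positions hold
#' the sentinel code 0, which sorts before every letter so padded k-mers sort
#' adjacent to their extensions. For full-length k-mers, comparing packed
#' values is identical to comparing letter strings lexicographically.
#'
#' @param letters Letter string of length at most `k_max`.
#' @param k_max Letters per k-mer (12 or 25).
#' @param table An [translation_table()] object.
#' @return An object of class `packed_kmer` with fields `key` (the packed
#'   word as a sortable fixed-width byte string), `k_max` and `valid_len`.
#' @export
pack_kmer <- function(letters, k_max = 12L, table = translation_table()) {
  k_max <- check_k_max(k_max)
  len <- nchar(letters)
  if (len > k_max) abort("kmer overflow: more letters than `k_max`")
  unknown <- setdiff(strsplit(letters, "")[[1]], table$letters)
  if (length(unknown) > 0) {
    abort(paste0("letters not in alphabet: ", paste(unknown, collapse = ", ")))
  }
  key <- paste0(encode_letters(letters, table),
                strrep(KMER_SENTINEL_CHAR, k_max - len))
  structure(list(key = key, k_max = as.integer(k_max), valid_len = len),
            class = "packed_kmer")
}

#' Unpack a k-mer word back into its letter string
#'
#' @param x A `packed_kmer` from [pack_kmer()].
#' @param table The [translation_table()] used to pack it.
#' @return The letter string (sentinel padding removed).
#' @export
unpack_kmer <- function(x, table = translation_table()) {
  stopifnot(inherits(x, "packed_kmer"))
  decode_key(x$key, table)
}

#' @export
print.packed_kmer <- function(x, ...) {
  cat("<packed_kmer> k_max=", x$k_max, " valid_len=", x$valid_len,
      " key=", x$key, "\n", sep = "")
  invisible(x)
}

#' Extract the k-mer windows of a translated letter string
#'
#' If the string has at least `k_max` letters, one full-length window per
#' start position is returned (the index stores only full-length k-mers). If
#' the whole string is shorter than `k_max` but at least `k_lower` letters,
#' and `emit_padded` is `TRUE` (the read side), a single sentinel-padded
#' window with `valid_len` equal to the string length is returned. Shorter
#' strings yield no windows.
#'
#' @param letters A single letter string (already translated).
#' @param k_max Letters per k-mer (12 or 25).
#' @param k_lower Smallest k that will be queried.
#' @param table An [translation_table()] object.
#' @param emit_padded Emit the single padded window for short strings
#'   (read side); the index side leaves this `FALSE`.
#' @return A tibble with columns `pos` (1-based start), `key` and `valid_len`.
#' @export
kmers_of <- function(letters, k_max = 12L, k_lower = 7L,
                     table = translation_table(), emit_padded = FALSE) {
  k_max <- check_k_max(k_max)
  len <- nchar(letters)
  if (len >= k_max) {
    keystr <- encode_letters(letters, table)
    starts <- seq_len(len - k_max + 1L)
    tibble(pos = starts,
           key = substring(keystr, starts, starts + k_max - 1L),
           valid_len = k_max)
  } else if (emit_padded && len >= k_lower) {
    keystr <- encode_letters(letters, table)
    tibble(pos = 1L,
           key = paste0(keystr, strrep(KMER_SENTINEL_CHAR, k_max - len)),
           valid_len = len)
  } else {
    tibble(pos = integer(), key = character(), valid_len = integer())
  }
}

# radix (C-locale) order — the packed-integer order; used everywhere keys are
# sorted so results never depend on the session locale
key_order <- function(key, ...) order(key, ..., method = "radix")
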