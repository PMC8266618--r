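test_that("index entries match a hand enumeration on a tiny genome", {
  td <- withr::local_tempdir()
  seq <- strrep("ATG", 20)  # 60 nt
  fa <- file.path(td, "toy.fasta")
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- "TOY1.1"
  Biostrings::writeXStringSet(x, fa)
  tax <- taxonomy(c(TOY1.1 = 9L),
                  tibble::tibble(tax_id = c(1L, 9L), parent_id = c(1L, 1L),
                                 rank = c("no rank", "species"),
                                 name = c("root", "toy")))
  content <- build_content(fa, tax)
  idx <- build_index(fa, content, k_max = 12, frames = 1, mem_mb = 10)
  # frame 0 translates to M x 20; expected windows are the distinct
  # full-length 12-mers of that string paired with the single taxon
  lets <- translate_frame(seq, 0, STD)
  wins <- unique(substring(lets, 1:(nchar(lets) - 11), 12:nchar(lets)))
  expect_equal(nrow(idx$entries), length(wins))
  expect_equal(sort(vapply(wins, function(w) pack_kmer(w, 12, STD)$key,
                           character(1)), method = "radix"),
               idx$entries$key, ignore_attr = TRUE)
  expect_true(all(idx$entries$line == 1L))
})

test_that("the same k-mer may carry several taxa, once per taxon", {
  td <- withr::local_tempdir()
  seq <- random_dna(300, seed = 21)
  fa <- file.path(td, "dup.fasta")
  x <- Biostrings::DNAStringSet(c(seq, seq))
  names(x) <- c("DUPA.1", "DUPB.1")
  Biostrings::writeXStringSet(x, fa)
  tax <- taxonomy(c(DUPA.1 = 11L, DUPB.1 = 22L),
                  tibble::tibble(tax_id = c(1L, 11L, 22L),
                                 parent_id = c(1L, 1L, 1L),
                                 rank = c("no rank", "species", "species"),
                                 name = c("root", "a", "b")))
  idx <- build_index(fa, build_content(fa, tax), frames = 6, mem_mb = 10)
  per_key <- table(table(idx$entries$key))
  expect_equal(names(per_key), "2")  # every k-mer listed once per taxon
  expect_equal(idx$freq[1], idx$freq[2])
  expect_equal(ambiguity_value(idx), 0.5)
})

test_that("the index payload is independent of the memory budget", {
  ref <- make_reference(n_taxa = 2, genome_len = 1200, seed = 31)
  p_small <- file.path(ref$dir, "small.bin")
  p_big <- file.path(ref$dir, "big.bin")
  i_small <- build_index(ref$fasta, ref$content, mem_mb = 0.02, path = p_small)
  i_big <- build_index(ref$fasta, ref$content, mem_mb = 100, path = p_big)
  expect_identical(i_small$entries, i_big$entries)
  expect_identical(readBin(p_small, "raw", file.size(p_small)),
                   readBin(p_big, "raw", file.size(p_big)))
  expect_error(build_index(ref$fasta, ref$content, mem_mb = 0.0001),
               "below floor")
})

test_that("trie ranges agree with a linear scan and partition the index", {
  ref <- make_reference(n_taxa = 3, genome_len = 900, seed = 41)
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10)
  n <- nrow(idx$entries)
  # partition invariant: ordered, disjoint, union [0, N)
  expect_equal(idx$trie$lower[1], 0L)
  expect_equal(idx$trie$upper[length(idx$trie$upper)], n)
  expect_true(all(idx$trie$lower < idx$trie$upper))
  if (length(idx$trie$lower) > 1) {
    expect_equal(idx$trie$lower[-1], idx$trie$upper[-length(idx$trie$upper)])
  }
  expect_true(all(nchar(idx$trie$prefix) == 6L))
  # lookups equal linear scan
  withr::with_seed(5, picks <- sample(n, 25))
  for (i in picks) {
    key <- idx$entries$key[i]
    rng <- trie_lookup(idx, key)
    scan <- which(substr(idx$entries$key, 1, 6) == substr(key, 1, 6))
    expect_equal(unname(rng), c(min(scan) - 1L, max(scan)))
  }
  # absent prefix: empty range
  absent <- pack_kmer(strrep("W", 12), 12, STD)
  if (!substr(absent$key, 1, 6) %in% idx$trie$prefix) {
    expect_equal(unname(trie_lookup(idx, absent)), c(0L, 0L))
  }
  expect_error(trie_lookup(idx, pack_kmer("MKA", 12, STD)), "6")
})

test_that("an index survives a save/load round trip", {
  ref <- make_reference(n_taxa = 2, genome_len = 800, seed = 51)
  p <- file.path(ref$dir, "idx.bin")
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10, path = p)
  back <- load_index(p, ref$content_path)
  expect_identical(back$entries, idx$entries)
  expect_identical(back$trie, idx$trie)
  expect_equal(back$freq, idx$freq)
  expect_equal(back$meta$k_max, idx$meta$k_max)
  expect_equal(back$table$codon_map, idx$table$codon_map, ignore_attr = TRUE)
})

test_that("updating equals rebuilding and respects append-only content", {
  ref <- make_reference(n_taxa = 2, genome_len = 1000, seed = 61)
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10)
  # identity on empty additions
  expect_identical(update_index(idx, character(0), ref$content)$entries,
                   idx$entries)
  # new genomes under new taxa
  g2 <- sample_genomes(2, 1000, seed = 62)
  g2$accession <- sprintf("ADD%04d.1", 1:2)
  g2$tax_id <- c(901L, 902L)
  g2$name <- paste0("Added taxon ", 1:2)
  fa2 <- file.path(ref$dir, "add.fasta")
  write_genomes_fasta(g2, fa2)
  all_g <- dplyr::bind_rows(ref$genomes, g2)
  tax_all <- write_taxonomy(all_g, file.path(ref$dir, "a2.tsv"),
                            file.path(ref$dir, "n2.tsv"))
  content_all <- build_content(c(ref$fasta, fa2), tax_all)
  rebuilt <- build_index(c(ref$fasta, fa2), content_all, mem_mb = 10)
  updated <- update_index(idx, fa2, content_all)
  expect_identical(rebuilt$entries, updated$entries)
  expect_identical(rebuilt$trie, updated$trie)
  # reordered content is rejected
  shuffled <- aakmer:::new_content(content_all[c(2, 1, 3, 4), ] |>
                                     dplyr::mutate(line = 1:4))
  expect_error(update_index(idx, fa2, shuffled), "appended")
})

test_that("lossless shrink halves records, reconstructs exactly, stays static", {
  ref <- make_reference(n_taxa = 3, genome_len = 700, seed = 71)
  p_full <- file.path(ref$dir, "full.bin")
  p_shr <- file.path(ref$dir, "shr.bin")
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10, path = p_full)
  shr <- shrink_lossless(idx)
  save_index(shr, p_shr)
  n <- nrow(idx$entries)
  header <- 28  # magic + six int32 fields
  expect_equal((file.size(p_full) - header) / n, 16)
  expect_equal((file.size(p_shr) - header) / n, 8)
  # reconstruction through the trie leaf prefixes is exact
  back <- load_index(p_shr, ref$content_path)
  expect_identical(back$entries, idx$entries)
  expect_true(back$meta$shrunken_lossless)
  # static from now on
  expect_error(update_index(back, character(0), ref$content), "static")
  # wrong content file refuses to load
  other <- file.path(ref$dir, "other.tsv")
  writeLines("someone\t42\tX.1", other)
  expect_error(load_index(p_shr, other), "checksum")
})

test_that("lossless shrink enforces its constraints", {
  big_content <- make_content(65536L)
  idx_big <- fake_index(big_content)
  expect_error(shrink_lossless(idx_big), "65535")
  ok_content <- make_content(3L)
  idx25 <- fake_index(ok_content, k_max = 25L)
  idx25$meta$width_bits <- 128L
  expect_error(shrink_lossless(idx25), "64-bit")
  expect_silent(shrink_lossless(fake_index(ok_content)))
})

test_that("lossy shrink deletes a fair per-taxon share, reproducibly", {
  ref <- make_reference(n_taxa = 3, genome_len = 1200, seed = 81)
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10)
  half <- shrink_lossy(idx, percent = 50, seed = 9)
  expect_equal(half$freq, idx$freq - floor(idx$freq * 0.5 + 0.5))
  # taxa with more k-mers lose more in absolute terms
  lost <- idx$freq - half$freq
  expect_true(all(diff(lost[order(idx$freq)]) >= 0))
  # identical seed, identical result; sortedness preserved
  expect_identical(shrink_lossy(idx, percent = 50, seed = 9)$entries,
                   half$entries)
  expect_identical(half$entries,
                   half$entries[order(half$entries$key, half$entries$line,
                                      method = "radix"), ])
  # identity and boundary cases
  expect_identical(shrink_lossy(idx, percent = 0)$entries, idx$entries)
  expect_warning(noop <- shrink_lossy(idx, target_gb = 1), "unchanged")
  expect_identical(noop$entries, idx$entries)
  gone <- shrink_lossy(idx, percent = 100, seed = 9)
  expect_equal(nrow(gone$entries), 0)
  # single-entry taxa are protected below 100%
  one <- idx$entries[!duplicated(idx$entries$line), ]
  idx_one <- aakmer:::new_index(one[order(one$key, method = "radix"), ],
                                ref$content, STD, idx$meta)
  kept <- shrink_lossy(idx_one, percent = 90, seed = 2)
  expect_equal(kept$freq, idx_one$freq)
})
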