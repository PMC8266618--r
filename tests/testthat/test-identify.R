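test_that("pair conversion emits every window, keeps duplicates, stays sorted", {
  ref <- make_reference(n_taxa = 1, genome_len = 600, seed = 91)
  region <- substr(ref$genomes$seq[1], 101, 200)
  pairs <- reads_to_pairs(tibble::tibble(read_id = "r1", seq = region),
                          k_max = 12, frames = 1, table = STD)
  lets <- translate_frame(region, 0, STD)
  expect_equal(nrow(pairs), nchar(lets) - 12 + 1)
  expect_identical(pairs$key, sort(pairs$key, method = "radix"))
  # two identical reads double every pair
  pairs2 <- reads_to_pairs(tibble::tibble(read_id = c("r1", "r2"),
                                          seq = c(region, region)),
                           k_max = 12, frames = 1, table = STD)
  expect_equal(nrow(pairs2), 2 * nrow(pairs))
  expect_equal(table(pairs2$read_id), table(c(rep("r1", nrow(pairs)),
                                              rep("r2", nrow(pairs)))),
               ignore_attr = TRUE)
  # a too-short read yields no pairs and is reported unclassified
  expect_message(
    p0 <- reads_to_pairs(tibble::tibble(read_id = "tiny", seq = "ACGTACGT"),
                         k_max = 12, frames = 3, table = STD),
    "unclassified")
  expect_equal(nrow(p0), 0)
  expect_equal(attr(p0, "read_info")$n_pairs, 0L)
})

test_that("an exact read matches its own taxon at every k and only there", {
  ref <- make_reference(n_taxa = 3, genome_len = 2000, seed = 101)
  idx <- build_index(ref$fasta, ref$content, frames = 6, mem_mb = 10)
  region <- substr(ref$genomes$seq[2], 501, 600)
  ident <- identify_reads(idx, c(r = region), k = c(7, 12), frames = 3)
  counts <- aakmer:::match_counts(ident$matches)
  full <- counts[counts$line == 2, ]
  expect_setequal(full$k, 7:12)
  n_pairs <- ident$matches$read_info$n_pairs
  # every one of the read's k-mer occurrences matches the true taxon at k=12
  expect_equal(full$n[full$k == 12], n_pairs)
  expect_equal(ident$results$tax_id[1], ref$genomes$tax_id[2])
})

test_that("a reverse-strand read reaches the same maximal-k matches", {
  ref <- make_reference(n_taxa = 2, genome_len = 2000, seed = 111)
  idx <- build_index(ref$fasta, ref$content, frames = 6, mem_mb = 10)
  region <- substr(ref$genomes$seq[1], 301, 400)
  fwd <- identify_reads(idx, c(f = region), k = c(7, 12), frames = 3)
  rev <- identify_reads(idx, c(r = reverse_complement(region)),
                        k = c(7, 12), frames = 3)
  cf <- aakmer:::match_counts(fwd$matches)
  cr <- aakmer:::match_counts(rev$matches)
  expect_equal(max(cf$k[cf$line == 1]), 12)
  expect_equal(max(cr$k[cr$line == 1]), 12)
  expect_equal(fwd$results$tax_id[1], rev$results$tax_id[1])
})

test_that("match counts equal the brute-force oracle on mutated reads", {
  withr::with_seed(121, {
    for (i in 1:5) {
      g <- sample_genomes(3, 600, seed = 1000 + i)
      reads <- sample_reads(g, 15, 90, seed = 2000 + i)
      reads <- mutate_reads(reads, runif(1, 0, 0.15), seed = 3000 + i)
      td <- withr::local_tempdir()
      fa <- file.path(td, "g.fasta")
      write_genomes_fasta(g, fa)
      tax <- write_taxonomy(g, file.path(td, "a.tsv"), file.path(td, "n.tsv"))
      idx <- build_index(fa, build_content(fa, tax), frames = 6, mem_mb = 10)
      pairs <- reads_to_pairs(reads[, c("read_id", "seq")], k_max = 12,
                              frames = 3, table = STD)
      got <- impl_match_counts(match_pairs(pairs, idx, 7, 12))
      ref_tbl <- tibble::tibble(line = seq_len(nrow(g)), seq = g$seq)
      want <- oracle_match_counts(ref_tbl, reads, STD, 12, 7, 12)
      expect_equal(got, want)
    }
  })
})

test_that("splitting the input into pieces does not change the scores", {
  ref <- make_reference(n_taxa = 3, genome_len = 1500, seed = 131)
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10)
  reads <- mutate_reads(sample_reads(ref$genomes, 30, 100, seed = 4),
                        0.08, seed = 5)[, c("read_id", "seq")]
  whole <- identify_reads(idx, reads, k = c(7, 12))
  parts <- split(seq_len(nrow(reads)), rep(1:3, length.out = nrow(reads)))
  piecewise <- dplyr::bind_rows(lapply(parts, function(ix) {
    identify_reads(idx, reads[ix, ], k = c(7, 12))$results
  }))
  a <- dplyr::arrange(whole$results, read_id, tax_id)
  b <- dplyr::arrange(piecewise, read_id, tax_id)
  expect_equal(a, b)
})

test_that("k-mer scores implement the weighted shared-taxa sum", {
  # one k-mer matching only taxon t at exactly k = 25
  m <- fake_matches(tibble::tibble(read_id = "r", prefix = "p", occ = 1L,
                                   line = 1L, n_taxa = 1L, k = 25L), 25, 25)
  expect_equal(kmer_scores(m)$kmer_score, 1.0)
  # shared with a second taxon: half each
  m2 <- fake_matches(tibble::tibble(read_id = "r", prefix = "p", occ = 1L,
                                    line = 1:2, n_taxa = 2L, k = 25L), 25, 25)
  expect_equal(kmer_scores(m2)$kmer_score, c(0.5, 0.5))
  # multi-k: one k-mer alone at every k from 7 to 12
  m3 <- fake_matches(tibble::tibble(read_id = "r", prefix = "p", occ = 1L,
                                    line = 1L, n_taxa = 1L, k = 7:12), 7, 12)
  expect_equal(kmer_scores(m3)$kmer_score, sum((7:12)^2) / 625)
  expect_equal(kmer_scores(m3)$kmer_score, 0.8944, tolerance = 1e-10)
})

test_that("the relative score normalizes by read length and taxon frequency", {
  for (s in c(0.3, 1, 7)) expect_equal(relative_score(s, 1, 1), s)
  expect_equal(relative_score(1, 100, 1000), 1 / (1 + log2(1e5)),
               tolerance = 1e-12)
  expect_equal(relative_score(1, 100, 1000), 0.05679, tolerance = 1e-4)
  freqs <- c(1, 10, 100, 1000)
  expect_true(all(diff(relative_score(1, 50, freqs)) < 0))
  expect_error(relative_score(1, 0, 1), ">= 1")
})

test_that("identification output is ranked, tie-broken and filterable", {
  ref <- make_reference(n_taxa = 3, genome_len = 1500, seed = 141)
  idx <- build_index(ref$fasta, ref$content, mem_mb = 10)
  reads <- mutate_reads(sample_reads(ref$genomes, 10, 100, seed = 6),
                        0.12, seed = 7)[, c("read_id", "seq")]
  ident <- identify_reads(idx, reads, k = c(7, 12))
  by_read <- split(ident$results, ident$results$read_id)
  for (rr in by_read) {
    expect_true(all(diff(rr$relative_score) <= 0))
    ties <- split(rr$tax_id, rr$relative_score)
    for (tt in ties) expect_true(all(diff(tt) >= 0))
  }
  td <- withr::local_tempdir()
  out <- file.path(td, "ident.tsv")
  write_identification(ident, out)
  tsv <- utils::read.table(out, sep = "\t", header = TRUE, fill = TRUE,
                           na.strings = c("", "NA"))
  expect_equal(sort(unique(tsv$read_id)), sort(reads$read_id))
  # the filter drops sub-cutoff rows
  cut <- mean(range(ident$results$relative_score))
  out2 <- file.path(td, "ident_f.tsv")
  write_identification(ident, out2, filter = cut)
  tsv2 <- utils::read.table(out2, sep = "\t", header = TRUE, fill = TRUE,
                            na.strings = c("", "NA"))
  kept <- tsv2[!is.na(tsv2$relative_score), ]
  expect_true(all(kept$relative_score >= cut - 1e-6))
  expect_lt(nrow(kept), nrow(tsv[!is.na(tsv$relative_score), ]))
  # json format round-trips the same calls
  outj <- file.path(td, "ident.json")
  write_identification(ident, outj, format = "json")
  j <- jsonlite::read_json(outj)
  expect_equal(length(j), nrow(ident$read_info))
})

test_that("shrunken indices refuse k_lower below the trie depth", {
  ref <- make_reference(n_taxa = 2, genome_len = 700, seed = 151)
  idx <- shrink_lossless(build_index(ref$fasta, ref$content, mem_mb = 10))
  reads <- sample_reads(ref$genomes, 3, 100, seed = 7)[, c("read_id", "seq")]
  pairs <- reads_to_pairs(reads, k_max = 12, k_lower = 5, table = STD)
  expect_error(match_pairs(pairs, idx, k_lower = 5), "k_lower >= 7")
  expect_error(match_pairs(pairs, idx, k_lower = 7, k_upper = 13), "k_max")
  expect_error(match_pairs(pairs, idx, k_lower = 9, k_upper = 8), "k_lower")
})
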