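# Shared fixtures: toy genomes, taxonomies and indices built in code.

STD <- translation_table()

# genomes + FASTA + taxonomy + content written under a temp dir
make_reference <- function(n_taxa = 3, genome_len = 1500, seed = 7,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  g <- sample_genomes(n_taxa, genome_len, seed = seed)
  fa <- file.path(dir, "genomes.fasta")
  write_genomes_fasta(g, fa)
  tax <- write_taxonomy(g, file.path(dir, "acc2tax.tsv"),
                        file.path(dir, "nodes.tsv"))
  content_path <- file.path(dir, "content.tsv")
  content <- write_content(build_content(fa, tax, level = "lowest"),
                           content_path)
  list(genomes = g, fasta = fa, taxonomy = tax, content = content,
       content_path = content_path, dir = dir)
}

# hand-made match table for formula-level tests
fake_matches <- function(hits, k_lower, k_upper, input_totals = NULL) {
  ks <- k_lower:k_upper
  structure(
    list(hits = tibble::as_tibble(hits),
         input_totals = input_totals %||%
           tibble::tibble(k = ks, n_input = rep(1L, length(ks))),
         k_lower = as.integer(k_lower), k_upper = as.integer(k_upper),
         read_info = NULL),
    class = "aak_matches"
  )
}

# minimal index shell when only content/metadata is consulted
fake_index <- function(content, k_max = 12L) {
  aakmer:::new_index(tibble::tibble(key = character(), line = integer()),
                     content, STD,
                     list(k_max = k_max, width_bits = 64L, frames = 6L,
                          level = "lowest", shrunken_lossless = FALSE,
                          lossy_seed = NA_integer_,
                          content_checksum = NA_character_))
}

make_content <- function(n) {
  aakmer:::new_content(tibble::tibble(
    line = seq_len(n),
    name = paste0("taxon ", seq_len(n)),
    tax_id = seq_len(n),
    accessions = lapply(seq_len(n), function(i) paste0("ACC", i))
  ))
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else aakmer:::with_seed(seed, draw())
}
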