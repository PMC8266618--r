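# Synthetic benchmark data: random reference genomes with a flat toy
# taxonomy, uniformly sampled fixed-length reads with per-base substitution
# mutations, and per-read sensitivity/precision/F1 evaluation.

#' Generate random reference genomes with a toy taxonomy
#'
#' Sequences are i.i.d. uniform over ACGT, one per taxon, with generated
#' accessions and a flat taxonomy (every taxon a species under a single
#' root). Fully determined by the seed.
#'
#' @param n_taxa Number of genomes/taxa.
#' @param genome_len Length of each genome in nucleotides (>= 300).
#' @param seed Integer seed.
#' @return A tibble of class `aak_genomes` with columns `accession`,
#'   `tax_id`, `name`, `seq`.
#' @export
sample_genomes <- function(n_taxa = 3L, genome_len = 50000L, seed = 1L) {
  if (n_taxa < 1L) abort("`n_taxa` must be >= 1")
  if (genome_len < 300L) abort("`genome_len` must be >= 300")
  seqs <- with_seed(seed, {
    vapply(seq_len(n_taxa), function(i) {
      paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  g <- tibble(
    accession = sprintf("SYN%04d.1", seq_len(n_taxa)),
    tax_id = 100L + seq_len(n_taxa),
    name = paste0("Synthetic taxon ", seq_len(n_taxa)),
    seq = seqs
  )
  structure(g, class = c("aak_genomes", class(g)))
}

#' Write genomes as a FASTA reference file
#'
#' @param genomes An `aak_genomes` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes$seq)
  names(x) <- paste(genomes$accession, genomes$name)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the toy taxonomy TSVs for a set of genomes
#'
#' Emits the two files [read_taxonomy()] consumes: an
#' `accession<TAB>tax_id` map and a node table with every taxon as a
#' species under a single root (tax_id 1).
#'
#' @param genomes An `aak_genomes` tibble.
#' @param acc2tax_path,nodes_path Output paths.
#' @return An [taxonomy()] object, invisibly.
#' @export
write_taxonomy <- function(genomes, acc2tax_path, nodes_path) {
  writeLines(paste(genomes$accession, genomes$tax_id, sep = "\t"),
             acc2tax_path)
  nodes <- tibble(
    tax_id = c(1L, genomes$tax_id),
    parent_id = c(1L, rep(1L, nrow(genomes))),
    rank = c("no rank", rep("species", nrow(genomes))),
    name = c("root", genomes$name)
  )
  writeLines(paste(nodes$tax_id, nodes$parent_id, nodes$rank, nodes$name,
                   sep = "\t"), nodes_path)
  invisible(taxonomy(setNames(genomes$tax_id, genomes$accession), nodes))
}

#' Sample reads of fixed length from a set of genomes
#'
#' Genome choice and start position are uniform; reads are taken from the
#' forward strand unless `reverse_strand` is `TRUE`, in which case each
#' read is reverse-complemented with probability 1/2. The returned truth
#' table records the source of every read.
#'
#' @param genomes An `aak_genomes` tibble.
#' @param n_reads Number of reads.
#' @param read_len Read length in nucleotides (default 100).
#' @param seed Integer seed.
#' @param reverse_strand Also sample reverse-strand reads.
#' @return A tibble of class `aak_reads`: `read_id`, `seq`, `true_tax_id`,
#'   `accession`, `pos`, `strand`, `mutation_rate` (0 until
#'   [mutate_reads()]).
#' @export
sample_reads <- function(genomes, n_reads = 1000L, read_len = 100L,
                         seed = 1L, reverse_strand = FALSE) {
  if (read_len > min(nchar(genomes$seq))) {
    abort("`read_len` cannot exceed the genome length")
  }
  with_seed(seed, {
    gi <- sample.int(nrow(genomes), n_reads, replace = TRUE)
    pos <- floor(runif(n_reads) * (nchar(genomes$seq)[gi] - read_len + 1)) + 1L
    strand <- if (reverse_strand) {
      sample(c("+", "-"), n_reads, replace = TRUE)
    } else {
      rep("+", n_reads)
    }
    seq <- substr(genomes$seq[gi], pos, pos + read_len - 1L)
    seq[strand == "-"] <- reverse_complement(seq[strand == "-"])
    r <- tibble(
      read_id = sprintf("read_%06d", seq_len(n_reads)),
      seq = seq,
      true_tax_id = genomes$tax_id[gi],
      accession = genomes$accession[gi],
      pos = as.integer(pos),
      strand = strand,
      mutation_rate = 0
    )
    structure(r, class = c("aak_reads", class(r)))
  })
}

#' Mutate reads with per-base substitutions
#'
#' Every base is independently substituted with probability `p`, and a
#' substituted base always becomes a uniformly chosen *different* base
#' (Bernoulli-per-base model of a stated mutation percentage).
#'
#' @param reads An `aak_reads` tibble.
#' @param p Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The reads with mutated `seq` and `mutation_rate` set to `p`.
#' @export
mutate_reads <- function(reads, p, seed = 1L) {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1]")
  if (p == 0 || nrow(reads) == 0) {
    reads$mutation_rate <- p
    return(reads)
  }
  lens <- nchar(reads$seq)
  with_seed(seed, {
    bases <- strsplit(paste(reads$seq, collapse = ""), "")[[1]]
    hit <- runif(length(bases)) < p & bases %in% c("A", "C", "G", "T")
    if (any(hit)) {
      # uniformly one of the three other bases
      alt <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pick <- sample.int(3L, sum(hit), replace = TRUE)
      bases[hit] <- alt[cbind(match(bases[hit], rownames(alt)), pick)]
    }
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    all_seq <- paste(bases, collapse = "")
    reads$seq <- substring(all_seq, starts, ends)
  })
  reads$mutation_rate <- p
  reads
}

#' Write reads as a FASTQ file with constant quality
#'
#' @param reads An `aak_reads` tibble.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write the per-read truth table
#'
#' @param reads An `aak_reads` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(reads, path) {
  utils::write.table(
    reads[, c("read_id", "true_tax_id", "mutation_rate", "accession", "pos")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Score per-read classifications against the truth
#'
#' The prediction for a read is its top-ranked taxon (highest Relative
#' Score). A correct top call is a true positive; a wrong top call counts as
#' both a false positive and a false negative; an unclassified read is a
#' false negative only. Sensitivity is `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' and F1 their harmonic mean; an undefined ratio is reported as 0.
#'
#' @param predictions An `aak_identification`, or a tibble with `read_id`
#'   and `tax_id` columns holding top calls (`NA` tax_id = unclassified).
#' @param truth An `aak_reads` tibble or a tibble with `read_id` and
#'   `true_tax_id`.
#' @param level Taxonomic level at which to compare (default `"lowest"`).
#' @param taxonomy An [taxonomy()] object; required for levels other than
#'   `"lowest"`.
#' @return A one-row tibble: `sensitivity`, `precision`, `f1`, `tp`, `fp`,
#'   `fn`, `n_reads`.
#' @export
evaluate_classification <- function(predictions, truth, level = "lowest",
                                    taxonomy = NULL) {
  if (inherits(predictions, "aak_identification")) {
    predictions <- top_calls(predictions)
  }
  predictions <- as_tibble(predictions)
  truth <- as_tibble(truth)
  if (!"true_tax_id" %in% names(truth)) {
    abort("truth must have a `true_tax_id` column")
  }
  unknown <- setdiff(predictions$read_id, truth$read_id)
  if (length(unknown) > 0) {
    abort(paste0("prediction(s) for read(s) absent from truth: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  df <- truth |>
    select("read_id", "true_tax_id") |>
    left_join(predictions, by = "read_id")
  if (level != "lowest") {
    if (is.null(taxonomy)) abort("`taxonomy` is required for level resolution")
    df$true_tax_id <- resolve_level(df$true_tax_id, level, taxonomy)
    ok <- !is.na(df$tax_id)
    df$tax_id[ok] <- resolve_level(df$tax_id[ok], level, taxonomy)
  }
  classified <- !is.na(df$tax_id)
  tp <- sum(classified & df$tax_id == df$true_tax_id)
  fp <- sum(classified & df$tax_id != df$true_tax_id)
  fn <- sum(!classified) + fp  # wrong calls count as FN as well
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  tibble(sensitivity = sens, precision = prec, f1 = f1,
         tp = tp, fp = fp, fn = fn, n_reads = nrow(df))
}

#' Plot benchmark metrics against the mutation rate
#'
#' @param results A tibble with a `mutation_rate` column and metric columns
#'   (`f1`, `sensitivity`, `precision`), e.g. rows of
#'   [evaluate_classification()] output; an optional `scheme` column is
#'   mapped to color.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  long <- tidyr::pivot_longer(results,
                              cols = dplyr::any_of(c("f1", "sensitivity",
                                                     "precision")),
                              names_to = "metric", values_to = "value")
  aes <- if ("scheme" %in% names(long)) {
    ggplot2::aes(x = .data$mutation_rate, y = .data$value,
                 color = .data$scheme)
  } else {
    ggplot2::aes(x = .data$mutation_rate, y = .data$value)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "per-base mutation rate", y = NULL) +
    ggplot2::theme_minimal()
}
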