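# aakmer

Taxonomic identification and profiling of sequencing reads with
amino-acid-like encoded k-mers, a range of word lengths, and a sorted,
memory-budgeted reference index.

## The problem and the method

Metagenomic classifiers compare read k-mers against a reference database.
Fixed-k, nucleotide-exact tools force a single trade-off between
sensitivity (small k) and precision (large k), and lose reads quickly as
sequencing error or genuine divergence grows. aakmer attacks both problems
at once:

* **Amino-acid-like encoding.** Every nucleotide triplet — coding or not —
  is translated through a codon table (standard genetic code by default,
  plus `*` for stops and `X` for ambiguous codons) into a ≤31-letter
  alphabet stored in 5 bits per letter. Synonymous substitutions vanish in
  at least one reading frame, so matching is robust to a large class of
  mutations. Three forward frames lose no internal base; the index is
  built six-frame by default so reverse-strand reads need only the three
  forward frames at query time.
* **A range of k.** The index stores only maximum-length k-mers
  (`k_max` = 12 letters for 64-bit words or 25 for 128-bit words; 25
  letters ≡ 75 nt). Queries match every k in `[k_lower, k_upper]`
  simultaneously: a long match is strong evidence, and when a mutation
  breaks it, the surviving shorter prefix still counts. A depth-6 prefix
  trie narrows every lookup to the index range sharing the query's
  6-letter prefix (hence the default `k_lower = 7`).

A match of taxon *t* for read *r* at length *k* carries weight
`w(k) = k²/625` (k² normalized to (0,1] over k = 1..25), shared evenly
among the taxa matched by that k-mer:

    Score(t, r)    = Σ_{x ∈ I_r} Σ_k  w(k) · [x matches t at k] / |T(x, k)|
    RelScore(t, r) = Score(t, r) / (1 + log2(length(r) · frequency(t)))

with `frequency(t)` the taxon's total k-mer count in the index. Per-read
output ranks taxa by Relative Score. Profiles aggregate the same matches
per k into unique (`h_u`), non-unique (`h`, each shared occurrence split
`1/|T|` ways) and overall relative frequencies, plus an index ambiguity
value. The index supports updating without rebuilds, lossless halving of
its record width (prefix moved into the trie, taxon ID replaced by a
16-bit content-file line number) and seeded lossy per-taxon shrinking.

A seeded simulator (uniform random genomes, fixed-length reads, per-base
substitution mutations) and a per-read sensitivity/precision/F1 evaluator
make the whole pipeline testable at desk scale with no downloads.

## Worked example

```r
library(aakmer)

dir     <- tempfile("aakmer_demo_"); dir.create(dir)
genomes <- sample_genomes(n_taxa = 3, genome_len = 20000, seed = 42)
fasta   <- file.path(dir, "refs.fasta")
write_genomes_fasta(genomes, fasta)
taxo    <- write_taxonomy(genomes, file.path(dir, "acc2tax.tsv"),
                          file.path(dir, "nodes.tsv"))
content <- write_content(build_content(fasta, taxo, level = "lowest"),
                         file.path(dir, "content.tsv"))

index <- build_index(fasta, content, k_max = 12, frames = 6, mem_mb = 64)
index
#> <aak_index> 119790 entries | k_max=12 (64-bit) | frames=6 | level=lowest
#>   3 taxa | 119471 trie leaves (depth 6)

reads <- sample_reads(genomes, n_reads = 500, read_len = 100, seed = 7) |>
  mutate_reads(p = 0.10, seed = 8)          # 10% per-base substitutions

ident <- identify_reads(index, reads[, c("read_id", "seq")],
                        k = c(7, 12), frames = 3)
head(tidy(ident), 5)
#> # A tibble: 5 × 5
#>   read_id     tax_id name              relative_score kmer_score
#>   <chr>        <int> <chr>                      <dbl>      <dbl>
#> 1 read_000001    102 Synthetic taxon 2        0.123       2.82
#> 2 read_000002    103 Synthetic taxon 3        0.00342     0.0784
#> 3 read_000003    103 Synthetic taxon 3        0.124       2.84
#> 4 read_000004    103 Synthetic taxon 3        0.575      13.2
#> 5 read_000005    102 Synthetic taxon 2        0.292       6.69

evaluate_classification(ident, reads)
#> # A tibble: 1 × 7
#>   sensitivity precision    f1    tp    fp    fn n_reads
#>         <dbl>     <dbl> <dbl> <int> <int> <int>   <int>
#> 1       0.944         1 0.971   472     0    28     500
```

Even at 10% mutation — one error every ten bases — 472 of 500 reads keep a
scoring match and every classified read lands on its true genome: the
shorter k's recover reads whose 36-nt maximal windows are all broken, and
the quadratic weights keep by-chance short matches from outvoting real
ones. The per-k profile of the same run:

```r
profile <- taxonomic_profile(ident, index)
head(profile, 3)
#> # A tibble: 3 × 8
#>   tax_id name                  k unique_count nonunique_weight   h_u     h overall
#>    <int> <chr>             <int>        <int>            <dbl> <dbl> <dbl>   <dbl>
#> 1    101 Synthetic taxon 1     7         2062             2065 0.345 0.345  0.0635
#> 2    102 Synthetic taxon 2     7         1970             1972 0.329 0.329  0.0607
#> 3    103 Synthetic taxon 3     7         1948             1949 0.326 0.326  0.0600
```

`h` and `h_u` recover the uniform read mixture; `overall` is small because
mutated k-mers match nothing and still count in its denominator.
`autoplot(profile)` draws the per-k frequency panels, and
`apply_cutoff(profile, 0.01)` drops trace taxa. A command-line interface
(`exec/aakmer`) exposes `build`, `identify`, `profile`, `shrink`,
`update`, `simulate` and `evaluate` over the same functions.

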