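---
title: "Methods: amino-acid-like k-mer classification and profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino-acid-like k-mer classification and profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

aakmer assigns taxa to sequencing reads by comparing translated k-mers
against a sorted reference index, and aggregates those matches into per-k
taxonomic profiles. This vignette describes the model and the design
decisions behind the implementation; the README shows a worked example.

## The encoding

Every nucleotide triplet — coding or not — is mapped through a codon table
(the standard genetic code by default) to one letter of an alphabet of at
most 31 letters. Two letters extend the plain amino-acid alphabet:

* `*` for stop codons: translation continues through stops because
  non-coding sequence is encoded too;
* `X` for any codon containing a non-ACGT base. `X` matches `X` like any
  other letter; this is the simplest deterministic treatment of ambiguity
  and is resolved at translation time, not at reverse complementation
  (which maps `A<->T`, `C<->G` and leaves every other IUPAC letter in
  place).

A DNA sequence is scanned in one, three, or six reading frames (three
forward frames, then the three frames of the reverse complement). Index
building defaults to six frames; read identification defaults to three,
because reverse-strand hits are already covered by a six-frame index. Three
forward frames are lossless up to the first and last base: the frames
contribute `floor(L/3) + floor((L-1)/3) + floor((L-2)/3) = L - 2` codons,
one per internal base triple. The translation is also invariant under
synonymous codon substitutions, which is the main source of the method's
robustness to sequencing errors and real mutations: in at least one frame a
synonymous change leaves the letter sequence untouched.

### Packed k-mers

Letters get 5-bit codes 1..31 assigned in ascending lexicographic order;
code 0 is the padding sentinel. A k-mer of up to `k_max` letters
(`k_max = 12` for 64-bit words, 25 for 128-bit words; 60 and 125 payload
bits) packs its letters most-significant-first, so integer order equals
lexicographic order and a shared k-letter prefix is a shared high-bit
block.

In this implementation the packed word is realized as a fixed-width byte
string, one byte per 5-bit code (byte `0x40 + code`), because base R has no
native 64/128-bit unsigned integer. Byte-wise order of these strings under
a radix sort is exactly the packed-integer order, prefix extraction is
`substr()`, and every ordering in the package goes through radix (C-locale)
sorting so results never depend on the session locale.

The index stores only maximum-length k-mers, so it is independent of the k
range chosen later. On the read side, a whole translated frame shorter than
`k_max` (but at least `k_lower` letters) contributes a single
sentinel-padded window so short reads stay classifiable; trailing
sub-`k_max` suffixes of long frames are not emitted, keeping the read side
symmetric with the index. The sentinel sorts before every letter, so padded
words sort directly before their extensions.

## The content file and taxonomy

The index never stores taxonomic IDs directly; it stores the line number of
a human-readable "content file", a headerless TSV with one taxon per line:
`name<TAB>tax_id<TAB>acc1;acc2;...`. Entries appear in first-appearance
order; accessions parsed from FASTA headers (first token, with the classic
NCBI pipe dialect handled) are grouped under the tax_id resolved to the
requested taxonomic level. Records whose accession is unknown to the
taxonomy are kept under the dummy tax_id 0 ("unnamed") with a warning —
references are never silently dropped, and a taxon with no ancestor at the
requested rank keeps its own ID for the same reason.

Toy taxonomies are two TSVs (`accession<TAB>tax_id`;
`tax_id<TAB>parent<TAB>rank<TAB>name`), so nothing is downloaded. The
content file's checksum is recorded in the index metadata; a
lossless-shrunken index refuses to load against any other content file,
because its records are only recoverable through that file's line numbers.

## Index construction under a memory budget

Building streams (k-mer, line) pairs into a buffer whose capacity is
derived from the `mem_mb` budget (about `k_max + 60` bytes per buffered
pair, a documented soft accounting; budgets below room for 100 pairs are
rejected). A full buffer is radix-sorted, deduplicated and spilled as a
sorted binary chunk; chunks are k-way merged at the end with cross-chunk
deduplication of identical pairs. Identical k-mers under *different* taxa
are all kept — that redundancy is what the profiles later divide out.

The merge emits, per round, every loaded pair strictly below the smallest
last-loaded key over chunks that still hold unread data. A key can
therefore never straddle two rounds, which makes within-round sort +
deduplication globally correct without any cross-locale string comparison.
The final index is byte-identical whatever the budget, which the tests
assert directly. The budget is a soft contract sizing buffers, not an
OS-level limit, and the finished in-memory index is an ordinary R object.

A depth-6 prefix trie maps each 6-letter prefix to the half-open range of
index positions sharing it (0-based `[lower, upper)`); ranges are ordered,
disjoint and cover the whole index. The default `k_lower = 7` lets the trie
fully resolve every query prefix before the suffix is compared.

On disk an index is a flat little-endian file of fixed-width records
(magic, version and geometry in a 28-byte header), a `.trie` sidecar and a
`.meta.json` sidecar carrying the level, per-taxon frequencies, the codon
table and the content checksum. This portable layout replaces an
external-memory vector library with an explicit contract: uniform space per
entry, sorted order, sequential merge access.

### Updating and shrinking

New references are merged into an existing index without a rebuild; the
content file may only gain appended lines, so stored line numbers stay
valid. Two shrink modes exist:

* **Lossless halving** (requires `k_max = 12`, at most 65535 content
  entries, and a static index): each record drops its first six letters —
  recoverable from the trie leaf that owns its position — and stores a
  16-bit content line number, 8 bytes instead of 16. Identification output
  is unchanged, byte for byte; updating is disabled.
* **Lossy per-taxon deletion**: `round(percent * n_t / 100)` entries of
  each taxon `t` are deleted uniformly at random (half-up rounding; a taxon
  with one entry is protected below 100%, a choice this package makes where
  the method description is silent), so larger taxa lose more in absolute
  terms. A target size in GB is first converted to a percentage. The seed
  is recorded in the metadata.

## Identification

Reads are converted to sorted (k-mer, read) pairs exactly like references,
except that each k-mer carries a read ID and duplicates are kept — repeated
motifs should count per occurrence (de-duplicate reads beforehand if that
would distort abundances). For every k in `[k_lower, k_upper]` an input
occurrence matches taxon `t` when its k-letter prefix equals the k-prefix
of one of `t`'s entries; because a prefix match at k implies one at every
smaller k, a maximal match of length `m` contributes matches at every k in
`[k_lower, m]`. Padded input words match only up to their valid length.
Matching is implemented as per-k joins of prefix groups after the trie
discards input k-mers whose 6-letter prefix is absent; this is equivalent
to the classical two-pointer sweep over the two sorted lists and is checked
exactly against a brute-force translated-substring oracle in the tests.
Because every score below is a sum over input occurrences, splitting an
input file into pieces and concatenating the per-piece results changes
nothing.

Matches of length k are weighted `w(k) = k^2 / 625` — the quadratic
normalized to (0, 1] over k = 1..25, so `w(25) = 1`. The same denominator
is kept for `k_max = 12` indices; renormalizing to `k^2/144` would only
rescale all scores of a run by a constant and change no ranking, so the
single fixed scheme is preferred for comparability across indices. The
k-mer Score of taxon `t` for read `r` is

$$\mathrm{Score}(t, r) = \sum_{x \in I_r} \; \sum_{k=k_{\ell}}^{k_u}
  w_k \, \frac{[x \text{ matches } t \text{ at } k]}{|T(x, k)|},$$

where `I_r` are the read's k-mer occurrences and `T(x, k)` the set of taxa
matched by `x` at length k. The denominator is deliberately the
*per-(k-mer, k)* matched-taxa set: an occurrence shared by three taxa gives
each a third, which keeps the score consistent with the profiling rule
below (the printed-formula alternative — one global matched-taxa set per
run — would let a taxon matched by an unrelated read dilute every other
score). The Relative Score then normalizes for read length and for how
generic a taxon is:

$$\mathrm{RelScore}(t, r) = \frac{\mathrm{Score}(t, r)}
  {1 + \log_2(\mathrm{length}(r) \cdot \mathrm{frequency}(t))},$$

with `frequency(t)` the taxon's total entry count in the index. Output rows
per read are sorted by decreasing Relative Score, ties broken by ascending
tax_id for determinism. A significance filter (0.4 is the conventional
cutoff for reads of length 100) is available but never applied silently.

## Profiling

Profiles aggregate the same match table per k — read scoring can be skipped
entirely. With `c(v, k)` the occurrence count of input k-mer prefix `v` and
`T(v, k)` its matched taxa:

* unique relative frequency `h_u`: occurrences matched by `t` alone,
  divided by all uniquely matched occurrences;
* non-unique relative frequency `h`: each occurrence contributes
  `c/|T|` to every matched taxon (a k-mer hit five times in three taxa adds
  5/3 to each), divided by all matched occurrences — so `h` sums to 1
  whenever anything matched;
* overall relative frequency: the same numerator divided by *all* input
  occurrences at that k, which stays honest when much of the input is
  unknown to the index.

Counts are occurrences, not distinct k-mers, matching the 5/3 rule. At a k
with no matches all frequencies are reported as 0, never NaN. Profiles
carry one column group per k: no single k is best for every dataset, and a
taxon prominent only at smaller k would be invisible in a maximum-k-only
profile.

The package also reports an ambiguity value guiding the choice between
`h_u` and `h`: `(N - D)/N` with `N` entries and `D` distinct k-mers — 0
when no k-mer is shared, 0.5 when every k-mer belongs to two taxa. The
underlying method names such a value without printing a formula; this
definition is this package's own and is only meant to rank indices by
redundancy. A low-frequency cutoff (`apply_cutoff()`, conventionally 0.01)
drops taxa without renormalizing the survivors, so reported values stay
interpretable.

## The synthetic benchmark

`sample_genomes()` draws i.i.d. uniform ACGT genomes, one per taxon, under
a flat species-level taxonomy; `sample_reads()` samples fixed-length reads
(default 100 nt) with uniform genome choice and start position, forward
strand by default; `mutate_reads()` substitutes each base independently
with probability `p`, always to a *different* base — a Bernoulli-per-base
reading of a stated "mutation percentage", the simplest seedable model
consistent with it. Evaluation takes each read's top-ranked taxon: a
correct call is a TP, a wrong call counts as both FP and FN, an
unclassified read as FN only; sensitivity `TP/(TP+FN)`, precision
`TP/(TP+FP)`, F1 their harmonic mean, undefined ratios reported as 0 —
the standard per-read multiclass convention.

What the generator emulates: several clearly distinct reference genomes,
uniform read coverage, and substitution noise up to 20%. What it does not:
real genome composition and repeats, homology shared between related taxa,
indels, or quality-correlated error profiles. Passing benchmarks therefore
demonstrates the mechanics of multi-k matching under substitution noise —
recovery of a signal that is present — not performance on real communities,
where shared sequence between taxa moves weight from `h_u` to `h` and
classification to higher k.

The packaged study conditions — three 50 kb genomes, 3000 reads of length
100, mutation rates 0/5/10/15% — are what the tests and the acceptance
script run. At these sizes random 12-letter collisions between taxa are
vanishingly rare, so perfect reads classify perfectly (F1 = 1 at rate 0),
F1 decays with the mutation rate, and the k range `[7, 12]` dominates a
fixed `k = 12`, which loses entire reads once every 36 nt window is likely
to contain a mutation.

## Degenerate inputs and numerical choices

* Reads too short to yield a single k-mer in any frame (below about
  `3 k_lower + 2` nt) produce no pairs and are counted as unclassified.
* Empty pair lists, empty match tables and empty indices flow through and
  yield empty results or zero frequencies; the ambiguity of an empty index
  is 0.
* All randomness (genomes, reads, mutations, lossy deletion) is behind
  explicit seeds; lossy deletion records its seed in the index metadata.
* Ties anywhere are broken deterministically (ascending tax_id; stable
  radix sorts).

## Limitations

Single-threaded; no paired-end awareness, quality use, or LCA
reassignment of multi-matched reads; no gapped matching (robustness to
indels is out of scope); no compression beyond the lossless halving; the
toy-taxonomy TSV readers deliberately do not parse NCBI `names.dmp` /
`nodes.dmp` dumps. The CLI accepts multi-valued flags comma-separated
(`--k 7,12`), a constraint of the option parser used.
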