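# Per-k taxonomic profiles: unique, non-unique and overall relative
# frequencies aggregated from the match table, plus the index ambiguity
# value and the recommended low-frequency cutoff.

#' Taxonomic profile from a match table
#'
#' For every k in the match range and taxon `t`:
#' * `unique_count` — occurrences of input k-mers matched by `t` alone;
#' * `h_u` — `unique_count` divided by all uniquely matched occurrences;
#' * `nonunique_weight` — every matched occurrence contributes `1/|T|` to
#'   each of its `|T|` matched taxa (a k-mer hit five times in three taxa
#'   adds 5/3 to each);
#' * `h` — `nonunique_weight` divided by all matched occurrences;
#' * `overall` — `nonunique_weight` divided by *all* input k-mer
#'   occurrences at that k, guarding against over-interpretation when much
#'   of the input is unknown to the index.
#'
#' Occurrences are counted per input k-mer occurrence, not per distinct
#' k-mer. At a k with no matches all frequencies are 0, not NaN. Scoring of
#' reads is not needed: profiling consumes the match table directly.
#'
#' @param matches An `aak_matches` from [match_pairs()] (or an
#'   `aak_identification`, whose match table is used).
#' @param index The `aak_index` the matches were computed against.
#' @return A tibble of class `aak_profile`, one row per (taxon, k), columns
#'   `tax_id`, `name`, `k`, `unique_count`, `nonunique_weight`, `h_u`, `h`,
#'   `overall`.
#' @export
taxonomic_profile <- function(matches, index) {
  if (inherits(matches, "aak_identification")) matches <- matches$matches
  ks <- matches$k_lower:matches$k_upper
  hits <- matches$hits
  empty <- tibble(tax_id = integer(), name = character(), k = integer(),
                  unique_count = integer(), nonunique_weight = double(),
                  h_u = double(), h = double(), overall = double())
  if (nrow(hits) == 0) {
    return(structure(empty, class = c("aak_profile", class(empty)),
                     k_range = range(ks)))
  }
  # per-(k, k-mer prefix, taxon): total occurrence count across reads
  ph <- hits |>
    group_by(.data$k, .data$prefix, .data$line) |>
    summarise(c = sum(.data$occ), n_taxa = .data$n_taxa[1], .groups = "drop")

  per_taxon <- ph |>
    group_by(.data$k, .data$line) |>
    summarise(
      unique_count = sum(.data$c[.data$n_taxa == 1L]),
      nonunique_weight = sum(.data$c / .data$n_taxa),
      .groups = "drop"
    )
  totals <- ph |>
    distinct(.data$k, .data$prefix, .keep_all = TRUE) |>
    group_by(.data$k) |>
    summarise(total_matched = sum(.data$c),
              total_unique = sum(.data$c[.data$n_taxa == 1L]),
              .groups = "drop")

  prof <- per_taxon |>
    tidyr::complete(k = ks, line = unique(per_taxon$line),
                    fill = list(unique_count = 0L, nonunique_weight = 0)) |>
    left_join(totals, by = "k") |>
    left_join(matches$input_totals, by = "k") |>
    mutate(
      h_u = ifelse(is.na(.data$total_unique) | .data$total_unique == 0, 0,
                   .data$unique_count / .data$total_unique),
      h = ifelse(is.na(.data$total_matched) | .data$total_matched == 0, 0,
                 .data$nonunique_weight / .data$total_matched),
      overall = ifelse(.data$n_input == 0, 0,
                       .data$nonunique_weight / .data$n_input),
      tax_id = index$content$tax_id[.data$line],
      name = index$content$name[.data$line]
    ) |>
    select("tax_id", "name", "k", "unique_count", "nonunique_weight",
           "h_u", "h", "overall") |>
    arrange(.data$k, .data$tax_id)
  structure(prof, class = c("aak_profile", class(empty)),
            k_range = range(ks))
}

#' Ambiguity value of an index
#'
#' A single number describing the degree of redundancy in the index:
#' `(N - D) / N`, where `N` is the number of (k-mer, taxon) entries and `D`
#' the number of distinct k-mers. 0 means no k-mer is shared between taxa;
#' an index where every k-mer is carried by exactly two taxa scores 0.5.
#' High ambiguity is a hint to prefer the non-unique over the unique
#' relative frequency.
#'
#' @param index An `aak_index`.
#' @return A number in `[0, 1)`; 0 for an empty index.
#' @export
ambiguity_value <- function(index) {
  n <- nrow(index$entries)
  if (n == 0) return(0)
  (n - dplyr::n_distinct(index$entries$key)) / n
}

#' Drop low-frequency taxa from a profile
#'
#' Removes taxa whose selected relative frequency at the selected k falls
#' below the threshold (0.01 is the conventional choice for species-level
#' profiles). Remaining values are deliberately not renormalized so they
#' stay interpretable.
#'
#' @param profile An `aak_profile`.
#' @param threshold Non-negative cutoff.
#' @param on Which frequency to threshold: `"nonunique"` (`h`), `"unique"`
#'   (`h_u`) or `"overall"`.
#' @param k The k at which to apply the cutoff; defaults to the largest k
#'   in the profile.
#' @return The filtered `aak_profile` (all k rows of surviving taxa).
#' @export
apply_cutoff <- function(profile, threshold,
                         on = c("nonunique", "unique", "overall"),
                         k = NULL) {
  if (threshold < 0) abort("`threshold` must be >= 0")
  on <- match.arg(on)
  col <- switch(on, nonunique = "h", unique = "h_u", overall = "overall")
  k <- k %||% max(profile$k)
  at_k <- profile[profile$k == k, ]
  keep <- at_k$tax_id[at_k[[col]] >= threshold]
  out <- profile[profile$tax_id %in% keep, ]
  if (nrow(out) == 0) warn("cutoff removed every taxon from the profile")
  out
}

#' Write a profile as a TSV with one column group per k
#'
#' @param profile An `aak_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  wide <- profile |>
    tidyr::pivot_wider(
      id_cols = c("tax_id", "name"),
      names_from = "k",
      values_from = c("unique_count", "nonunique_weight", "h_u", "h", "overall"),
      names_glue = "{.value}_k{k}"
    )
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a taxonomic profile
#'
#' Bar chart of a chosen relative frequency per taxon, faceted by k.
#'
#' @param object An `aak_profile`.
#' @param on Frequency to plot: `"h"`, `"h_u"` or `"overall"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.aak_profile <- function(object, on = c("h", "h_u", "overall"), ...) {
  on <- match.arg(on)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$name, -.data[[on]]),
                               y = .data[[on]])) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = switch(on,
                                       h = "non-unique relative frequency",
                                       h_u = "unique relative frequency",
                                       overall = "overall relative frequency")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
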