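#' AT skew
#'
#' `(A - T) / (A + T)`: the strand-asymmetry statistic of adenine versus
#' thymine content. Scale-invariant, so counts and percentages give the same
#' value; flips sign under reverse complementation.
#'
#' @param freq_a,freq_t Counts or percentages of A and T.
#' @return Skew in `[-1, 1]`; `NA` when `A + T = 0` (with a warning).
#' @examples
#' at_skew(31.84, 25.53) # 0.1100... (protein-coding-gene-scale skew)
#' @export
at_skew <- function(freq_a, freq_t) {
  denom <- freq_a + freq_t
  if (any(denom <= 0)) {
    warn("at_skew undefined: A + T = 0", class = "mitochar_skew_warning")
  }
  ifelse(denom > 0, (freq_a - freq_t) / denom, NA_real_)
}

#' GC skew
#'
#' `(G - C) / (G + C)`, the guanine/cytosine analogue of [at_skew()].
#'
#' @param freq_g,freq_c Counts or percentages of G and C.
#' @return Skew in `[-1, 1]`; `NA` when `G + C = 0` (with a warning).
#' @export
gc_skew <- function(freq_g, freq_c) {
  denom <- freq_g + freq_c
  if (any(denom <= 0)) {
    warn("gc_skew undefined: G + C = 0", class = "mitochar_skew_warning")
  }
  ifelse(denom > 0, (freq_g - freq_c) / denom, NA_real_)
}

#' Base composition of a sequence
#'
#' Counts A/C/G/T with N excluded from numerator and denominator; percentages
#' and skews are computed from the unrounded counts (display rounding is the
#' caller's concern; see [composition_report()]).
#'
#' @param seq DNA string.
#' @param label Row label.
#' @return A one-row tibble: `label`, `pct_a`, `pct_c`, `pct_g`, `pct_t`,
#'   `pct_at`, `at_skew`, `gc_skew`, `length_bp`, plus raw counts `n_a`,
#'   `n_c`, `n_g`, `n_t`, `n_n`.
#' @export
base_composition <- function(seq, label = "sequence") {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) {
    abort("base_composition: empty sequence", class = "mitochar_validation_error")
  }
  counts <- vapply(c("A", "C", "G", "T", "N"), function(b) {
    sum(charToRaw(seq) == charToRaw(b))
  }, integer(1))
  total <- sum(counts[c("A", "C", "G", "T")])
  if (total == 0L) {
    abort("base_composition: sequence is all N", class = "mitochar_validation_error")
  }
  pct <- 100 * counts[c("A", "C", "G", "T")] / total
  tibble(
    label = label,
    pct_a = pct[["A"]], pct_c = pct[["C"]], pct_g = pct[["G"]],
    pct_t = pct[["T"]],
    pct_at = pct[["A"]] + pct[["T"]],
    at_skew = at_skew(counts[["A"]], counts[["T"]]),
    gc_skew = gc_skew(counts[["G"]], counts[["C"]]),
    length_bp = nchar(seq),
    n_a = counts[["A"]], n_c = counts[["C"]], n_g = counts[["G"]],
    n_t = counts[["T"]], n_n = counts[["N"]]
  )
}

#' Composition report for an annotated mitogenome
#'
#' Rows for the whole genome, pooled rRNA, each rRNA, pooled protein-coding
#' genes, each PCG, and pooled tRNA. Every row is computed on the coding
#' strand: L-strand genes (e.g. ND6) are reverse-complemented first, which is
#' why their skews come out with inverted sign relative to H-strand genes.
#' Pooled rows concatenate the coding-strand gene sequences, so overlapping
#' genome positions count once per gene (the pooled PCG length is the plain
#' sum of gene lengths).
#'
#' @param genome A [mitogenome()] object.
#' @param digits_pct,digits_skew Display rounding (half-up) applied to the
#'   `pct_*` and `*_skew` columns; raw counts are kept alongside. Use
#'   `NULL` to skip rounding.
#' @return A tibble of composition rows (see [base_composition()]).
#' @export
composition_report <- function(genome, digits_pct = 2, digits_skew = 4) {
  stopifnot(inherits(genome, "mitogenome"))
  feat <- genome$features
  seq_of <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) extract_feature(genome, rows[i, ]),
           character(1))
  }
  rows <- list(base_composition(genome$sequence, "whole genome"))
  pool <- function(category, label) {
    sub <- feat[feat$category == category, ]
    if (nrow(sub) == 0L) return(NULL)
    seqs <- seq_of(sub)
    c(list(base_composition(paste(seqs, collapse = ""), label)),
      if (category != "tRNA") {
        purrr::map2(seqs, sub$name, base_composition)
      })
  }
  rows <- c(rows, pool("rRNA", "ribosomal RNA"),
            pool("PCG", "protein-coding genes"),
            pool("tRNA", "transfer RNA"))
  out <- bind_rows(rows)
  if (!is.null(digits_pct)) {
    out <- mutate(out, across(dplyr::starts_with("pct_"),
                              ~ round_half_up(.x, digits_pct)))
  }
  if (!is.null(digits_skew)) {
    out <- mutate(out, across(dplyr::ends_with("_skew"),
                              ~ round_half_up(.x, digits_skew)))
  }
  out
}

#' Recompute skews from a printed composition table
#'
#' Verification entry point for published tables: takes the rounded
#' percentages as printed and recomputes AT/GC skew at the table's own display
#' rounding. Kept separate from [composition_report()] because a skew computed
#' from raw counts and one computed from 1-dp-rounded percentages can differ
#' in the 4th decimal - provenance must be explicit.
#'
#' @param printed A tibble with columns `pct_a`, `pct_c`, `pct_g`, `pct_t`
#'   (printed percentages) and any label columns.
#' @param digits_skew Half-up rounding applied to the recomputed skews.
#' @return `printed` with columns `at_skew_recomputed`, `gc_skew_recomputed`.
#' @export
skews_from_percentages <- function(printed, digits_skew = 4) {
  printed |>
    mutate(
      at_skew_recomputed =
        round_half_up(at_skew(.data$pct_a, .data$pct_t), digits_skew),
      gc_skew_recomputed =
        round_half_up(gc_skew(.data$pct_g, .data$pct_c), digits_skew)
    )
}

#' Codon usage and RSCU over a set of coding sequences
#'
#' Counts codons in frame (frame fixed at base 1 of each CDS); incomplete
#' trailing codons, as left by `T--`/`TA-` incomplete stops, are ignored.
#' Relative synonymous codon usage (RSCU) is each codon's count divided by the
#' mean count over its synonymous family, so a uniformly used family has RSCU
#' 1 for all members. Stop codons form their own family and are tallied but
#' given no RSCU. An in-frame internal stop raises a warning naming the
#' sequence and codon position.
#'
#' @param cds_list Named character vector (or list) of strand-oriented CDSs.
#' @param code Genetic code.
#' @return A tibble `codon`, `amino_acid`, `count`, `rscu` covering all 64
#'   codons.
#' @export
codon_usage <- function(cds_list, code = mito_genetic_code()) {
  cds_list <- unlist(cds_list)
  counts <- setNames(integer(length(code$map)), names(code$map))
  nm <- names(cds_list) %||% paste0("cds", seq_along(cds_list))
  for (k in seq_along(cds_list)) {
    codons <- split_codons(toupper(cds_list[[k]]))
    codons <- codons[grepl("^[ACGT]{3}$", codons)]
    if (length(codons) == 0L) next
    internal_stop <- which(codons %in% code$stops & seq_along(codons) < length(codons))
    if (length(internal_stop)) {
      warn(paste0(nm[k], ": in-frame internal stop codon at codon position ",
                  internal_stop[1]),
           class = "mitochar_internal_stop_warning")
    }
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- tibble(
    codon = names(counts),
    amino_acid = unname(code$map[names(counts)]),
    count = unname(counts)
  )
  out |>
    group_by(.data$amino_acid) |>
    mutate(rscu = dplyr::if_else(
      .data$amino_acid == "*" | sum(.data$count) == 0,
      NA_real_,
      .data$count / mean(.data$count)
    )) |>
    ungroup() |>
    arrange(.data$amino_acid, .data$codon)
}

#' Codon usage for an annotated mitogenome
#'
#' Extracts all PCGs on their coding strands and tallies [codon_usage()].
#'
#' @inheritParams composition_report
#' @param code Genetic code.
#' @return See [codon_usage()].
#' @export
genome_codon_usage <- function(genome, code = mito_genetic_code()) {
  stopifnot(inherits(genome, "mitogenome"))
  pcg <- genome$features[genome$features$category == "PCG", ]
  seqs <- setNames(
    vapply(seq_len(nrow(pcg)), function(i) extract_feature(genome, pcg[i, ]),
           character(1)),
    pcg$name
  )
  codon_usage(seqs, code)
}
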