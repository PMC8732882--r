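#' Gene length from closed 1-based coordinates
#'
#' @param from,to 1-based inclusive coordinates (vectorized).
#' @return `to - from + 1`.
#' @examples
#' gene_length(7759, 7959) # ATP8-style 201 bp
#' @export
gene_length <- function(from, to) {
  as.integer(to) - as.integer(from) + 1L
}

#' Intergenic nucleotides between consecutive features
#'
#' In table order, the value for feature i (i >= 2) is
#' `from(i) - to(i-1) - 1`: positive for a spacer, negative for an overlap,
#' zero for abutting genes. The first feature gets 0 by convention. Computed
#' over H-strand coordinates regardless of strand, which is the convention
#' mitogenome tables print.
#'
#' @param features Feature tibble in table order.
#' @return Integer vector, one value per feature.
#' @export
intergenic_nucleotides <- function(features) {
  if (nrow(features) == 0L) return(integer(0))
  c(0L, features$from[-1L] - features$to[-nrow(features)] - 1L)
}

#' Detect a coding sequence's start codon
#'
#' @param cds Strand-oriented (5'->3') coding sequence, length >= 3.
#' @param code Genetic code, as from [mito_genetic_code()].
#' @return A list with `codon` (first triplet) and `is_atn` (does it belong to
#'   the code's ATN start set?).
#' @export
detect_start_codon <- function(cds, code = mito_genetic_code()) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) {
    abort("coding sequence shorter than 3 nt", class = "mitochar_validation_error")
  }
  codon <- substr(cds, 1L, 3L)
  list(codon = codon, is_atn = codon %in% code$starts)
}

#' Classify a coding sequence's stop codon
#'
#' Vertebrate mitochondrial PCGs may end in a complete stop triplet (TAA, TAG,
#' AGA, AGG) or in an incomplete stop - a trailing `T` (reported `"T--"`) or
#' `TA` (reported `"TA-"`) completed to UAA by post-transcriptional
#' polyadenylation. The reading frame starts at base 1, so `length mod 3`
#' decides which case applies; trailing bases inconsistent with it raise an
#' annotation-inconsistency error.
#'
#' @param cds Strand-oriented coding sequence.
#' @param code Genetic code.
#' @param gene Gene name used in error messages.
#' @return One of `"TAA"`, `"TAG"`, `"AGA"`, `"AGG"`, `"T--"`, `"TA-"`.
#' @export
classify_stop_codon <- function(cds, code = mito_genetic_code(), gene = "CDS") {
  cds <- toupper(cds)
  n <- nchar(cds)
  rem <- n %% 3L
  if (rem == 0L) {
    last3 <- substr(cds, n - 2L, n)
    if (!last3 %in% code$stops) {
      abort(paste0(gene, ": length is a codon multiple but final triplet '",
                   last3, "' is not a stop codon"),
            class = "mitochar_annotation_error")
    }
    return(last3)
  }
  if (rem == 1L) {
    if (substr(cds, n, n) != "T") {
      abort(paste0(gene, ": length mod 3 = 1 but trailing base '",
                   substr(cds, n, n), "' is not T"),
            class = "mitochar_annotation_error")
    }
    return("T--")
  }
  if (substr(cds, n - 1L, n) != "TA") {
    abort(paste0(gene, ": length mod 3 = 2 but trailing bases '",
                 substr(cds, n - 1L, n), "' are not TA"),
          class = "mitochar_annotation_error")
  }
  "TA-"
}

#' Build the characterization table of an annotated mitogenome
#'
#' One row per feature in table order, with the columns mitogenome
#' announcement tables print: coordinates, length, anticodon, start and stop
#' codon (PCGs only; stop may be the incomplete `"T--"`/`"TA-"`), intergenic
#' nucleotides relative to the previous feature (negative = overlap), and
#' strand. Non-ATN start codons generate a warning, not an error (other taxa
#' may violate the ATN rule); stop codons inconsistent with the reading frame
#' are errors.
#'
#' @param genome A [mitogenome()] object.
#' @param code Genetic code.
#' @return A tibble with columns `name`, `category`, `from`, `to`,
#'   `length_bp`, `anticodon`, `start_codon`, `stop_codon`, `intergenic`,
#'   `strand`, plus attributes `genome_length` (max `to`) and `circular_gap`
#'   (wrap-around spacer from the last feature to the first, for circular
#'   genomes).
#' @export
characterize <- function(genome, code = mito_genetic_code()) {
  stopifnot(inherits(genome, "mitogenome"))
  feat <- genome$features
  start_codon <- rep(NA_character_, nrow(feat))
  stop_codon <- rep(NA_character_, nrow(feat))
  for (i in which(feat$category == "PCG")) {
    cds <- extract_feature(genome, feat[i, ])
    st <- detect_start_codon(cds, code)
    if (!st$is_atn) {
      warn(paste0(feat$name[i], ": non-ATN start codon '", st$codon, "'"),
           class = "mitochar_start_codon_warning")
    }
    start_codon[i] <- st$codon
    stop_codon[i] <- classify_stop_codon(cds, code, gene = feat$name[i])
  }
  out <- tibble(
    name = feat$name,
    category = feat$category,
    from = feat$from,
    to = feat$to,
    length_bp = gene_length(feat$from, feat$to),
    anticodon = feat$anticodon,
    start_codon = start_codon,
    stop_codon = stop_codon,
    intergenic = intergenic_nucleotides(feat),
    strand = feat$strand
  )
  attr(out, "genome_length") <- max(feat$to)
  attr(out, "circular_gap") <- if (genome$circular && nrow(feat) > 0L) {
    nchar(genome$sequence) - max(feat$to) + min(feat$from) - 1L
  } else {
    NA_integer_
  }
  out
}

#' Characterization-table arithmetic from coordinates alone
#'
#' The coordinate-derived columns of [characterize()] (length, intergenic)
#' without needing the sequence - useful for checking a printed annotation
#' table's internal arithmetic.
#'
#' @param features Feature tibble in table order.
#' @return A tibble `name`, `category`, `from`, `to`, `length_bp`,
#'   `intergenic`, `strand`.
#' @export
characterize_coordinates <- function(features) {
  features <- validate_features(as_tibble(features))
  tibble(
    name = features$name,
    category = features$category,
    from = features$from,
    to = features$to,
    length_bp = gene_length(features$from, features$to),
    intergenic = intergenic_nucleotides(features),
    strand = features$strand
  )
}

#' Feature counts by category and strand
#'
#' @param features Feature tibble.
#' @return A tibble `category`, `strand`, `n` covering all category/strand
#'   combinations (zeros included).
#' @export
count_by_strand_and_category <- function(features) {
  grid <- tidyr::expand_grid(
    category = FEATURE_CATEGORIES,
    strand = c("H", "L")
  )
  if (nrow(features) == 0L) return(mutate(grid, n = 0L))
  counts <- features |>
    group_by(.data$category, .data$strand) |>
    summarise(n = dplyr::n(), .groups = "drop")
  grid |>
    left_join(counts, by = c("category", "strand")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Write a characterization table as TSV
#'
#' Serializes with the printed-table column set (Gene, From, To, Length,
#' Anticodon, Start, Stop, Intergenic, Strand).
#'
#' @param table1 Output of [characterize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_characterization_table <- function(table1, path) {
  out <- data.frame(
    Gene = table1$name, From = table1$from, To = table1$to,
    Length = table1$length_bp,
    Anticodon = ifelse(is.na(table1$anticodon), "", table1$anticodon),
    Start = ifelse(is.na(table1$start_codon), "", table1$start_codon),
    Stop = ifelse(is.na(table1$stop_codon), "", table1$stop_codon),
    Intergenic = table1$intergenic, Strand = table1$strand,
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
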