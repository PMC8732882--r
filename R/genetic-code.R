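#' The vertebrate mitochondrial genetic code
#'
#' Returns the codon table used throughout the package: the vertebrate
#' mitochondrial code (NCBI translation table 2), in which AGA/AGG are stop
#' codons, TGA codes tryptophan, ATA codes methionine, and any ATN triplet can
#' serve as a start codon.
#'
#' @return A list with elements `id` ("2"), `map` (named character vector of
#'   64 codons to one-letter amino acids, `"*"` for stops), `starts` (the ATN
#'   start set: ATG, ATA, ATT, ATC) and `stops` (TAA, TAG, AGA, AGG).
#' @examples
#' code <- mito_genetic_code()
#' code$map[["TGA"]] # "W", not a stop in this code
#' @export
mito_genetic_code <- function() {
  map <- Biostrings::getGeneticCode("2")
  map <- setNames(as.character(map), names(map))
  stops <- sort(names(map)[map == "*"])
  list(
    id = "2",
    map = map,
    starts = c("ATG", "ATA", "ATT", "ATC"),
    stops = stops
  )
}

# three-letter amino-acid labels for reports (Fig.-2-style tRNA naming)
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a strand-oriented coding sequence
#'
#' Translates complete codons under the vertebrate mitochondrial code;
#' trailing incomplete codons (1-2 nt, as left by incomplete stop codons) are
#' ignored. Codons containing N translate to `X`.
#'
#' @param cds A strand-oriented DNA string.
#' @param code A genetic code, as from [mito_genetic_code()].
#' @return A character string of one-letter amino acids (`*` = stop).
#' @export
translate_cds <- function(cds, code = mito_genetic_code()) {
  codons <- split_codons(toupper(cds))
  aa <- unname(code$map[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
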