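#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and U is normalized to T. Characters outside
#' `{A, C, G, T, N}` (after normalization) and duplicate record ids are
#' rejected with an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path), class = "mitochar_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("failed to parse FASTA '", path, "': ", conditionMessage(e)),
            class = "mitochar_parse_error")
    }
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records"),
          class = "mitochar_parse_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]),
          class = "mitochar_parse_error")
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    abort(
      paste0("record '", ids[i], "' contains illegal character(s): ",
             paste(unique(strsplit(bad[i], "")[[1]]), collapse = ", ")),
      class = "mitochar_parse_error"
    )
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id`, `sequence` (as from [read_fasta()]),
#'   or a named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- tibble(id = names(x), sequence = unname(x))
  lines <- character(0)
  for (i in seq_len(nrow(x))) {
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    lines <- c(lines, paste0(">", x$id[i]),
               substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control")

validate_features <- function(feat, context = "feature table") {
  required <- c("name", "category", "from", "to", "anticodon", "strand")
  missing <- setdiff(required, names(feat))
  if (length(missing)) {
    abort(paste0(context, " lacks column(s): ", paste(missing, collapse = ", ")),
          class = "mitochar_validation_error")
  }
  for (i in seq_len(nrow(feat))) {
    row <- feat[i, ]
    where <- paste0(context, " row ", i, " ('", row$name, "')")
    if (is.na(row$from) || is.na(row$to)) {
      abort(paste0(where, ": non-integer coordinates"),
            class = "mitochar_validation_error")
    }
    if (row$to < row$from) {
      abort(paste0(where, ": end (", row$to, ") < start (", row$from, ")"),
            class = "mitochar_validation_error")
    }
    if (row$from < 1L) {
      abort(paste0(where, ": coordinates must be >= 1"),
            class = "mitochar_validation_error")
    }
    if (!row$strand %in% c("H", "L")) {
      abort(paste0(where, ": unknown strand '", row$strand, "'"),
            class = "mitochar_validation_error")
    }
    if (!row$category %in% FEATURE_CATEGORIES) {
      abort(paste0(where, ": unknown category '", row$category, "'"),
            class = "mitochar_validation_error")
    }
    if (!is.na(row$anticodon)) {
      if (row$category != "tRNA") {
        abort(paste0(where, ": anticodon given for non-tRNA feature"),
              class = "mitochar_validation_error")
      }
      if (!grepl("^[ACGU]{3}$", row$anticodon)) {
        abort(paste0(where, ": anticodon '", row$anticodon,
                     "' is not a 5'->3' triplet over A/C/G/U"),
              class = "mitochar_validation_error")
      }
    }
  }
  if (anyDuplicated(feat$name)) {
    abort(paste0(context, ": duplicate feature name '",
                 feat$name[duplicated(feat$name)][1], "'"),
          class = "mitochar_validation_error")
  }
  invisible(feat)
}

#' Read a mitogenome feature table
#'
#' Reads a tab-separated annotation table with header columns `name`,
#' `category`, `from`, `to`, `anticodon`, `strand` (extra columns are kept).
#' Coordinates are 1-based, fully closed intervals on the H strand, exactly as
#' annotation tables print them. `.` or empty marks a missing anticodon.
#'
#' @param path Path to the TSV file.
#' @return A tibble of features in file order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("feature table does not exist: ", path),
          class = "mitochar_io_error")
  }
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  feat <- as_tibble(raw)
  for (col in c("from", "to")) {
    if (!col %in% names(feat)) next
    v <- suppressWarnings(as.integer(feat[[col]]))
    bad <- which(is.na(v) & nzchar(feat[[col]]))
    if (length(bad)) {
      abort(paste0("feature table row ", bad[1], ": non-integer '", col,
                   "' value '", feat[[col]][bad[1]], "'"),
            class = "mitochar_validation_error")
    }
    feat[[col]] <- v
  }
  blank_to_na <- function(x) ifelse(x %in% c("", "."), NA_character_, x)
  for (col in setdiff(names(feat), c("from", "to"))) {
    feat[[col]] <- blank_to_na(feat[[col]])
  }
  validate_features(feat)
  feat
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: `read_feature_table(write_feature_table(x, p))`
#' returns `x` for valid feature tibbles. Missing anticodons serialize as `.`.
#'
#' @param features A feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- as.data.frame(features)
  for (col in names(out)) {
    if (is.character(out[[col]])) out[[col]][is.na(out[[col]])] <- "."
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a mitogenome object
#'
#' Bundles a (typically circular) mitochondrial sequence with its ordered
#' feature annotation. Features must lie within `[1, nchar(sequence)]`;
#' wrap-around features are not supported and are rejected.
#'
#' @param id Genome label.
#' @param sequence DNA string over `{A,C,G,T,N}` (lowercase and U accepted and
#'   normalized).
#' @param features Feature tibble (see [read_feature_table()]).
#' @param circular Is the molecule circular? Recorded, used for the
#'   wrap-around gap report in [characterize()].
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, features, circular = TRUE) {
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (nchar(sequence) < 1L) {
    abort("sequence must have length >= 1", class = "mitochar_validation_error")
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    abort(paste0("sequence contains illegal character(s): ",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
          class = "mitochar_validation_error")
  }
  features <- validate_features(as_tibble(features))
  if (any(features$to > nchar(sequence))) {
    off <- features$name[features$to > nchar(sequence)][1]
    abort(paste0("feature '", off, "' extends beyond the sequence end (",
                 nchar(sequence), " bp); wrap-around features are not supported"),
          class = "mitochar_validation_error")
  }
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         features = features),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  counts <- table(factor(x$features$category, levels = FEATURE_CATEGORIES))
  cat("<mitogenome> ", x$id, ": ", nchar(x$sequence), " bp",
      if (x$circular) " (circular)", "\n", sep = "")
  cat("  features: ", paste0(counts, " ", names(counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' N maps to N; the operation is an involution.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @examples
#' reverse_complement("ATGC") # "GCAT"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (nzchar(gsub("[ACGTN]", "", seq))) {
    abort("reverse_complement: sequence contains characters outside {A,C,G,T,N}",
          class = "mitochar_validation_error")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a feature's strand-oriented sequence
#'
#' Returns the H-strand substring `[from, to]`; for L-strand features the
#' reverse complement, i.e. the feature read 5'->3' on its coding strand.
#'
#' @param genome A [mitogenome()] object (or a bare DNA string).
#' @param feature A one-row feature tibble, or a list with `from`, `to`,
#'   `strand`.
#' @return A DNA string of length `to - from + 1`.
#' @export
extract_feature <- function(genome, feature) {
  seq <- if (inherits(genome, "mitogenome")) genome$sequence else toupper(genome)
  from <- as.integer(feature$from)
  to <- as.integer(feature$to)
  if (is.na(from) || is.na(to) || from < 1L || to > nchar(seq) || to < from) {
    abort(paste0("feature out of bounds: [", from, ", ", to,
                 "] on a ", nchar(seq), " bp sequence"),
          class = "mitochar_validation_error")
  }
  s <- substr(seq, from, to)
  if (identical(feature$strand, "L")) reverse_complement(s) else s
}
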