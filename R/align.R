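ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a DNA alignment
#'
#' An alignment is a character matrix over `{A,C,G,T,-,N}` with unique taxon
#' rownames and equal-length rows. Accepts a named character vector of
#' equal-length aligned strings or a character matrix; lowercase and U are
#' normalized. IUPAC ambiguity codes other than N are rejected.
#'
#' @param x Named character vector of aligned sequences, or character matrix.
#' @return A `dna_alignment` (character matrix subclass).
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) {
      abort("aligned sequences must be named by taxon",
            class = "mitochar_validation_error")
    }
    if (length(unique(nchar(x))) > 1L) {
      abort("aligned rows differ in length", class = "mitochar_validation_error")
    }
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
  } else if (is.matrix(x)) {
    mat <- toupper(x)
    if (is.null(rownames(mat))) {
      abort("alignment matrix must have taxon rownames",
            class = "mitochar_validation_error")
    }
  } else {
    abort("cannot interpret input as an alignment",
          class = "mitochar_validation_error")
  }
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad)) {
    abort(paste0("alignment contains unsupported character(s): ",
                 paste(bad, collapse = ", "),
                 " (only N is accepted as ambiguity)"),
          class = "mitochar_validation_error")
  }
  if (anyDuplicated(rownames(mat))) {
    abort("duplicate taxon names in alignment",
          class = "mitochar_validation_error")
  }
  structure(mat, class = c("dna_alignment", class(matrix())))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> ", nrow(x), " taxa x ", ncol(x), " sites\n", sep = "")
  show <- pmin(ncol(x), 60L)
  for (i in seq_len(min(nrow(x), 10L))) {
    cat(sprintf("  %-20s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(show)], collapse = ""),
                if (ncol(x) > show) "..." else ""))
  }
  invisible(x)
}

#' @export
as_tibble.dna_alignment <- function(x, ...) {
  tibble(taxon = rownames(x),
         sequence = apply(unclass(x), 1L, paste, collapse = ""))
}

aln_strings <- function(aln) {
  setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Default alignment scoring parameters
#'
#' Match/mismatch and affine gap penalties for the built-in aligner. A gap of
#' length L costs `gap_open + (L - 1) * gap_extend`; end gaps are penalized.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (gap penalties negative).
#' @return A named list.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

# profile = 4 x ncol matrix of A/C/G/T counts (gaps and N contribute nothing)
# plus the number of sequences
profile_of <- function(aln) {
  mat <- unclass(aln)
  cnt <- vapply(c("A", "C", "G", "T"),
                function(b) colSums(mat == b), numeric(ncol(mat)))
  if (ncol(mat) == 1L) cnt <- matrix(cnt, nrow = 1L)
  list(counts = t(cnt), nseq = nrow(mat))
}

# sum-of-pairs expected column score between two profiles, normalized by
# nseq_x * nseq_y; gap/N residues score 0 against everything
profile_score_matrix <- function(px, py, params) {
  cross <- crossprod(px$counts, py$counts) # sum_a fx[a,i] * fy[a,j]
  sx <- colSums(px$counts)
  sy <- colSums(py$counts)
  ((params$match - params$mismatch) * cross +
      params$mismatch * outer(sx, sy)) / (px$nseq * py$nseq)
}

# merge two alignments along a Gotoh path
merge_by_ops <- function(alnx, alny, ops) {
  mx <- unclass(alnx)
  my <- unclass(alny)
  nc <- length(ops)
  out <- matrix("-", nrow(mx) + nrow(my), nc,
                dimnames = list(c(rownames(mx), rownames(my)), NULL))
  xi <- which(ops != 1L) # columns consuming an X column
  yi <- which(ops != 2L)
  out[seq_len(nrow(mx)), xi] <- mx
  out[nrow(mx) + seq_len(nrow(my)), yi] <- my
  dna_alignment(out)
}

align_profiles <- function(alnx, alny, params) {
  S <- profile_score_matrix(profile_of(alnx), profile_of(alny), params)
  res <- .gotoh_align(S, params$gap_open, params$gap_extend)
  out <- merge_by_ops(alnx, alny, res$ops)
  attr(out, "score") <- res$score
  out
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment maximizing
#' `matches * match + mismatches * mismatch + sum(gap costs)` with affine gap
#' costs and penalized end gaps. Tie-breaking is deterministic: the
#' match/mismatch move is preferred over gaps, and a gap in the first sequence
#' over a gap in the second.
#'
#' @param a,b DNA strings (may carry names; defaults `"a"`, `"b"`).
#' @param params Scoring from [align_params()].
#' @return A 2-row `dna_alignment` with attribute `score`.
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  na <- names(a) %||% "a"
  nb <- names(b) %||% "b"
  if (nchar(a) == 0L || nchar(b) == 0L) {
    abort("pairwise_align: empty sequence", class = "mitochar_validation_error")
  }
  ax <- dna_alignment(setNames(gsub("U", "T", toupper(unname(a))), na))
  by <- dna_alignment(setNames(gsub("U", "T", toupper(unname(b))), nb))
  align_profiles(ax, by, params)
}

# k-mer (k-tuple presence) distance between unaligned sequences; crude but
# monotone in divergence at mitogenome-scale identity, used only to order the
# progressive merges
kmer_distance_matrix <- function(seqs, k = 6L) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  m <- length(seqs)
  d <- matrix(0, m, m, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      denom <- min(length(kmers[[i]]), length(kmers[[j]]))
      d[i, j] <- d[j, i] <- if (denom > 0) 1 - shared / denom else 1
    }
  }
  d
}

#' Progressive multiple alignment
#'
#' Builds a UPGMA guide tree from k-mer distances, then merges sequences and
#' profiles by global affine-gap profile alignment in guide-tree order
#' (deepest joins first). Suited to the mitogenome-scale divergences it is
#' used for here; not a general-purpose aligner.
#'
#' @param seqs Named character vector of unaligned DNA sequences (>= 2).
#' @param params Scoring from [align_params()].
#' @param k k-mer size for the guide distances.
#' @return A `dna_alignment` over all input taxa.
#' @export
progressive_align <- function(seqs, params = align_params(), k = 6L) {
  seqs <- unlist(seqs)
  if (length(seqs) < 2L) {
    abort("progressive_align needs >= 2 sequences",
          class = "mitochar_validation_error")
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- setNames(gsub("U", "T", toupper(seqs)), names(seqs))
  if (length(seqs) == 2L) {
    return(pairwise_align(seqs[1], seqs[2], params))
  }
  d <- kmer_distance_matrix(seqs, k)
  guide <- phangorn::upgma(stats::as.dist(d))
  guide <- ape::reorder.phylo(guide, "postorder")
  ntip <- length(guide$tip.label)
  part <- vector("list", ntip + guide$Nnode)
  for (i in seq_len(ntip)) {
    part[[i]] <- dna_alignment(seqs[guide$tip.label[i]])
  }
  for (e in seq_len(nrow(guide$edge))) {
    parent <- guide$edge[e, 1L]
    child <- guide$edge[e, 2L]
    part[[parent]] <- if (is.null(part[[parent]])) {
      part[[child]]
    } else {
      align_profiles(part[[parent]], part[[child]], params)
    }
  }
  root <- ntip + 1L
  out <- part[[root]]
  out[names(seqs), , drop = FALSE] |> dna_alignment()
}

#' Pairwise identity of two aligned rows
#'
#' Percentage of matching positions. By default, columns where either row has
#' a gap or N are excluded from the denominator; set `exclude_gaps = FALSE`
#' to count them as mismatches instead (the definition is stated because
#' published "similarity" figures rarely say which they used).
#'
#' @param a,b Aligned rows: equal-length strings or character vectors.
#' @param exclude_gaps Drop gap/N columns from the denominator?
#' @return Percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, exclude_gaps = TRUE) {
  va <- if (length(a) == 1L) strsplit(toupper(a), "")[[1]] else toupper(a)
  vb <- if (length(b) == 1L) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(va) != length(vb)) {
    abort("aligned rows differ in length", class = "mitochar_validation_error")
  }
  usable <- if (exclude_gaps) {
    !(va %in% c("-", "N")) & !(vb %in% c("-", "N"))
  } else {
    rep(TRUE, length(va))
  }
  if (!any(usable)) {
    abort("pairwise_identity: no usable columns (denominator 0)",
          class = "mitochar_validation_error")
  }
  100 * sum(va[usable] == vb[usable]) / sum(usable)
}

#' Concatenate per-gene alignments
#'
#' Column-wise concatenation of gene blocks sharing the same taxon set, with a
#' partition map recording each gene's column range.
#'
#' @param blocks Named list of `dna_alignment` objects (names = gene names).
#' @return A `dna_alignment` with attribute `partition`: a tibble
#'   `gene`, `start`, `end`.
#' @export
concatenate_genes <- function(blocks) {
  if (length(blocks) == 0L) {
    abort("no gene blocks given", class = "mitochar_validation_error")
  }
  if (is.null(names(blocks))) names(blocks) <- paste0("gene", seq_along(blocks))
  taxa <- sort(rownames(blocks[[1]]))
  for (g in names(blocks)) {
    missing <- setdiff(taxa, rownames(blocks[[g]]))
    extra <- setdiff(rownames(blocks[[g]]), taxa)
    if (length(missing)) {
      abort(paste0("taxon '", missing[1], "' missing from gene block '", g, "'"),
            class = "mitochar_validation_error")
    }
    if (length(extra)) {
      abort(paste0("taxon '", extra[1], "' absent from gene block '",
                   names(blocks)[1], "' but present in '", g, "'"),
            class = "mitochar_validation_error")
    }
  }
  mats <- lapply(blocks, function(b) unclass(b)[taxa, , drop = FALSE])
  widths <- unname(vapply(mats, ncol, integer(1)))
  out <- dna_alignment(do.call(cbind, mats))
  attr(out, "partition") <- tibble(
    gene = names(blocks),
    start = cumsum(c(1L, widths[-length(widths)])),
    end = cumsum(widths)
  )
  out
}
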