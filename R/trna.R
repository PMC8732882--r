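#' Cloverleaf arm-geometry bounds
#'
#' One config block holding the constrained search space for
#' [fold_cloverleaf()], chosen from canonical tRNA architecture. All lengths
#' in nucleotides; stem lengths in base pairs. `spacer1` sits between the
#' acceptor 5' half and the DHU stem, `spacer2` between the DHU arm and the
#' anticodon stem, `tail` after the acceptor 3' half (discriminator + NCCA),
#' and `dhu_connector` replaces the whole DHU arm in degenerate (DHU-less)
#' folds.
#'
#' @param acceptor_bp,dhu_bp,ac_bp,t_bp Stem length ranges (bp).
#' @param dhu_loop,t_loop Loop length ranges; the anticodon loop is fixed at
#'   7 nt with the anticodon at loop positions 3-5.
#' @param spacer1,spacer2,variable,tail,dhu_connector Unpaired-region ranges.
#' @param min_len,max_len Accepted tRNA lengths.
#' @return A named list of integer vectors.
#' @export
cloverleaf_geometry <- function(acceptor_bp = 6:7, spacer1 = 0:3,
                                dhu_bp = 3:4, dhu_loop = 4:11, spacer2 = 0:2,
                                ac_bp = 4:5, variable = 3:23,
                                t_bp = 4:5, t_loop = 4:9, tail = 0:5,
                                dhu_connector = 2:16,
                                min_len = 55L, max_len = 95L) {
  list(acceptor_bp = acceptor_bp, spacer1 = spacer1, dhu_bp = dhu_bp,
       dhu_loop = dhu_loop, spacer2 = spacer2, ac_bp = ac_bp,
       variable = variable, t_bp = t_bp, t_loop = t_loop, tail = tail,
       dhu_connector = dhu_connector,
       min_len = as.integer(min_len), max_len = as.integer(max_len))
}

# Watson-Crick + G.U wobble pairing over DNA alphabet (T read as U)
PAIR_OK <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})
PAIR_WC <- local({
  m <- PAIR_OK
  m["G", "T"] <- m["T", "G"] <- FALSE
  m
})

# For every (i, j): length of the maximal perfect stem whose outermost pair is
# (i, j) growing inward ((i+1, j-1), ...), and the WC-pair count along that
# run. Makes each stem-validity query O(1).
stem_run_tables <- function(seq) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T")) # N -> NA, pairs with nothing
  R <- matrix(0L, n, n)
  W <- matrix(0L, n, n)
  for (span in seq_len(n - 1L)) { # j - i, ascending so (i+1, j-1) is ready
    i <- seq_len(n - span)
    j <- i + span
    ok <- !is.na(idx[i]) & !is.na(idx[j]) & PAIR_OK[cbind(idx[i], idx[j])]
    inner_r <- if (span >= 2L) R[cbind(i + 1L, j - 1L)] else 0L
    inner_w <- if (span >= 2L) W[cbind(i + 1L, j - 1L)] else 0L
    wc <- !is.na(idx[i]) & !is.na(idx[j]) & PAIR_WC[cbind(idx[i], idx[j])]
    R[cbind(i, j)] <- ifelse(ok, 1L + inner_r, 0L)
    W[cbind(i, j)] <- ifelse(ok, as.integer(wc) + inner_w, 0L)
  }
  list(R = R, W = W, n = n)
}

# WC pairs in the first k pairs of the run starting at outermost pair (i, j);
# only valid when R[i, j] >= k
stem_wc <- function(tab, i, j, k) {
  inner <- ifelse(tab$R[cbind(i, j)] > k,
                  tab$W[cbind(i + k, j - k)], 0L)
  tab$W[cbind(i, j)] - inner
}

# enumerate all full-cloverleaf placements for sequence length n; returns a
# data.frame of geometry tuples with derived positions, validity left to caller
cloverleaf_candidates <- function(n, geom, dhu = TRUE) {
  if (dhu) {
    g <- expand.grid(a = geom$acceptor_bp, s1 = geom$spacer1, d = geom$dhu_bp,
                     dl = geom$dhu_loop, s2 = geom$spacer2, c = geom$ac_bp,
                     v = geom$variable, t = geom$t_bp, tl = geom$t_loop,
                     KEEP.OUT.ATTRS = FALSE)
    used <- with(g, 2L * a + s1 + 2L * d + dl + s2 + 2L * c + 7L + v +
                    2L * t + tl)
  } else {
    g <- expand.grid(a = geom$acceptor_bp, cn = geom$dhu_connector,
                     c = geom$ac_bp, v = geom$variable, t = geom$t_bp,
                     tl = geom$t_loop, KEEP.OUT.ATTRS = FALSE)
    g$s1 <- g$d <- g$dl <- g$s2 <- 0L
    used <- with(g, 2L * a + cn + 2L * c + 7L + v + 2L * t + tl)
  }
  g$tail <- n - used
  g <- g[g$tail %in% geom$tail, , drop = FALSE]
  if (nrow(g) == 0L) return(g)
  pre_ac <- if (dhu) with(g, g$a + g$s1 + 2L * g$d + g$dl + g$s2) else g$a + g$cn
  g$dhu5 <- if (dhu) g$a + g$s1 + 1L else NA_integer_
  g$ac5 <- pre_ac + 1L
  g$ac_loop1 <- g$ac5 + g$c            # first loop position
  g$ac3 <- g$ac5 + g$c + 7L
  g$t5 <- g$ac3 + g$c + g$v
  g$t3 <- g$t5 + g$t + g$tl
  g$acc3 <- g$t3 + g$t
  g
}

# filter candidates to placements whose four (or three) stems all pair
valid_placements <- function(g, tab, dhu = TRUE) {
  if (nrow(g) == 0L) return(g)
  ok <- tab$R[cbind(1L, g$acc3 + g$a - 1L)] >= g$a &
    tab$R[cbind(g$ac5, g$ac3 + g$c - 1L)] >= g$c &
    tab$R[cbind(g$t5, g$t3 + g$t - 1L)] >= g$t
  if (dhu) {
    ok <- ok & tab$R[cbind(g$dhu5, g$dhu5 + 2L * g$d + g$dl - 1L)] >= g$d
  }
  g <- g[ok, , drop = FALSE]
  if (nrow(g) == 0L) return(g)
  g$score <- g$a + (if (dhu) g$d else 0L) + g$c + g$t
  g$wc <- stem_wc(tab, rep(1L, nrow(g)), g$acc3 + g$a - 1L, g$a) +
    stem_wc(tab, g$ac5, g$ac3 + g$c - 1L, g$c) +
    stem_wc(tab, g$t5, g$t3 + g$t - 1L, g$t) +
    (if (dhu) stem_wc(tab, g$dhu5, g$dhu5 + 2L * g$d + g$dl - 1L, g$d) else 0L)
  g$loop_total <- g$dl + 7L + g$tl
  g
}

# deterministic best placement: max pairs, then max WC, then min total loop,
# then leftmost DHU, then enumeration order
pick_placement <- function(g) {
  dhu_pos <- if ("dhu5" %in% names(g) && !all(is.na(g$dhu5))) {
    g$dhu5
  } else {
    rep(0L, nrow(g))
  }
  ord <- order(-g$score, -g$wc, g$loop_total, dhu_pos)
  g[ord[1], , drop = FALSE]
}

stem_pairs <- function(start5, start3, k) {
  lapply(seq_len(k) - 1L, function(i) c(start5 + i, start3 + k - 1L - i))
}

placement_to_cloverleaf <- function(seq, p, dhu, geom) {
  n <- nchar(seq)
  acc_pairs <- stem_pairs(1L, p$acc3, p$a)
  ac_pairs <- stem_pairs(p$ac5, p$ac3, p$c)
  t_pairs <- stem_pairs(p$t5, p$t3, p$t)
  dhu_arm <- NULL
  pairs <- c(acc_pairs, ac_pairs, t_pairs)
  if (dhu) {
    d_pairs <- stem_pairs(p$dhu5, p$dhu5 + p$d + p$dl, p$d)
    pairs <- c(pairs, d_pairs)
    dhu_arm <- list(
      stem5 = c(p$dhu5, p$dhu5 + p$d - 1L),
      loop = c(p$dhu5 + p$d, p$dhu5 + p$d + p$dl - 1L),
      stem3 = c(p$dhu5 + p$d + p$dl, p$dhu5 + 2L * p$d + p$dl - 1L),
      pairs = d_pairs
    )
  }
  anticodon_at <- p$ac_loop1 + 2L
  db <- rep(".", n)
  for (pr in pairs) {
    db[pr[1]] <- "("
    db[pr[2]] <- ")"
  }
  structure(list(
    sequence = seq,
    length = n,
    degenerate = !dhu,
    acceptor_stem = list(stem5 = c(1L, p$a), stem3 = c(p$acc3, p$acc3 + p$a - 1L),
                         pairs = acc_pairs),
    dhu_arm = dhu_arm,
    anticodon_arm = list(
      stem5 = c(p$ac5, p$ac5 + p$c - 1L),
      loop = c(p$ac_loop1, p$ac_loop1 + 6L),
      stem3 = c(p$ac3, p$ac3 + p$c - 1L),
      pairs = ac_pairs,
      anticodon = chartr("T", "U", substr(seq, anticodon_at, anticodon_at + 2L)),
      anticodon_pos = c(anticodon_at, anticodon_at + 2L)
    ),
    variable_region = if (p$v > 0) c(p$ac3 + p$c, p$ac3 + p$c + p$v - 1L) else integer(0),
    tpsic_arm = list(stem5 = c(p$t5, p$t5 + p$t - 1L),
                     loop = c(p$t5 + p$t, p$t5 + p$t + p$tl - 1L),
                     stem3 = c(p$t3, p$t3 + p$t - 1L),
                     pairs = t_pairs),
    tail = if (p$tail > 0) c(n - p$tail + 1L, n) else integer(0),
    score = p$score,
    wc_pairs = p$wc,
    dot_bracket = paste(db, collapse = ""),
    geometry = geom
  ), class = "cloverleaf")
}

#' Fold a tRNA sequence into a cloverleaf
#'
#' Exhaustive search over constrained arm placements: acceptor stem 6-7 bp,
#' DHU stem 3-4 bp with 4-11 nt loop, anticodon stem 4-5 bp with a fixed 7-nt
#' loop carrying the anticodon at loop positions 3-5, 3-23 nt variable region,
#' and TpsiC stem 4-5 bp with 4-9 nt loop (bounds adjustable via
#' [cloverleaf_geometry()]). Stems must pair perfectly (Watson-Crick or G.U
#' wobble; T read as U). The placement maximizing the number of base pairs
#' wins; ties broken by more WC pairs, then smaller total loop length, then
#' leftmost DHU arm. If no full cloverleaf exists (equivalently, no DHU stem
#' of >= 3 bp fits between the acceptor 5' half and the anticodon arm), a
#' degenerate DHU-less cloverleaf is returned - the mitochondrial
#' tRNA-Ser(GCU) case.
#'
#' @param seq tRNA sequence (DNA or RNA alphabet), 55-95 nt.
#' @param anticodon Optional anticodon triplet (A/C/G/U). When given, only
#'   placements putting it at anticodon-loop positions 3-5 are considered.
#' @param geometry Arm bounds from [cloverleaf_geometry()].
#' @return A `cloverleaf` object: arm coordinates, pair list, `score` (number
#'   of base pairs), `wc_pairs`, `degenerate` flag and a dot-bracket string.
#' @export
fold_cloverleaf <- function(seq, anticodon = NULL, geometry = cloverleaf_geometry()) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  n <- nchar(seq)
  if (n < geometry$min_len || n > geometry$max_len) {
    abort(paste0("tRNA length ", n, " outside [", geometry$min_len, ", ",
                 geometry$max_len, "]"),
          class = "mitochar_validation_error")
  }
  if (nzchar(gsub("[ACGTN]", "", seq))) {
    abort("tRNA sequence contains characters outside {A,C,G,T,U,N}",
          class = "mitochar_validation_error")
  }
  ac_dna <- if (!is.null(anticodon)) {
    if (!grepl("^[ACGU]{3}$", anticodon)) {
      abort("anticodon must be a triplet over A/C/G/U",
            class = "mitochar_validation_error")
    }
    chartr("U", "T", anticodon)
  }
  tab <- stem_run_tables(seq)
  search <- function(dhu) {
    g <- cloverleaf_candidates(n, geometry, dhu = dhu)
    if (!is.null(ac_dna) && nrow(g)) {
      hit <- substr(rep(seq, nrow(g)), g$ac_loop1 + 2L, g$ac_loop1 + 4L) == ac_dna
      g <- g[hit, , drop = FALSE]
    }
    valid_placements(g, tab, dhu = dhu)
  }
  full <- search(dhu = TRUE)
  if (nrow(full)) {
    return(placement_to_cloverleaf(seq, pick_placement(full), TRUE, geometry))
  }
  degen <- search(dhu = FALSE)
  if (nrow(degen)) {
    return(placement_to_cloverleaf(seq, pick_placement(degen), FALSE, geometry))
  }
  msg <- if (!is.null(ac_dna)) {
    paste0("no cloverleaf placement puts anticodon '", anticodon,
           "' at anticodon-loop positions 3-5 with valid stems")
  } else {
    "no valid cloverleaf placement (acceptor/anticodon/TpsiC stems unsatisfiable)"
  }
  abort(msg, class = "mitochar_fold_error")
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("<cloverleaf> ", x$length, " nt, ", x$score, " bp paired (",
      x$wc_pairs, " WC)", if (x$degenerate) ", DHU arm absent", "\n", sep = "")
  cat("  anticodon ", x$anticodon_arm$anticodon, " at ",
      x$anticodon_arm$anticodon_pos[1], "-", x$anticodon_arm$anticodon_pos[2],
      "\n  ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Decode an anticodon to its amino acid
#'
#' The anticodon (5'->3') is reverse-complemented to the codon it reads and
#' decoded under the vertebrate mitochondrial code.
#'
#' @param anticodon Triplet over A/C/G/U.
#' @param code Genetic code.
#' @return Three-letter amino-acid label (e.g. `"Phe"` for GAA).
#' @examples
#' anticodon_to_amino_acid("GAA") # "Phe"
#' @export
anticodon_to_amino_acid <- function(anticodon, code = mito_genetic_code()) {
  if (!grepl("^[ACGU]{3}$", anticodon)) {
    abort("anticodon must be a 5'->3' triplet over A/C/G/U",
          class = "mitochar_validation_error")
  }
  codon <- reverse_complement(chartr("U", "T", anticodon))
  aa <- code$map[[codon]]
  if (aa == "*") {
    abort(paste0("anticodon '", anticodon, "' reads stop codon ", codon),
          class = "mitochar_validation_error")
  }
  unname(AA_THREE[aa])
}

fmt_range <- function(r) {
  if (is.null(r) || length(r) == 0L) NA_character_ else paste0(r[1], "-", r[2])
}

#' Tabular report over folded cloverleaves
#'
#' @param cloverleaves A (possibly named) list of `cloverleaf` objects.
#'   `NULL` entries (unfoldable sequences) are skipped and counted in the
#'   `n_unfoldable` attribute.
#' @return A tibble with one row per tRNA: arm coordinate ranges, pair counts,
#'   degenerate flag, anticodon, amino acid and dot-bracket string; attribute
#'   `n_degenerate` carries the count of DHU-less structures.
#' @export
structure_report <- function(cloverleaves) {
  nm <- names(cloverleaves) %||% paste0("tRNA_", seq_along(cloverleaves))
  keep <- !vapply(cloverleaves, is.null, logical(1))
  n_unfoldable <- sum(!keep)
  cloverleaves <- cloverleaves[keep]
  nm <- nm[keep]
  rows <- purrr::map2(cloverleaves, nm, function(cl, name) {
    tibble(
      name = name,
      length = cl$length,
      pairs = cl$score,
      wc_pairs = cl$wc_pairs,
      degenerate = cl$degenerate,
      acceptor = paste0(fmt_range(cl$acceptor_stem$stem5), "/",
                        fmt_range(cl$acceptor_stem$stem3)),
      dhu = if (cl$degenerate) NA_character_ else
        paste0(fmt_range(cl$dhu_arm$stem5), "/", fmt_range(cl$dhu_arm$stem3)),
      anticodon_arm = paste0(fmt_range(cl$anticodon_arm$stem5), "/",
                             fmt_range(cl$anticodon_arm$stem3)),
      tpsic = paste0(fmt_range(cl$tpsic_arm$stem5), "/",
                     fmt_range(cl$tpsic_arm$stem3)),
      anticodon = cl$anticodon_arm$anticodon,
      amino_acid = tryCatch(anticodon_to_amino_acid(cl$anticodon_arm$anticodon),
                            error = function(e) NA_character_),
      dot_bracket = cl$dot_bracket
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(name = character(0), length = integer(0), pairs = integer(0),
                  wc_pairs = integer(0), degenerate = logical(0),
                  acceptor = character(0), dhu = character(0),
                  anticodon_arm = character(0), tpsic = character(0),
                  anticodon = character(0), amino_acid = character(0),
                  dot_bracket = character(0))
  }
  attr(out, "n_degenerate") <- sum(out$degenerate)
  attr(out, "n_unfoldable") <- n_unfoldable
  out
}

#' Fold all annotated tRNAs of a mitogenome
#'
#' Extracts each tRNA on its coding strand and folds it with its annotated
#' anticodon as the placement constraint; falls back to unconstrained folding
#' (with a warning) if the constrained fold fails.
#'
#' @param genome A [mitogenome()] object.
#' @param geometry Arm bounds.
#' @return A named list of `cloverleaf` objects.
#' @export
fold_genome_trnas <- function(genome, geometry = cloverleaf_geometry()) {
  stopifnot(inherits(genome, "mitogenome"))
  trna <- genome$features[genome$features$category == "tRNA", ]
  out <- list()
  for (i in seq_len(nrow(trna))) {
    seq <- extract_feature(genome, trna[i, ])
    anticodon <- if (is.na(trna$anticodon[i])) NULL else trna$anticodon[i]
    cl <- tryCatch(
      fold_cloverleaf(seq, anticodon, geometry),
      mitochar_fold_error = function(e) {
        warn(paste0(trna$name[i], ": ", conditionMessage(e),
                    "; refolding unconstrained"),
             class = "mitochar_fold_warning")
        tryCatch(
          fold_cloverleaf(seq, NULL, geometry),
          mitochar_fold_error = function(e2) {
            # a tRNA whose span is partly overwritten by an overlapping gene
            # (annotation overlaps do occur) may admit no cloverleaf at all
            warn(paste0(trna$name[i], ": unfoldable (",
                        conditionMessage(e2), ")"),
                 class = "mitochar_fold_warning")
            NULL
          }
        )
      }
    )
    out[trna$name[i]] <- list(cl)
  }
  out
}
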