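#' Default per-category base-composition targets
#'
#' Base frequencies (A, C, G, T) used when sampling synthetic feature and
#' spacer sequences, chosen to emulate a pangolin-like mammalian mitogenome:
#' A-rich, G-poor, with category-specific profiles for PCGs, structural RNAs
#' and non-coding regions.
#'
#' @return Named list of length-4 frequency vectors (`PCG`, `tRNA`, `rRNA`,
#'   `control`, `spacer`).
#' @export
composition_targets <- function() {
  list(
    PCG = c(A = 0.3184, C = 0.2935, G = 0.1328, T = 0.2553),
    tRNA = c(A = 0.3646, C = 0.2094, G = 0.1538, T = 0.2722),
    rRNA = c(A = 0.3792, C = 0.2154, G = 0.1774, T = 0.2280),
    control = c(A = 0.345, C = 0.269, G = 0.132, T = 0.254),
    spacer = c(A = 0.345, C = 0.269, G = 0.132, T = 0.254)
  )
}

#' The default mitogenome template
#'
#' The packaged 38-feature gene plan (13 PCGs, 22 tRNAs, 2 rRNAs, control
#' region) mirroring the canonical pangolin mitogenome annotation, including
#' its quirks: gene overlaps down to -40 nt, an ND2 start inside the upstream
#' tRNA, incomplete T--/TA- stops, one L-strand PCG (ND6) and a 113-nt gap
#' before the control region.
#'
#' @return A template tibble: `name`, `category`, `from`, `to`, `length_bp`,
#'   `spacing` (intergenic nucleotides before the feature), `strand`,
#'   `anticodon`, `start_codon`, `stop_codon`; attribute `composition` holds
#'   the [composition_targets()].
#' @export
default_genome_template <- function() {
  path <- system.file("extdata", "mpp_features.tsv", package = "mitochar",
                      mustWork = TRUE)
  plan <- read_feature_table(path)
  genome_template(plan)
}

#' Build and validate a genome template
#'
#' @param plan Feature tibble with `name`, `category`, `from`, `to`,
#'   `strand`, `anticodon`, and for PCGs `start_codon` and `stop_codon`
#'   (complete triplet, `"T--"` or `"TA-"`).
#' @param composition Per-category base-frequency targets
#'   ([composition_targets()]).
#' @param trna_geometry Cloverleaf bounds tRNA lengths must satisfy.
#' @return The validated template (see [default_genome_template()]).
#' @export
genome_template <- function(plan, composition = composition_targets(),
                            trna_geometry = cloverleaf_geometry()) {
  plan <- validate_features(as_tibble(plan), context = "template")
  plan$length_bp <- gene_length(plan$from, plan$to)
  plan$spacing <- intergenic_nucleotides(plan)
  for (i in which(plan$category == "PCG")) {
    row <- plan[i, ]
    if (is.na(row$start_codon) || !row$start_codon %in% mito_genetic_code()$starts) {
      abort(paste0("template PCG '", row$name, "': start_codon must be ATN"),
            class = "mitochar_validation_error")
    }
    need <- c("TAA" = 0L, "TAG" = 0L, "AGA" = 0L, "AGG" = 0L,
              "T--" = 1L, "TA-" = 2L)
    if (is.na(row$stop_codon) || !row$stop_codon %in% names(need)) {
      abort(paste0("template PCG '", row$name, "': unknown stop type '",
                   row$stop_codon, "'"),
            class = "mitochar_validation_error")
    }
    if (row$length_bp %% 3L != need[[row$stop_codon]]) {
      abort(paste0("template PCG '", row$name, "': length ", row$length_bp,
                   " mod 3 inconsistent with stop type ", row$stop_codon),
            class = "mitochar_validation_error")
    }
    if (row$length_bp < 6L) {
      abort(paste0("template PCG '", row$name, "' too short"),
            class = "mitochar_validation_error")
    }
  }
  for (i in which(plan$category == "tRNA")) {
    len <- plan$length_bp[i]
    if (len < trna_geometry$min_len || len > trna_geometry$max_len) {
      abort(paste0("template tRNA '", plan$name[i], "': length ", len,
                   " outside cloverleaf bounds"),
            class = "mitochar_validation_error")
    }
  }
  # overlaps must be shorter than both participating genes
  for (i in seq_len(nrow(plan))[-1]) {
    ov <- -plan$spacing[i]
    if (ov > 0 && (ov >= plan$length_bp[i] || ov >= plan$length_bp[i - 1L])) {
      abort(paste0("template overlap before '", plan$name[i],
                   "' swallows a whole gene"),
            class = "mitochar_validation_error")
    }
  }
  # PCG start/stop bases are hard constraints on genome positions; two PCGs
  # demanding different bases at one position make the plan unrealizable
  comp_base <- c(A = "T", C = "G", G = "C", T = "A")
  required <- list()
  for (i in which(plan$category == "PCG")) {
    row <- plan[i, ]
    trailing <- switch(row$stop_codon, "T--" = "T", "TA-" = "TA",
                       row$stop_codon)
    offs <- c(1:3, row$length_bp - nchar(trailing) + seq_len(nchar(trailing)))
    bases <- c(strsplit(row$start_codon, "")[[1]],
               strsplit(trailing, "")[[1]])
    pos <- if (row$strand == "H") row$from + offs - 1L else row$to - offs + 1L
    if (row$strand == "L") bases <- unname(comp_base[bases])
    for (k in seq_along(pos)) {
      key <- as.character(pos[k])
      if (!is.null(required[[key]]) && required[[key]] != bases[k]) {
        abort(paste0("template unrealizable: PCG start/stop constraints ",
                     "conflict at position ", pos[k]),
              class = "mitochar_validation_error")
      }
      required[[key]] <- bases[k]
    }
  }
  attr(plan, "composition") <- composition
  attr(plan, "trna_geometry") <- trna_geometry
  plan
}

sample_bases <- function(n, freqs) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs)
}

# sample one sense (non-stop) codon at the target composition
sample_codons <- function(n, freqs, stops) {
  if (n <= 0L) return(character(0))
  out <- character(n)
  done <- 0L
  while (done < n) {
    batch <- paste0(sample_bases(n - done, freqs),
                    sample_bases(n - done, freqs),
                    sample_bases(n - done, freqs))
    keep <- batch[!batch %in% stops]
    if (length(keep)) {
      out[done + seq_along(keep)] <- keep
      done <- done + length(keep)
    }
  }
  out
}

# coding-strand PCG sequence honoring start codon and stop type
sample_pcg <- function(length_bp, start_codon, stop_codon, freqs, code) {
  trailing <- switch(stop_codon, "T--" = "T", "TA-" = "TA", "")
  n_codons <- (length_bp - nchar(trailing)) %/% 3L
  body <- sample_codons(n_codons - 1L - (trailing == ""), freqs, code$stops)
  if (trailing == "") {
    paste0(start_codon, paste(body, collapse = ""), stop_codon)
  } else {
    paste0(start_codon, paste(body, collapse = ""), trailing)
  }
}

#' Generate a synthetic tRNA with known cloverleaf truth
#'
#' Samples a valid arm geometry for the requested length, fills stems with
#' complementary pairs (a fraction `gu_prob` G.U wobble) and loops/spacers at
#' the tRNA composition target, and places the anticodon at anticodon-loop
#' positions 3-5. With `dhu_present = FALSE` the DHU arm is replaced by an
#' unpaired connector and the construction is rejection-sampled until
#' [fold_cloverleaf()] confirms no full cloverleaf fits.
#'
#' @param anticodon Anticodon triplet (A/C/G/U).
#' @param length Total tRNA length (nt) within the geometry bounds.
#' @param dhu_present Build a DHU arm?
#' @param seed Integer seed (omit when already inside a seeded context by
#'   passing `NULL`).
#' @param geometry Bounds from [cloverleaf_geometry()].
#' @param gu_prob Per-pair probability of a G.U wobble pair in stems.
#' @param avoid_ambiguity Resample constructions whose loops/spacers happen to
#'   admit an alternative placement that outranks the constructed arms, so
#'   [fold_cloverleaf()] recovers the construction; disable for speed when arm
#'   truth is not needed.
#' @return List with `sequence` and `truth` (the constructed geometry tuple
#'   and arm coordinates).
#' @export
generate_trna <- function(anticodon, length = 72L, dhu_present = TRUE,
                          seed = NULL, geometry = cloverleaf_geometry(),
                          gu_prob = 0.1, avoid_ambiguity = TRUE) {
  run <- function() generate_trna_impl(anticodon, length, dhu_present,
                                       geometry, gu_prob, avoid_ambiguity)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

generate_trna_impl <- function(anticodon, length, dhu_present, geometry,
                               gu_prob, avoid_ambiguity = TRUE) {
  cand <- cloverleaf_candidates(as.integer(length), geometry,
                                dhu = dhu_present)
  if (nrow(cand) == 0L) {
    abort(paste0("no cloverleaf geometry of length ", length,
                 if (!dhu_present) " without a DHU arm"),
          class = "mitochar_validation_error")
  }
  freqs <- composition_targets()$tRNA
  ac_dna <- chartr("U", "T", anticodon)
  build <- function() {
    p <- cand[sample.int(nrow(cand), 1L), ]
    pair_of <- function(b) {
      wc <- c(A = "T", C = "G", G = "C", T = "A")[[b]]
      if (b == "G" && runif(1) < gu_prob) "T"
      else if (b == "T" && runif(1) < gu_prob) "G"
      else wc
    }
    make_stem <- function(k) {
      s5 <- sample_bases(k, freqs)
      s3 <- rev(vapply(s5, pair_of, character(1)))
      list(s5 = paste(s5, collapse = ""), s3 = paste(s3, collapse = ""))
    }
    acc <- make_stem(p$a)
    ac <- make_stem(p$c)
    tp <- make_stem(p$t)
    ac_loop <- paste0(paste(sample_bases(2L, freqs), collapse = ""), ac_dna,
                      paste(sample_bases(2L, freqs), collapse = ""))
    mid <- if (dhu_present) {
      dh <- make_stem(p$d)
      paste0(paste(sample_bases(p$s1, freqs), collapse = ""),
             dh$s5, paste(sample_bases(p$dl, freqs), collapse = ""), dh$s3,
             paste(sample_bases(p$s2, freqs), collapse = ""))
    } else {
      paste(sample_bases(p$cn, freqs), collapse = "")
    }
    seqs <- paste0(acc$s5, mid, ac$s5, ac_loop, ac$s3,
                   paste(sample_bases(p$v, freqs), collapse = ""),
                   tp$s5, paste(sample_bases(p$tl, freqs), collapse = ""),
                   tp$s3, acc$s3,
                   paste(sample_bases(p$tail, freqs), collapse = ""))
    list(sequence = seqs, placement = p)
  }
  if (dhu_present) {
    b <- build()
    if (avoid_ambiguity) {
      for (try in seq_len(25L)) {
        p <- b$placement
        cl <- tryCatch(fold_cloverleaf(b$sequence, anticodon, geometry),
                       error = function(e) NULL)
        recovered <- !is.null(cl) && !cl$degenerate &&
          cl$acceptor_stem$stem5[2] == p$a &&
          identical(unname(cl$dhu_arm$stem5), c(p$dhu5, p$dhu5 + p$d - 1L)) &&
          identical(unname(cl$anticodon_arm$stem5),
                    c(p$ac5, p$ac5 + p$c - 1L)) &&
          identical(unname(cl$tpsic_arm$stem5), c(p$t5, p$t5 + p$t - 1L))
        if (recovered) break
        b <- build()
      }
    }
  } else {
    # reject constructions in which some full cloverleaf still fits
    for (try in seq_len(100L)) {
      b <- build()
      fold <- tryCatch(fold_cloverleaf(b$sequence, anticodon, geometry),
                       error = function(e) NULL)
      if (!is.null(fold) && fold$degenerate) break
      b <- NULL
    }
    if (is.null(b)) {
      abort("failed to sample a DHU-less tRNA that admits no full cloverleaf",
            class = "mitochar_numeric_error")
    }
  }
  p <- b$placement
  truth <- list(
    geometry = as.list(p),
    acceptor_stem5 = c(1L, p$a),
    dhu_stem5 = if (dhu_present) c(p$dhu5, p$dhu5 + p$d - 1L),
    anticodon_stem5 = c(p$ac5, p$ac5 + p$c - 1L),
    anticodon_pos = c(p$ac_loop1 + 2L, p$ac_loop1 + 4L),
    tpsic_stem5 = c(p$t5, p$t5 + p$t - 1L),
    dhu_present = dhu_present
  )
  list(sequence = b$sequence, truth = truth)
}

#' Generate an annotated synthetic mitogenome
#'
#' Realizes a [genome_template()] into a concrete genome: spacers sampled at
#' the spacer composition target, rRNA/control regions at theirs, tRNAs built
#' by [generate_trna()], and PCGs codon-sampled with the planned ATN start, no
#' in-frame stop codons, and the planned complete or incomplete stop. Features
#' are written in table order; where features overlap, the later feature's
#' bases win, and a final pass force-writes every PCG's start and stop bases
#' (overlapping plans like an ND2-start-inside-a-tRNA are exactly the cases
#' this supports). L-strand features are inserted as reverse complements.
#' [characterize()] on the result reproduces the planned lengths, intergenic
#' values, starts and stop labels exactly.
#'
#' @param template From [genome_template()] / [default_genome_template()].
#' @param seed Integer seed; the same seed gives a byte-identical genome.
#' @param id Genome label.
#' @return List with `genome` (a [mitogenome()]) and `truth` (template,
#'   coordinates, seed).
#' @export
generate_mitogenome <- function(template, seed = 1L, id = "synthetic") {
  if (is.null(attr(template, "composition"))) {
    template <- genome_template(template)
  }
  comp <- attr(template, "composition")
  geometry <- attr(template, "trna_geometry")
  code <- mito_genetic_code()
  withr::with_seed(seed, {
    n <- max(template$to)
    genome <- sample_bases(n, comp$spacer)
    forced <- rep(FALSE, n)
    write_span <- function(from, to, seqs, strand) {
      if (strand == "L") seqs <- reverse_complement(seqs)
      genome[from:to] <<- strsplit(seqs, "")[[1]]
    }
    for (i in seq_len(nrow(template))) {
      row <- template[i, ]
      seqs <- switch(
        row$category,
        PCG = sample_pcg(row$length_bp, row$start_codon, row$stop_codon,
                         comp$PCG, code),
        tRNA = generate_trna(if (is.na(row$anticodon)) "GAA" else row$anticodon,
                             length = row$length_bp, dhu_present = TRUE,
                             seed = NULL, geometry = geometry,
                             avoid_ambiguity = FALSE)$sequence,
        rRNA = paste(sample_bases(row$length_bp, comp$rRNA), collapse = ""),
        control = paste(sample_bases(row$length_bp, comp$control), collapse = "")
      )
      write_span(row$from, row$to, seqs, row$strand)
    }
    # force-write PCG start/stop bases (overlapping features may have
    # overwritten them), tracking forced positions
    comp_base <- c(A = "T", C = "G", G = "C", T = "A")
    h_pos <- function(row, offsets) {
      # coding-strand offset -> H-strand position
      if (row$strand == "H") row$from + offsets - 1L else row$to - offsets + 1L
    }
    put <- function(row, offsets, bases) {
      pos <- h_pos(row, offsets)
      if (row$strand == "L") bases <- unname(comp_base[bases])
      genome[pos] <<- bases
      forced[pos] <<- TRUE
    }
    for (i in which(template$category == "PCG")) {
      row <- template[i, ]
      put(row, 1:3, strsplit(row$start_codon, "")[[1]])
      trailing <- switch(row$stop_codon, "T--" = "T", "TA-" = "TA",
                         row$stop_codon)
      tb <- strsplit(trailing, "")[[1]]
      put(row, row$length_bp - length(tb) + seq_along(tb), tb)
    }
    # remove in-frame stops introduced by overlaps/forcing wherever the codon
    # has at least one unforced base; fully forced stops (cross-PCG overlap
    # conflicts) are left and recorded in the truth
    residual_stops <- character(0)
    for (i in which(template$category == "PCG")) {
      row <- template[i, ]
      for (pass in 1:20) {
        cds <- extract_feature(paste(genome, collapse = ""), row)
        codons <- split_codons(cds)
        is_internal <- seq_along(codons) > 1L &
          (seq_along(codons) < length(codons) |
             row$stop_codon %in% c("T--", "TA-"))
        bad <- which(codons %in% code$stops & is_internal)
        if (length(bad) == 0L) break
        changed <- FALSE
        for (cj in bad) {
          offs <- (cj - 1L) * 3L + 1:3
          pos <- h_pos(row, offs)
          free <- which(!forced[pos])
          if (length(free) == 0L) {
            residual_stops <- c(residual_stops,
                                paste0(row$name, ":codon", cj))
            next
          }
          keep <- strsplit(codons[cj], "")[[1]]
          for (att in 1:50) {
            cand <- keep
            cand[free] <- sample_bases(length(free), comp$PCG)
            if (!paste(cand, collapse = "") %in% code$stops) {
              keep <- cand
              changed <- TRUE
              break
            }
          }
          bh <- if (row$strand == "L") unname(comp_base[keep]) else keep
          genome[pos] <- bh
        }
        if (!changed) break
      }
    }
    seqs <- paste(genome, collapse = "")
    feats <- template[, c("name", "category", "from", "to", "anticodon",
                          "strand")]
    g <- mitogenome(id, seqs, feats, circular = TRUE)
    truth <- list(
      template = as.data.frame(template), seed = seed, id = id,
      genome_length = n, residual_inframe_stops = residual_stops
    )
    list(genome = g, truth = truth)
  })
}

#' Simulate sequence evolution along a tree
#'
#' Site-independent simulation under a [phylo_model()]: each site draws a rate
#' (0 with probability `p_inv`, else a rescaled discrete-gamma category rate)
#' and evolves from the root down every branch with matrix-exponential
#' transition probabilities.
#'
#' @param root Root DNA string (states over A/C/G/T), or an integer length, in
#'   which case the root is drawn from the model's stationary frequencies.
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param model A [phylo_model()].
#' @param seed Integer seed.
#' @return Named character vector: tip taxon -> sequence.
#' @export
evolve_sequences <- function(root, tree, model, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "mitochar_validation_error")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    root_states <- if (is.numeric(root)) {
      sample.int(4L, root, replace = TRUE, prob = model$base_freqs)
    } else {
      st <- match(strsplit(gsub("U", "T", toupper(root)), "")[[1]], bases)
      if (anyNA(st)) {
        abort("root sequence must be over A/C/G/T",
              class = "mitochar_validation_error")
      }
      st
    }
    nsite <- length(root_states)
    mix <- model_rate_mixture(model)
    site_cat <- sample.int(length(mix$rates), nsite, replace = TRUE,
                           prob = mix$weights)
    eig <- gtr_eigen(model)
    tree_pre <- ape::reorder.phylo(tree, "cladewise")
    nnode <- length(tree$tip.label) + tree$Nnode
    states <- vector("list", nnode)
    root_node <- tree_pre$edge[1L, 1L]
    states[[root_node]] <- root_states
    for (e in seq_len(nrow(tree_pre$edge))) {
      parent <- tree_pre$edge[e, 1L]
      child <- tree_pre$edge[e, 2L]
      t_e <- tree_pre$edge.length[e]
      out <- states[[parent]]
      for (k in seq_along(mix$rates)) {
        idx <- which(site_cat == k)
        if (length(idx) == 0L) next
        r <- mix$rates[k]
        if (r == 0 || t_e == 0) next
        P <- transition_matrix(eig, t_e * r)
        P <- pmax(P, 0)
        P <- P / rowSums(P)
        for (s in 1:4) {
          here <- idx[states[[parent]][idx] == s]
          if (length(here)) {
            out[here] <- sample.int(4L, length(here), replace = TRUE,
                                    prob = P[s, ])
          }
        }
      }
      states[[child]] <- out
    }
    tips <- vapply(seq_along(tree$tip.label), function(i) {
      paste(bases[states[[i]]], collapse = "")
    }, character(1))
    setNames(tips, tree$tip.label)
  })
}
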