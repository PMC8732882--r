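# shared fixtures and independent oracles

mpp_features <- function() {
  read_feature_table(system.file("extdata", "mpp_features.tsv",
                                 package = "mitochar", mustWork = TRUE))
}

mpp_composition <- function() {
  tibble::as_tibble(utils::read.delim(
    system.file("extdata", "mpp_composition.tsv", package = "mitochar",
                mustWork = TRUE),
    check.names = FALSE
  ))
}

random_dna <- function(n, freqs = c(0.3, 0.25, 0.15, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# a small realizable random genome template (few short features); retries
# until the sampled plan passes realizability validation
random_small_template <- function() {
  repeat {
    tpl <- tryCatch(random_small_template_once(), error = function(e) NULL)
    if (!is.null(tpl)) return(tpl)
  }
}

random_small_template_once <- function() {
  starts <- mito_genetic_code()$starts
  n_feat <- sample(5:9, 1)
  rows <- list()
  pos <- 1L
  for (i in seq_len(n_feat)) {
    cat_i <- sample(c("PCG", "tRNA", "rRNA", "control"), 1,
                    prob = c(0.45, 0.3, 0.15, 0.1))
    stop_i <- NA_character_
    start_i <- NA_character_
    if (cat_i == "PCG") {
      start_i <- sample(starts, 1)
      stop_i <- sample(c("TAA", "TAG", "AGA", "AGG", "T--", "TA-"), 1)
      extra <- switch(stop_i, "T--" = 1L, "TA-" = 2L, 0L)
      len <- 3L * sample(8:40, 1) + extra
    } else if (cat_i == "tRNA") {
      len <- sample(59:80, 1)
    } else {
      len <- sample(100:300, 1)
    }
    spacing <- if (i == 1) 0L else sample(c(0L, 1L, 3L, 10L, -2L), 1)
    from <- pos + spacing
    if (from < 1L) from <- pos
    rows[[i]] <- tibble::tibble(
      name = paste0("g", i), category = cat_i, from = from,
      to = from + len - 1L,
      anticodon = if (cat_i == "tRNA") "GAA" else NA_character_,
      strand = sample(c("H", "L"), 1, prob = c(0.8, 0.2)),
      start_codon = start_i, stop_codon = stop_i
    )
    pos <- rows[[i]]$to + 1L
  }
  genome_template(dplyr::bind_rows(rows))
}

# ---- independent cloverleaf oracle ---------------------------------------
# plain nested-loop enumeration of every constrained placement, pairing
# checked base by base; returns max pair count for full (dhu) and degenerate
# layouts, or -Inf when none is valid
oracle_can_pair <- function(x, y) {
  (x == "A" && y == "T") || (x == "T" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G") ||
    (x == "G" && y == "T") || (x == "T" && y == "G")
}

oracle_stem_ok <- function(ch, s5, s3, k) {
  # pairs (s5 + i, s3 + k - 1 - i)
  for (i in 0:(k - 1)) {
    if (!oracle_can_pair(ch[s5 + i], ch[s3 + k - 1 - i])) return(FALSE)
  }
  TRUE
}

oracle_cloverleaf_best <- function(seq, anticodon = NULL,
                                   geom = cloverleaf_geometry()) {
  ch <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  n <- length(ch)
  ac <- if (!is.null(anticodon)) strsplit(chartr("U", "T", anticodon), "")[[1]]
  best_full <- -Inf
  best_degen <- -Inf
  for (a in geom$acceptor_bp) {
    for (c_ in geom$ac_bp) for (t_ in geom$t_bp) for (tl in geom$t_loop) {
      for (v in geom$variable) for (tail in geom$tail) {
        # full layout: iterate DHU block
        for (s1 in geom$spacer1) for (d in geom$dhu_bp) {
          for (dl in geom$dhu_loop) for (s2 in geom$spacer2) {
            total <- 2 * a + s1 + 2 * d + dl + s2 + 2 * c_ + 7 + v +
              2 * t_ + tl + tail
            if (total != n) next
            dhu5 <- a + s1 + 1
            ac5 <- a + s1 + 2 * d + dl + s2 + 1
            ac3 <- ac5 + c_ + 7
            t5 <- ac3 + c_ + v
            t3 <- t5 + t_ + tl
            acc3 <- t3 + t_
            if (!is.null(ac)) {
              loop1 <- ac5 + c_
              if (!identical(ch[(loop1 + 2):(loop1 + 4)], ac)) next
            }
            if (!oracle_stem_ok(ch, 1, acc3, a)) next
            if (!oracle_stem_ok(ch, dhu5, dhu5 + d + dl, d)) next
            if (!oracle_stem_ok(ch, ac5, ac3, c_)) next
            if (!oracle_stem_ok(ch, t5, t3, t_)) next
            score <- a + d + c_ + t_
            if (score > best_full) best_full <- score
          }
        }
        # degenerate layout
        for (cn in geom$dhu_connector) {
          total <- 2 * a + cn + 2 * c_ + 7 + v + 2 * t_ + tl + tail
          if (total != n) next
          ac5 <- a + cn + 1
          ac3 <- ac5 + c_ + 7
          t5 <- ac3 + c_ + v
          t3 <- t5 + t_ + tl
          acc3 <- t3 + t_
          if (!is.null(ac)) {
            loop1 <- ac5 + c_
            if (!identical(ch[(loop1 + 2):(loop1 + 4)], ac)) next
          }
          if (!oracle_stem_ok(ch, 1, acc3, a)) next
          if (!oracle_stem_ok(ch, ac5, ac3, c_)) next
          if (!oracle_stem_ok(ch, t5, t3, t_)) next
          score <- a + c_ + t_
          if (score > best_degen) best_degen <- score
        }
      }
    }
  }
  list(full = best_full, degen = best_degen)
}

# ---- independent pairwise-alignment oracle -------------------------------
# enumerate every global alignment recursively, scoring with affine gaps
oracle_align_score <- function(a, b, params = align_params()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) params$match else params$mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (j <= length(bv)) { # gap in a
      g <- if (prev == "X") params$gap_extend else params$gap_open
      best <- max(best, g + rec(i, j + 1, "X"))
    }
    if (i <= length(av)) { # gap in b
      g <- if (prev == "Y") params$gap_extend else params$gap_open
      best <- max(best, g + rec(i + 1, j, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# ---- independent likelihood oracle ---------------------------------------
# brute-force sum over internal-node state assignments; Q and P built
# independently of the package (direct formula + Matrix::expm)
oracle_Q <- function(rates, freqs) {
  Q <- matrix(0, 4, 4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(freqs * diag(Q)))
}

oracle_loglik <- function(tree, seq_mat, model) {
  freqs <- unname(model$base_freqs)
  Q <- oracle_Q(unname(model$rates), freqs)
  # same Yang discretization, computed via direct numerical integration
  ncat <- model$n_cat
  rates <- if (is.infinite(model$alpha)) rep(1, ncat) else {
    br <- qgamma(seq(0, 1, length.out = ncat + 1), model$alpha, model$alpha)
    sapply(seq_len(ncat), function(k) {
      integrate(function(x) x * dgamma(x, model$alpha, rate = model$alpha),
                br[k], br[k + 1], rel.tol = 1e-10)$value * ncat
    })
  }
  if (model$p_inv > 0) {
    w <- c(model$p_inv, rep((1 - model$p_inv) / ncat, ncat))
    rates <- c(0, rates / (1 - model$p_inv))
  } else {
    w <- rep(1 / ncat, ncat)
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edges <- tree$edge
  root <- setdiff(edges[, 1], edges[, 2])[1]
  states <- c("A", "C", "G", "T")
  total_ll <- 0
  for (site in seq_len(ncol(seq_mat))) {
    obs <- match(seq_mat[tree$tip.label, site], states)
    site_lik <- 0
    for (k in seq_along(rates)) {
      Ps <- lapply(seq_len(nrow(edges)), function(e) {
        as.matrix(Matrix::expm(Q * rates[k] * tree$edge.length[e]))
      })
      lik_k <- 0
      grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
      for (g in seq_len(nrow(grid))) {
        assign_int <- grid[g, ]
        state_of <- function(node) {
          if (node <= ntip) obs[node] else assign_int[node - ntip]
        }
        p <- freqs[state_of(root)]
        for (e in seq_len(nrow(edges))) {
          p <- p * Ps[[e]][state_of(edges[e, 1]), state_of(edges[e, 2])]
        }
        lik_k <- lik_k + p
      }
      site_lik <- site_lik + w[k] * lik_k
    }
    total_ll <- total_ll + log(site_lik)
  }
  total_ll
}
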