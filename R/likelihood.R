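#' GTR+F+I+G4 substitution model
#'
#' General time-reversible model with empirical-style base frequencies, an
#' invariant-site proportion, and discrete-gamma rate heterogeneity with
#' `n_cat` equal-probability categories (each category's rate is the mean of
#' its quantile band). The rate matrix is scaled so the mean substitution rate
#' at stationarity is 1; the invariant/gamma mixture is rescaled so the total
#' mean rate stays 1, so branch lengths are in expected substitutions per
#' site.
#'
#' @param rates Six nonnegative GTR exchangeabilities, order AC, AG, AT, CG,
#'   CT, GT (GT conventionally fixed at 1 during optimization).
#' @param base_freqs Four frequencies (A, C, G, T) summing to 1.
#' @param p_inv Invariant-site proportion in `[0, 1)`.
#' @param alpha Gamma shape (> 0); `Inf` disables rate heterogeneity.
#' @param n_cat Number of discrete gamma categories.
#' @return A `phylo_model` object.
#' @export
phylo_model <- function(rates = c(1, 1, 1, 1, 1, 1),
                        base_freqs = rep(0.25, 4),
                        p_inv = 0, alpha = Inf, n_cat = 4L) {
  rates <- unname(as.numeric(rates))
  base_freqs <- unname(as.numeric(base_freqs))
  if (length(rates) != 6L || any(rates < 0)) {
    abort("rates must be 6 nonnegative exchangeabilities (AC, AG, AT, CG, CT, GT)",
          class = "mitochar_validation_error")
  }
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    abort("base_freqs must be 4 positive frequencies summing to 1",
          class = "mitochar_validation_error")
  }
  if (p_inv < 0 || p_inv >= 1) {
    abort("p_inv must lie in [0, 1)", class = "mitochar_validation_error")
  }
  if (!is.infinite(alpha) && alpha <= 0) {
    abort("alpha must be > 0 (or Inf for rate homogeneity)",
          class = "mitochar_validation_error")
  }
  structure(
    list(rates = setNames(rates, c("AC", "AG", "AT", "CG", "CT", "GT")),
         base_freqs = setNames(base_freqs, c("A", "C", "G", "T")),
         p_inv = p_inv, alpha = alpha, n_cat = as.integer(n_cat)),
    class = "phylo_model"
  )
}

#' @export
print.phylo_model <- function(x, ...) {
  cat("<phylo_model> GTR",
      if (x$p_inv > 0) "+I",
      if (!is.infinite(x$alpha)) paste0("+G", x$n_cat), "\n", sep = "")
  cat("  exchangeabilities:",
      paste(names(x$rates), sprintf("%.4g", x$rates), collapse = ", "), "\n")
  cat("  base freqs:",
      paste(names(x$base_freqs), sprintf("%.4f", x$base_freqs), collapse = ", "),
      "\n")
  cat("  p_inv:", sprintf("%.4f", x$p_inv),
      " alpha:", sprintf("%.4g", x$alpha), "\n")
  invisible(x)
}

# GTR rate matrix Q (rows/cols A,C,G,T), scaled to mean rate 1 at stationarity
gtr_rate_matrix <- function(model) {
  r <- model$rates
  pi <- model$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  Q["A", "C"] <- r[["AC"]] * pi[["C"]]; Q["C", "A"] <- r[["AC"]] * pi[["A"]]
  Q["A", "G"] <- r[["AG"]] * pi[["G"]]; Q["G", "A"] <- r[["AG"]] * pi[["A"]]
  Q["A", "T"] <- r[["AT"]] * pi[["T"]]; Q["T", "A"] <- r[["AT"]] * pi[["A"]]
  Q["C", "G"] <- r[["CG"]] * pi[["G"]]; Q["G", "C"] <- r[["CG"]] * pi[["C"]]
  Q["C", "T"] <- r[["CT"]] * pi[["T"]]; Q["T", "C"] <- r[["CT"]] * pi[["C"]]
  Q["G", "T"] <- r[["GT"]] * pi[["T"]]; Q["T", "G"] <- r[["GT"]] * pi[["G"]]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) {
    abort("degenerate rate matrix (all exchangeabilities zero?)",
          class = "mitochar_validation_error")
  }
  Q / scale
}

# eigendecomposition of the reversible Q via its symmetrization
# diag(sqrt(pi)) Q diag(1/sqrt(pi)); returns pieces for fast expm(Q t)
gtr_eigen <- function(model) {
  Q <- gtr_rate_matrix(model)
  pi <- model$base_freqs
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sp) %*% e$vectors,   # Q = right diag(values) left
       left = t(e$vectors) %*% diag(sp))
}

# P(t) = expm(Q * t), by eigendecomposition; clipped at 0 for safety
transition_matrix <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma category rates
#'
#' Mean-of-band discretization: the gamma(alpha, alpha) distribution (mean 1)
#' is cut into `n_cat` equal-probability bands and each category's rate is the
#' band's conditional mean, so the category rates average exactly 1.
#'
#' @param alpha Gamma shape.
#' @param n_cat Number of categories.
#' @return Numeric vector of `n_cat` rates.
#' @export
gamma_category_rates <- function(alpha, n_cat = 4L) {
  if (is.infinite(alpha)) return(rep(1, n_cat))
  breaks <- qgamma(seq(0, 1, length.out = n_cat + 1L), shape = alpha,
                   rate = alpha)
  # E[X * 1{X <= b}] for X ~ gamma(a, a) with mean 1 is pgamma(b, a + 1, a)
  partial <- pgamma(breaks, shape = alpha + 1, rate = alpha)
  n_cat * diff(partial)
}

# mixture of per-site rates implied by the model: rate 0 with weight p_inv,
# gamma category rates (rescaled by 1/(1 - p_inv)) with weight (1-p_inv)/n_cat
model_rate_mixture <- function(model) {
  g <- gamma_category_rates(model$alpha, model$n_cat)
  if (model$p_inv > 0) {
    list(rates = c(0, g / (1 - model$p_inv)),
         weights = c(model$p_inv, rep((1 - model$p_inv) / model$n_cat,
                                      model$n_cat)))
  } else {
    list(rates = g, weights = rep(1 / model$n_cat, model$n_cat))
  }
}

# ---- site patterns -------------------------------------------------------

# compress alignment columns into unique site patterns; returns the 4 x npat
# partial-likelihood matrix per taxon (gap/N = all ones) and pattern weights
compress_patterns <- function(aln) {
  mat <- unclass(aln)
  key <- apply(mat, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  weights <- tabulate(idx, nbins = sum(first))
  pat <- mat[, first, drop = FALSE]
  tips <- lapply(seq_len(nrow(pat)), function(i) {
    tp <- matrix(0, 4, ncol(pat))
    rownames(tp) <- c("A", "C", "G", "T")
    hit <- match(pat[i, ], c("A", "C", "G", "T"))
    known <- !is.na(hit)
    tp[cbind(hit[known], which(known))] <- 1
    tp[, !known] <- 1
    tp
  })
  names(tips) <- rownames(pat)
  list(tips = tips, weights = weights, pattern = pat, n_sites = ncol(mat))
}

# per-pattern log-likelihood at a single rate, by Felsenstein pruning;
# rate 0 short-circuits to the constant-site case. The fast path skips
# rescaling (safe at desk scale); on underflow it reruns with per-edge
# rescaling.
prune_loglik_per_pattern <- function(tree, tips, eig, pi, rate,
                                     rescale = FALSE) {
  npat <- ncol(tips[[1]])
  if (rate == 0) {
    acc <- matrix(1, 4, npat)
    for (tp in tips[tree$tip.label]) acc <- acc * tp
    return(log(colSums(pi * acc)))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- length(tree$tip.label) + tree$Nnode
  CL <- vector("list", nnode)
  logscale <- rep(0, npat)
  for (i in seq_along(tree$tip.label)) CL[[i]] <- tips[[tree$tip.label[i]]]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    P <- transition_matrix(eig, tree$edge.length[e] * rate)
    cl <- P %*% CL[[child]]
    if (!is.null(CL[[parent]])) cl <- CL[[parent]] * cl
    if (rescale) {
      s <- pmax.int(cl[1L, ], cl[2L, ], cl[3L, ], cl[4L, ])
      s[s == 0] <- 1
      cl <- cl / rep(s, each = 4L)
      logscale <- logscale + log(s)
    }
    CL[[parent]] <- cl
  }
  root <- tree$edge[nrow(tree$edge), 1L]
  lik <- colSums(pi * CL[[root]])
  if (!rescale && any(lik == 0)) {
    return(prune_loglik_per_pattern(tree, tips, eig, pi, rate, rescale = TRUE))
  }
  log(lik) + logscale
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under GTR+F+I+G: per site pattern, the likelihood is a
#' weighted mixture over the invariant class (rate 0, weight `p_inv`) and the
#' discrete-gamma categories. Gaps and N are treated as fully missing (partial
#' likelihood 1 for every state). The result is invariant to taxon order and,
#' by reversibility, to root placement.
#'
#' @param tree An `ape::phylo` tree with branch lengths, tips matching the
#'   alignment's taxa.
#' @param alignment A [dna_alignment()] (or coercible input).
#' @param model A [phylo_model()].
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(tree, alignment, model) {
  aln <- if (inherits(alignment, "dna_alignment")) alignment else dna_alignment(alignment)
  if (!setequal(tree$tip.label, rownames(aln))) {
    abort("tree tips and alignment taxa differ",
          class = "mitochar_validation_error")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "mitochar_validation_error")
  }
  pat <- compress_patterns(aln)
  ll <- loglik_from_patterns(tree, pat, model)
  if (!is.finite(ll)) {
    abort("non-finite log-likelihood", class = "mitochar_numeric_error")
  }
  ll
}

loglik_from_patterns <- function(tree, pat, model) {
  eig <- gtr_eigen(model)
  pi <- model$base_freqs
  mix <- model_rate_mixture(model)
  per_cat <- vapply(mix$rates, function(r) {
    prune_loglik_per_pattern(tree, pat$tips, eig, pi, r)
  }, numeric(length(pat$weights)))
  per_cat <- matrix(per_cat, nrow = length(pat$weights))
  # log-sum-exp across the rate mixture, per pattern
  mx <- per_cat[cbind(seq_len(nrow(per_cat)), max.col(per_cat, "first"))]
  site_ll <- mx + log(as.vector(
    exp(per_cat - mx) %*% mix$weights
  ))
  sum(site_ll * pat$weights)
}

#' Empirical base frequencies of an alignment
#'
#' The "+F" frequencies: A/C/G/T counts over all rows, gaps and N excluded.
#'
#' @param alignment A [dna_alignment()].
#' @param pseudocount Added to each count so no frequency is exactly zero.
#' @return Named numeric vector summing to 1.
#' @export
empirical_base_freqs <- function(alignment, pseudocount = 0.5) {
  mat <- unclass(alignment)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(mat == b), numeric(1))
  counts <- counts + pseudocount
  counts / sum(counts)
}
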