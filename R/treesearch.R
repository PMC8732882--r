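ml_settings_default <- function() {
  list(gamma = TRUE, p_inv = TRUE, n_cat = 4L, tol = 1e-6,
       max_rounds = 20L, max_nni_rounds = 10L,
       bl_bounds = c(1e-8, 10), rate_bounds = c(1e-4, 200),
       alpha_bounds = c(0.02, 50), pinv_max = 0.9)
}

#' Maximum-likelihood tree settings
#'
#' @param gamma Use discrete-gamma rate heterogeneity (+G4)?
#' @param p_inv Estimate an invariant-site proportion (+I)?
#' @param n_cat Gamma categories.
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_rounds Maximum coordinate-descent rounds per topology.
#' @param max_nni_rounds Maximum accepted-NNI rounds.
#' @param optimize_topology Run NNI hill climbing (otherwise only branch
#'   lengths and model parameters are fit on the start topology)?
#' @return A settings list for [fit_and_search()].
#' @export
ml_settings <- function(gamma = TRUE, p_inv = TRUE, n_cat = 4L, tol = 1e-6,
                        max_rounds = 20L, max_nni_rounds = 10L,
                        optimize_topology = TRUE) {
  s <- ml_settings_default()
  s$gamma <- gamma
  s$p_inv <- p_inv
  s$n_cat <- as.integer(n_cat)
  s$tol <- tol
  s$max_rounds <- as.integer(max_rounds)
  s$max_nni_rounds <- if (optimize_topology) as.integer(max_nni_rounds) else 0L
  s
}

# JC69-corrected NJ start tree; saturated distances are capped, not dropped
nj_start_tree <- function(aln) {
  bin <- ape::as.DNAbin(unclass(aln))
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  cap <- max(3, 2 * max(dm[is.finite(dm)], na.rm = TRUE))
  dm[!is.finite(dm)] <- cap
  tree <- ape::nj(stats::as.dist(dm))
  tree <- ape::unroot(tree)
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  tree
}

# coordinate-wise optimization of branch lengths then model parameters;
# returns list(tree, model, loglik)
optimize_on_topology <- function(tree, pat, model, settings) {
  ll <- loglik_from_patterns(tree, pat, model)
  for (round in seq_len(settings$max_rounds)) {
    ll_before <- ll
    # branch lengths, in edge order
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        loglik_from_patterns(tree, pat, model)
      }
      opt <- optimize(f, interval = settings$bl_bounds, maximum = TRUE,
                      tol = 1e-7)
      if (opt$objective > ll) {
        tree$edge.length[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    # exchangeabilities (GT fixed at 1), on log scale
    for (r in c("AC", "AG", "AT", "CG", "CT")) {
      f <- function(lx) {
        m <- model
        m$rates[[r]] <- exp(lx)
        loglik_from_patterns(tree, pat, m)
      }
      opt <- optimize(f, interval = log(settings$rate_bounds), maximum = TRUE,
                      tol = 1e-5)
      if (opt$objective > ll) {
        model$rates[[r]] <- exp(opt$maximum)
        ll <- opt$objective
      }
    }
    # joint rescaling of the five free exchangeabilities relative to the
    # fixed GT rate: walks the rate-scale/branch-length ridge that
    # one-at-a-time moves traverse slowly
    f_scale <- function(lc) {
      m <- model
      m$rates[1:5] <- pmin(pmax(m$rates[1:5] * exp(lc),
                                settings$rate_bounds[1]),
                           settings$rate_bounds[2])
      loglik_from_patterns(tree, pat, m)
    }
    opt <- optimize(f_scale, interval = c(log(0.2), log(5)), maximum = TRUE,
                    tol = 1e-5)
    if (opt$objective > ll) {
      model$rates[1:5] <- pmin(pmax(model$rates[1:5] * exp(opt$maximum),
                                    settings$rate_bounds[1]),
                               settings$rate_bounds[2])
      ll <- opt$objective
    }
    # gamma shape
    if (settings$gamma) {
      f <- function(la) {
        m <- model
        m$alpha <- exp(la)
        loglik_from_patterns(tree, pat, m)
      }
      opt <- optimize(f, interval = log(settings$alpha_bounds), maximum = TRUE,
                      tol = 1e-5)
      if (opt$objective > ll) {
        model$alpha <- exp(opt$maximum)
        ll <- opt$objective
      }
    }
    # invariant proportion
    if (settings$p_inv) {
      f <- function(p) {
        m <- model
        m$p_inv <- p
        loglik_from_patterns(tree, pat, m)
      }
      opt <- optimize(f, interval = c(1e-6, settings$pinv_max), maximum = TRUE,
                      tol = 1e-5)
      if (opt$objective > ll) {
        model$p_inv <- opt$maximum
        ll <- opt$objective
      }
    }
    if (ll - ll_before < settings$tol) break
  }
  list(tree = tree, model = model, loglik = ll,
       converged = (ll - ll_before < settings$tol))
}

#' Fit a GTR+F+I+G4 maximum-likelihood tree
#'
#' Starts from a neighbor-joining tree on JC69 distances, fits branch lengths
#' and model parameters by bounded coordinate descent (golden-section line
#' searches, deterministic order: branch lengths, exchangeabilities, gamma
#' shape, invariant proportion), then hill-climbs over nearest-neighbor
#' interchanges, re-optimizing after every accepted move, until no NNI
#' improves the log-likelihood by more than `tol`. Base frequencies are
#' empirical ("+F"). Deterministic given the input.
#'
#' @param alignment A [dna_alignment()] with >= 4 taxa.
#' @param settings From [ml_settings()].
#' @return A `mito_ml_fit` object: `tree` (ape phylo), `model`
#'   ([phylo_model()]), `loglik`, `converged`, and the search trace
#'   (`n_nni_accepted`).
#' @export
fit_and_search <- function(alignment, settings = ml_settings()) {
  aln <- if (inherits(alignment, "dna_alignment")) alignment else dna_alignment(alignment)
  if (nrow(aln) < 4L) {
    abort("tree search needs >= 4 taxa", class = "mitochar_validation_error")
  }
  pat <- compress_patterns(aln)
  model <- phylo_model(
    base_freqs = empirical_base_freqs(aln),
    p_inv = if (settings$p_inv) 0.05 else 0,
    alpha = if (settings$gamma) 1 else Inf,
    n_cat = settings$n_cat
  )
  tree <- nj_start_tree(aln)
  fit <- optimize_on_topology(tree, pat, model, settings)
  n_acc <- 0L
  for (nni_round in seq_len(settings$max_nni_rounds)) {
    neighbors <- tryCatch(phangorn::nni(fit$tree), error = function(e) NULL)
    if (is.null(neighbors) || length(neighbors) == 0L) break
    best <- fit
    improved <- FALSE
    for (k in seq_along(neighbors)) {
      cand <- neighbors[[k]] # [[ re-attaches multiPhylo tip labels
      if (is.null(cand$edge.length)) {
        cand$edge.length <- rep(mean(fit$tree$edge.length), nrow(cand$edge))
      }
      cand$edge.length[cand$edge.length < 1e-8] <- 1e-8
      quick <- settings
      quick$max_rounds <- 2L
      cfit <- optimize_on_topology(cand, pat, fit$model, quick)
      if (cfit$loglik > best$loglik + settings$tol) {
        best <- cfit
        improved <- TRUE
      }
    }
    if (!improved) break
    fit <- optimize_on_topology(best$tree, pat, best$model, settings)
    n_acc <- n_acc + 1L
  }
  if (!fit$converged) {
    warn("coordinate descent stopped at max_rounds before reaching tol; returning best-so-far",
         class = "mitochar_convergence_warning")
  }
  structure(
    list(tree = fit$tree, model = fit$model, loglik = fit$loglik,
         converged = fit$converged, n_nni_accepted = n_acc,
         n_taxa = nrow(aln), n_sites = pat$n_sites,
         n_patterns = length(pat$weights)),
    class = "mito_ml_fit"
  )
}

#' @export
print.mito_ml_fit <- function(x, ...) {
  cat("<mito_ml_fit> ", x$n_taxa, " taxa, ", x$n_sites, " sites (",
      x$n_patterns, " patterns)\n", sep = "")
  cat("  logL: ", sprintf("%.4f", x$loglik),
      if (!x$converged) "  [not converged]", "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
tidy.mito_ml_fit <- function(x, ...) {
  bind_rows(
    tibble(term = paste0("rate_", names(x$model$rates)),
           estimate = unname(x$model$rates)),
    tibble(term = paste0("freq_", names(x$model$base_freqs)),
           estimate = unname(x$model$base_freqs)),
    tibble(term = c("p_inv", "alpha"),
           estimate = c(x$model$p_inv, x$model$alpha))
  )
}

#' @export
glance.mito_ml_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_taxa = x$n_taxa, n_sites = x$n_sites,
         n_patterns = x$n_patterns, converged = x$converged,
         n_nni_accepted = x$n_nni_accepted)
}

#' Nonparametric bootstrap supports
#'
#' Standard Felsenstein bootstrap: alignment columns are resampled with
#' replacement, the full search is rerun per replicate, and each original
#' internal branch's support is the percentage of replicate trees containing
#' its bipartition. Supports are written to `tree$node.label`.
#'
#' @param alignment A [dna_alignment()].
#' @param settings From [ml_settings()]; replicates usually use lighter
#'   settings than the reference fit.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; resampling is deterministic given it.
#' @param fit Optionally, an existing reference [fit_and_search()] fit.
#' @return The reference `mito_ml_fit` with `tree$node.label` holding supports
#'   in `[0, 100]` (root label empty) and element `replicate_trees`.
#' @export
bootstrap_support <- function(alignment, settings = ml_settings(),
                              replicates = 100L, seed = 1L, fit = NULL) {
  if (replicates < 1L) {
    abort("replicates must be >= 1", class = "mitochar_validation_error")
  }
  aln <- if (inherits(alignment, "dna_alignment")) alignment else dna_alignment(alignment)
  mat <- unclass(aln)
  if (all(apply(mat, 2L, function(col) length(unique(col[col %in% c("A","C","G","T")])) <= 1L))) {
    warn("no variable sites: bootstrap supports are undefined",
         class = "mitochar_degenerate_warning")
  }
  if (is.null(fit)) fit <- fit_and_search(aln, settings)
  boot_trees <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      fit_and_search(dna_alignment(mat[, cols, drop = FALSE]), settings)$tree
    })
  })
  ref <- fit$tree
  counts <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates, 1)
  ref$node.label <- as.character(support)
  ref$node.label[1] <- ""
  fit$tree <- ref
  fit$replicate_trees <- boot_trees
  fit
}

#' Classify a taxon set as mono-, para- or polyphyletic
#'
#' On the tree rooted at `outgroup`: the group is monophyletic if it is
#' exactly the tip set of a clade; otherwise paraphyletic if the non-group
#' tips inside the group's minimal spanning clade themselves form a single
#' clade (one nested "intruder" lineage); otherwise polyphyletic.
#'
#' @param tree An `ape::phylo` tree.
#' @param group Character vector of tip labels (nonempty, proper subset).
#' @param outgroup Tip label(s) to root on; `NULL` if `tree` is already
#'   rooted as intended.
#' @return `"monophyletic"`, `"paraphyletic"` or `"polyphyletic"`.
#' @export
classify_group <- function(tree, group, outgroup = NULL) {
  tips <- tree$tip.label
  group <- unique(group)
  if (length(group) == 0L || !all(group %in% tips)) {
    missing <- setdiff(group, tips)
    abort(paste0("group is empty or contains unknown taxa",
                 if (length(missing)) paste0(": ", paste(missing, collapse = ", "))),
          class = "mitochar_validation_error")
  }
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% tips)) {
      abort(paste0("unknown outgroup taxon: ",
                   paste(setdiff(outgroup, tips), collapse = ", ")),
            class = "mitochar_validation_error")
    }
    if (any(outgroup %in% group)) {
      abort("outgroup taxa cannot be inside the tested group",
            class = "mitochar_validation_error")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  clade_tips <- function(node) {
    if (node <= length(tips)) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  span_tips <- if (length(group) == 1L) {
    group
  } else {
    clade_tips(ape::getMRCA(tree, group))
  }
  if (setequal(span_tips, group)) return("monophyletic")
  intruders <- setdiff(span_tips, group)
  intruder_span <- if (length(intruders) == 1L) {
    intruders
  } else {
    clade_tips(ape::getMRCA(tree, intruders))
  }
  if (setequal(intruder_span, intruders)) "paraphyletic" else "polyphyletic"
}

#' Write a tree with supports as Newick
#'
#' Supports (if present) are kept as internal node labels; branch lengths are
#' written with 6 significant digits.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- signif(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
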