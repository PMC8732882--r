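test_that("NJ on an exactly additive matrix returns the generating topology", {
  set.seed(37)
  for (rep in 1:3) {
    tree <- ape::rtree(sample(4:7, 1), br = function(n) runif(n, 0.1, 0.5))
    tree <- ape::unroot(tree)
    d <- ape::cophenetic.phylo(tree) # additive by construction
    nj <- ape::nj(stats::as.dist(d))
    expect_equal(phangorn::RF.dist(ape::unroot(nj), tree), 0)
  }
})

test_that("search recovers a simulated 6-taxon topology", {
  set.seed(41)
  true_tree <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.05, 0.25)))
  model <- phylo_model(rates = c(1.5, 4, 0.9, 1.2, 5, 1),
                       base_freqs = c(0.32, 0.28, 0.14, 0.26),
                       p_inv = 0, alpha = 0.8)
  seqs <- evolve_sequences(800L, true_tree, model, seed = 43)
  fit <- suppressWarnings(fit_and_search(
    dna_alignment(seqs),
    ml_settings(p_inv = FALSE, max_rounds = 4, max_nni_rounds = 3)
  ))
  expect_s3_class(fit, "mito_ml_fit")
  expect_equal(phangorn::RF.dist(fit$tree, true_tree), 0)
  expect_true(all(fit$tree$edge.length >= 0))
  expect_setequal(fit$tree$tip.label, names(seqs))
})

test_that("identical sequences give a near-zero-length tree", {
  seqs <- setNames(rep(strrep("ACGT", 100), 5), paste0("t", 1:5))
  fit <- suppressWarnings(fit_and_search(
    dna_alignment(seqs), ml_settings(gamma = FALSE, p_inv = FALSE,
                                     max_rounds = 2, optimize_topology = FALSE)
  ))
  expect_lt(sum(fit$tree$edge.length), 1e-4)
})

test_that("tidy and glance expose the fitted model", {
  set.seed(47)
  tree <- ape::unroot(ape::rtree(4, br = function(n) runif(n, 0.1, 0.3)))
  seqs <- evolve_sequences(300L, tree, phylo_model(alpha = 1), seed = 5)
  fit <- suppressWarnings(fit_and_search(
    dna_alignment(seqs), ml_settings(gamma = FALSE, p_inv = FALSE,
                                     max_rounds = 2, optimize_topology = FALSE)
  ))
  td <- tidy(fit)
  expect_setequal(td$term,
                  c(paste0("rate_", c("AC", "AG", "AT", "CG", "CT", "GT")),
                    paste0("freq_", c("A", "C", "G", "T")), "p_inv", "alpha"))
  expect_equal(td$estimate[td$term == "rate_GT"], 1)
  gl <- glance(fit)
  expect_equal(gl$n_taxa, 4L)
  expect_equal(gl$n_sites, 300L)
  expect_true(is.finite(gl$logLik))
})

test_that("bootstrap supports strong signal and stays in range", {
  set.seed(53)
  true_tree <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.08, 0.2)))
  seqs <- evolve_sequences(600L, true_tree, phylo_model(), seed = 59)
  light <- ml_settings(gamma = FALSE, p_inv = FALSE, max_rounds = 2,
                       max_nni_rounds = 1)
  fit <- suppressWarnings(
    bootstrap_support(dna_alignment(seqs), light, replicates = 10, seed = 61)
  )
  support <- suppressWarnings(as.numeric(fit$tree$node.label))
  support <- support[is.finite(support)]
  expect_true(all(support >= 0 & support <= 100))
  # clean long alignment: every true split strongly supported
  expect_true(all(support >= 95))
  expect_equal(phangorn::RF.dist(fit$tree, true_tree), 0)
  expect_error(bootstrap_support(dna_alignment(seqs), light, replicates = 0),
               class = "mitochar_validation_error")
})

test_that("zero variable sites flag the bootstrap as degenerate", {
  seqs <- setNames(rep(strrep("AAGG", 50), 4), paste0("t", 1:4))
  light <- ml_settings(gamma = FALSE, p_inv = FALSE, max_rounds = 1,
                       optimize_topology = FALSE)
  expect_warning(
    suppressWarnings(
      bootstrap_support(dna_alignment(seqs), light, replicates = 2, seed = 1),
      classes = c("mitochar_convergence_warning")
    ),
    class = "mitochar_degenerate_warning"
  )
})

test_that("group classification follows the clade definition", {
  # monophyly: exact clade
  t1 <- ape::read.tree(text = "((A1,A2),(B,C));")
  expect_equal(classify_group(t1, c("A1", "A2"), outgroup = "C"),
               "monophyletic")
  # paraphyly: one nested intruder lineage
  t2 <- ape::read.tree(text = "((A1,(A2,B)),C);")
  expect_equal(classify_group(t2, c("A1", "A2"), outgroup = "C"),
               "paraphyletic")
  # polyphyly: intruders do not form a single clade
  t3 <- ape::read.tree(text = "(((A1,B1),(A2,B2)),O);")
  expect_equal(classify_group(t3, c("A1", "A2"), outgroup = "O"),
               "polyphyletic")
  # errors
  expect_error(classify_group(t1, c("A1", "C"), outgroup = "C"),
               class = "mitochar_validation_error")
  expect_error(classify_group(t1, "nope", outgroup = "C"),
               class = "mitochar_validation_error")
})

test_that("classification matches the set-logic oracle on all 5-leaf trees", {
  # oracle: enumerate clades as the rooted tree's bipartition tip sets and
  # apply the definition literally
  oracle_classify <- function(tree, group) {
    clades <- lapply(ape::prop.part(tree), function(idx) tree$tip.label[idx])
    clades <- c(clades, as.list(tree$tip.label)) # singletons are clades
    is_clade <- function(s) any(vapply(clades, setequal, logical(1), s))
    if (is_clade(group)) return("monophyletic")
    spanning <- clades[[which.min(vapply(clades, function(cl) {
      if (all(group %in% cl)) length(cl) else Inf
    }, numeric(1)))]]
    intruders <- setdiff(spanning, group)
    if (is_clade(intruders)) "paraphyletic" else "polyphyletic"
  }
  trees <- phangorn::allTrees(4, rooted = TRUE,
                              tip.label = c("A1", "A2", "B1", "B2"))
  groups <- list(c("A1", "A2"), c("A1", "A2", "B1"), "A1")
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]] # [[ re-attaches multiPhylo tip labels
    for (g in groups) {
      expect_equal(classify_group(tr, g, outgroup = NULL),
                   oracle_classify(tr, g),
                   info = paste(ape::write.tree(tr), paste(g, collapse = ",")))
    }
  }
})

test_that("the whole tip set and singletons are monophyletic", {
  t1 <- ape::read.tree(text = "((A1,(A2,B)),C);")
  expect_equal(classify_group(t1, t1$tip.label), "monophyletic")
  for (tip in t1$tip.label) {
    expect_equal(classify_group(t1, tip), "monophyletic")
  }
})

test_that("newick output keeps supports and 6-significant-digit lengths", {
  tree <- ape::read.tree(text = "((a:0.123456789,b:0.2):0.111111119,c:0.3);")
  tree$node.label <- c("", "87")
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tf)
  txt <- readLines(tf)
  expect_match(txt, "87")
  expect_match(txt, "0.123457")
  back <- ape::read.tree(tf)
  expect_equal(phangorn::RF.dist(back, tree), 0)
})
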