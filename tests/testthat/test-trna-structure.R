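test_that("anticodons decode through the vertebrate mitochondrial code", {
  expect_equal(anticodon_to_amino_acid("GAA"), "Phe")
  expect_equal(anticodon_to_amino_acid("UAA"), "Leu")
  expect_equal(anticodon_to_amino_acid("CAU"), "Met")
  expect_equal(anticodon_to_amino_acid("UCA"), "Trp") # TGA = Trp in this code
  # UUA reads TAA, a stop
  expect_error(anticodon_to_amino_acid("UUA"), class = "mitochar_validation_error")
  expect_error(anticodon_to_amino_acid("XYZ"), class = "mitochar_validation_error")
})

test_that("constructed tRNAs fold back to their construction arms", {
  set.seed(123)
  hits <- 0L
  n_trials <- 40L
  for (i in seq_len(n_trials)) {
    len <- sample(62:80, 1)
    g <- generate_trna("GAA", length = len, dhu_present = TRUE, seed = 1000L + i)
    cl <- fold_cloverleaf(g$sequence, "GAA")
    expect_false(cl$degenerate)
    expect_equal(cl$anticodon_arm$anticodon, "GAA")
    truth_score <- with(g$truth$geometry, a + d + c + t)
    # the fold either recovers the construction or finds an equally good or
    # better placement; it can never score below the construction
    expect_gte(cl$score, truth_score)
    same_arms <- identical(unname(cl$acceptor_stem$stem5[2]),
                           g$truth$acceptor_stem5[2]) &&
      identical(unname(cl$dhu_arm$stem5), g$truth$dhu_stem5) &&
      identical(unname(cl$anticodon_arm$stem5), g$truth$anticodon_stem5) &&
      identical(unname(cl$tpsic_arm$stem5), g$truth$tpsic_stem5)
    if (same_arms) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("DHU-less construction yields a degenerate cloverleaf", {
  g <- generate_trna("GCU", length = 59, dhu_present = FALSE, seed = 77)
  cl <- fold_cloverleaf(g$sequence, "GCU")
  expect_true(cl$degenerate)
  expect_null(cl$dhu_arm)
  expect_equal(cl$anticodon_arm$anticodon, "GCU")
})

test_that("fold score equals the exhaustive-placement oracle", {
  set.seed(31)
  cases <- list()
  # structured cases: clean tRNAs and mutated copies that perturb stems
  for (i in 1:6) {
    g <- generate_trna("GAA", length = sample(60:75, 1), seed = 400L + i)
    cases[[length(cases) + 1L]] <- g$sequence
    mut <- strsplit(g$sequence, "")[[1]]
    pos <- sample(seq_along(mut), 3)
    mut[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    cases[[length(cases) + 1L]] <- paste(mut, collapse = "")
  }
  for (s in cases) {
    oracle <- oracle_cloverleaf_best(s)
    got <- tryCatch(fold_cloverleaf(s), error = function(e) NULL)
    if (is.null(got)) {
      expect_true(!is.finite(oracle$full) && !is.finite(oracle$degen))
    } else if (got$degenerate) {
      expect_true(!is.finite(oracle$full))
      expect_equal(got$score, oracle$degen)
    } else {
      expect_equal(got$score, oracle$full)
    }
  }
})

test_that("anticodon constraint failures name the constraint", {
  g <- generate_trna("GAA", length = 70, seed = 5)
  expect_error(fold_cloverleaf(g$sequence, "CCC"), "anticodon",
               class = "mitochar_fold_error")
  expect_error(fold_cloverleaf(strrep("A", 70)), class = "mitochar_fold_error")
  expect_error(fold_cloverleaf(random_dna(30)), class = "mitochar_validation_error")
})

test_that("returned pairs are WC or G.U and positions pair at most once", {
  for (i in 1:5) {
    g <- generate_trna("UUC", length = 68, seed = 600L + i)
    cl <- fold_cloverleaf(g$sequence)
    ch <- strsplit(cl$sequence, "")[[1]]
    all_pairs <- c(cl$acceptor_stem$pairs, cl$anticodon_arm$pairs,
                   cl$tpsic_arm$pairs,
                   if (!cl$degenerate) cl$dhu_arm$pairs)
    expect_equal(length(all_pairs), cl$score)
    seen <- unlist(all_pairs)
    expect_false(anyDuplicated(seen) > 0)
    ok_pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
    for (p in all_pairs) {
      expect_true(paste0(ch[p[1]], ch[p[2]]) %in% ok_pairs)
    }
  }
})

test_that("structure report counts degenerate folds and conserves pairs", {
  folds <- c(
    lapply(1:4, function(i) {
      fold_cloverleaf(generate_trna("GAA", length = 70, seed = 700L + i)$sequence)
    }),
    list(fold_cloverleaf(
      generate_trna("GCU", length = 59, dhu_present = FALSE, seed = 99)$sequence))
  )
  names(folds) <- paste0("t", 1:5)
  rep <- structure_report(folds)
  expect_equal(nrow(rep), 5L)
  expect_equal(attr(rep, "n_degenerate"), 1L)
  expect_equal(rep$pairs, vapply(folds, function(f) f$score, integer(1)),
               ignore_attr = TRUE)
  # dot-bracket is balanced with one character per base
  expect_equal(nchar(rep$dot_bracket), rep$length)
  n_open <- vapply(strsplit(rep$dot_bracket, ""),
                   function(v) sum(v == "("), integer(1))
  expect_equal(n_open, rep$pairs, ignore_attr = TRUE)

  empty <- structure_report(list())
  expect_equal(nrow(empty), 0L)
})

test_that("a full annotated genome folds its 22 tRNAs", {
  gen <- generate_mitogenome(default_genome_template(), seed = 3)
  folds <- suppressWarnings(fold_genome_trnas(gen$genome))
  expect_length(folds, 22L)
  rep <- structure_report(folds)
  # construction guarantees foldability except where an overlapping gene
  # overwrote part of a tRNA span (the plan has a few such overlaps)
  expect_gte(nrow(rep), 18L)
  expect_lte(attr(rep, "n_degenerate"), 3L)
  expect_lte(attr(rep, "n_unfoldable"), 4L)
})
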