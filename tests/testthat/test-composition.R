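test_that("skew formulas match their definition and the printed table rows", {
  # protein-coding pooled row and the L-strand ND6 row of the printed table
  expect_equal(round_half_up(at_skew(31.84, 25.53), 4), 0.1100)
  expect_equal(round_half_up(gc_skew(13.28, 29.35), 4), -0.3770)
  expect_equal(round_half_up(at_skew(16.38, 42.48), 4), -0.4434)
  expect_equal(round_half_up(gc_skew(32.57, 8.57), 4), 0.5834)
  for (x in c(0.5, 3, 42)) {
    expect_equal(at_skew(x, x), 0)
    expect_equal(gc_skew(x, x), 0)
  }
  expect_warning(expect_true(is.na(at_skew(0, 0))),
                 class = "mitochar_skew_warning")
  # scale invariance: counts and derived percentages give identical skew
  set.seed(4)
  for (i in 1:10) {
    counts <- sample(1:500, 2)
    pct <- 100 * counts / sum(counts)
    expect_equal(at_skew(counts[1], counts[2]), at_skew(pct[1], pct[2]))
  }
})

test_that("base composition counts exclude N and match a direct tally", {
  row <- suppressWarnings(base_composition("AATT")) # G+C = 0 warns
  expect_equal(row$pct_a, 50)
  expect_equal(row$pct_t, 50)
  expect_equal(row$at_skew, 0)
  expect_equal(suppressWarnings(base_composition("GGGC"))$gc_skew, 0.5)

  set.seed(7)
  s <- paste0(random_dna(10000), "NNNN")
  row <- base_composition(s)
  tally <- table(strsplit(s, "")[[1]]) # independent single-pass counter
  denom <- sum(tally[c("A", "C", "G", "T")])
  expect_equal(row$pct_a, 100 * tally[["A"]] / denom)
  expect_equal(row$pct_g, 100 * tally[["G"]] / denom)
  expect_equal(row$at_skew,
               (tally[["A"]] - tally[["T"]]) / (tally[["A"]] + tally[["T"]]))
  expect_equal(row$n_n, 4L)
  expect_error(base_composition(""), class = "mitochar_validation_error")
  expect_error(base_composition("NNN"), class = "mitochar_validation_error")
})

test_that("every printed composition row's skews recompute at 4-dp rounding", {
  printed <- mpp_composition()
  re <- skews_from_percentages(printed)
  expect_equal(re$at_skew_recomputed, printed$at_skew)
  expect_equal(re$gc_skew_recomputed, printed$gc_skew)
  # printed percentages are internally consistent up to one known misprint:
  # the COX1 row sums to 99.00, not 100 (its skews still recompute from the
  # printed values); A+T always matches the printed A+T column
  sums <- printed$pct_a + printed$pct_c + printed$pct_g + printed$pct_t
  expect_true(all(abs(sums - 100) < 0.03 | printed$label == "COX1"))
  expect_equal(sums[printed$label == "COX1"], 99)
  expect_true(all(abs(printed$pct_a + printed$pct_t - printed$pct_at) < 0.02))
})

test_that("reverse complementation flips both skews exactly", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_dna(300)
    fwd <- base_composition(s)
    rev <- base_composition(reverse_complement(s))
    expect_equal(rev$at_skew, -fwd$at_skew)
    expect_equal(rev$gc_skew, -fwd$gc_skew)
  }
})

test_that("composition report pools coding-strand sequences", {
  tpl <- default_genome_template()
  gen <- generate_mitogenome(tpl, seed = 55)
  rep <- composition_report(gen$genome, digits_pct = NULL, digits_skew = NULL)
  expect_equal(rep$label[1], "whole genome")
  expect_equal(rep$length_bp[rep$label == "whole genome"], 16570L)
  expect_equal(rep$length_bp[rep$label == "protein-coding genes"], 11396L)
  expect_equal(rep$length_bp[rep$label == "ribosomal RNA"], 960L + 1566L)
  # pooled percentages land near the generator's targets; codon-level
  # rejection of stop codons biases PCG composition slightly off-target
  pcg <- rep[rep$label == "protein-coding genes", ]
  expect_lt(abs(pcg$pct_a - 31.84), 2.5)
  expect_lt(abs(pcg$pct_g - 13.28), 2.5)
})

test_that("an L-strand gene with H-typical content shows inverted skews", {
  # A-rich, C-rich H-strand region annotated on the L strand: composed on its
  # coding strand the skews flip sign, the ND6 signature
  set.seed(11)
  h_rich <- random_dna(600, freqs = c(0.40, 0.30, 0.10, 0.20))
  feats <- tibble::tibble(name = "ND6-like", category = "PCG", from = 1L,
                          to = 600L, anticodon = NA_character_, strand = "L")
  h_row <- base_composition(h_rich)
  l_row <- base_composition(extract_feature(h_rich, feats[1, ]))
  expect_gt(h_row$at_skew, 0)
  expect_lt(h_row$gc_skew, 0)
  expect_lt(l_row$at_skew, 0)
  expect_gt(l_row$gc_skew, 0)
})

test_that("codon usage counts frames and computes RSCU", {
  u <- suppressWarnings(codon_usage(c(x = "ATGATGTAA")))
  expect_equal(u$count[u$codon == "ATG"], 2L)
  expect_equal(u$count[u$codon == "TAA"], 1L)
  expect_true(is.na(u$rscu[u$codon == "TAA"])) # stops carry no RSCU
  expect_equal(sum(u$count), 3L)

  # uniformly used family -> all RSCU 1 (Ala: GCT GCC GCA GCG)
  u2 <- codon_usage(c(x = paste0("ATG", "GCTGCCGCAGCG", "TAA")))
  ala <- u2[u2$amino_acid == "A", ]
  expect_equal(ala$rscu, rep(1, 4))

  # incomplete trailing codon from a T-- stop is ignored
  u3 <- codon_usage(c(x = paste0("ATG", "GCTGCC", "T")))
  expect_equal(sum(u3$count), 3L)

  # internal stop warns with sequence name and position
  expect_warning(codon_usage(c(bad = "ATGTAAGCTTAA")),
                 "bad.*codon position 2",
                 class = "mitochar_internal_stop_warning")
})

test_that("RSCU equals a hand-computed tally on a longer coding sequence", {
  set.seed(12)
  code <- mito_genetic_code()
  sense <- setdiff(names(code$map), code$stops)
  codons <- sample(sense, 60, replace = TRUE)
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  u <- suppressWarnings(codon_usage(setNames(cds, "toy")))
  # independent tally oracle
  counts <- table(factor(c(codons, "TAA"), levels = names(code$map)))
  fam <- split(names(code$map), code$map)
  for (codon in names(code$map)) {
    expect_equal(u$count[u$codon == codon], unname(counts[[codon]]))
    aa <- code$map[[codon]]
    if (aa != "*") {
      fam_counts <- counts[fam[[aa]]]
      expected <- if (sum(fam_counts) == 0) NA_real_ else
        unname(counts[[codon]] / mean(fam_counts))
      expect_equal(u$rscu[u$codon == codon], expected)
    }
  }
})
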