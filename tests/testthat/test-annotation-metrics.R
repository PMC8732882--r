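# printed per-gene lengths of the 13 protein-coding genes, the two rRNAs and
# the shortest tRNA in the reference annotation table
PCG_LENGTHS <- c(
  ND1 = 957L, ND2 = 1039L, COX1 = 1551L, COX2 = 684L, ATP8 = 201L,
  ATP6 = 681L, COX3 = 784L, ND3 = 347L, ND4L = 297L, ND4 = 1378L,
  ND5 = 1812L, ND6 = 525L, CYTB = 1140L
)

test_that("gene lengths are closed-interval arithmetic", {
  expect_equal(gene_length(7759, 7959), 201L) # shortest PCG (ATP8)
  expect_equal(gene_length(11743, 13554), 1812L) # longest PCG (ND5)
  expect_equal(gene_length(5, 5), 1L)
})

test_that("intergenic values reproduce the printed table convention", {
  feats <- mpp_features()
  ig <- intergenic_nucleotides(feats)
  names(ig) <- feats$name
  expect_equal(ig[["ATP6"]], -40L)   # 40 bp overlap with ATP8
  expect_equal(ig[["12S ribosomal RNA"]], 0L) # abuts tRNA-Phe
  expect_equal(ig[["tRNA-Lys"]], 2L) # spacer after COX2
  expect_equal(ig[["ND2"]], -27L)
  expect_equal(ig[["tRNA-Trp"]], 27L)
  expect_equal(ig[["tRNA-Cys"]], 32L)
  expect_equal(ig[["D_loop"]], 113L)
  expect_equal(ig[[1]], 0L) # first-row convention

  # translation invariance: shifting all coordinates leaves spacing unchanged
  shifted <- dplyr::mutate(feats, from = from + 1000L, to = to + 1000L)
  expect_equal(intergenic_nucleotides(shifted), ig, ignore_attr = TRUE)
  expect_equal(intergenic_nucleotides(feats[0, ]), integer(0))
})

test_that("start codons are detected and classified as ATN", {
  expect_equal(detect_start_codon("ATGAAACCC"), list(codon = "ATG", is_atn = TRUE))
  expect_equal(detect_start_codon("ATAAAACCC"), list(codon = "ATA", is_atn = TRUE))
  expect_equal(detect_start_codon("GTGAAACCC"), list(codon = "GTG", is_atn = FALSE))
  expect_error(detect_start_codon("AT"), class = "mitochar_validation_error")
})

test_that("stop codons classify complete and incomplete cases by frame", {
  code <- mito_genetic_code()
  body <- strrep("GCT", 10)
  expect_equal(classify_stop_codon(paste0("ATG", body, "TAA"), code), "TAA")
  expect_equal(classify_stop_codon(paste0("ATG", body, "AGA"), code), "AGA")
  expect_equal(classify_stop_codon(paste0("ATG", body, "T"), code), "T--")
  expect_equal(classify_stop_codon(paste0("ATG", body, "TA"), code), "TA-")
  # inconsistent annotations raise errors naming the gene
  expect_error(classify_stop_codon(paste0("ATG", body, "CCC"), code, gene = "ND9"),
               "ND9", class = "mitochar_annotation_error")
  expect_error(classify_stop_codon(paste0("ATG", body, "A"), code),
               class = "mitochar_annotation_error")
  expect_error(classify_stop_codon(paste0("ATG", body, "AT"), code),
               class = "mitochar_annotation_error")
})

test_that("coordinate arithmetic reproduces every printed length and spacer", {
  tab <- characterize_coordinates(mpp_features())
  pcg <- tab[tab$category == "PCG", ]
  expect_equal(setNames(pcg$length_bp, pcg$name), PCG_LENGTHS)
  expect_equal(sum(pcg$length_bp), 11396L) # concatenated PCG total
  rrna <- tab[tab$category == "rRNA", ]
  expect_equal(rrna$length_bp, c(960L, 1566L))
  expect_equal(min(tab$length_bp[tab$category == "tRNA"]), 59L)
  expect_equal(max(tab$to), 16570L)
})

test_that("PCG stop labels in the reference table satisfy the frame rule", {
  feats <- mpp_features()
  pcg <- feats[feats$category == "PCG", ]
  expected_rem <- c("TAA" = 0L, "TAG" = 0L, "AGA" = 0L, "AGG" = 0L,
                    "T--" = 1L, "TA-" = 2L)
  expect_equal(gene_length(pcg$from, pcg$to) %% 3L,
               unname(expected_rem[pcg$stop_codon]))
})

test_that("characterize() on a synthetic genome matches the plan exactly", {
  tpl <- default_genome_template()
  gen <- generate_mitogenome(tpl, seed = 101)
  tab <- characterize(gen$genome)
  expect_equal(nrow(tab), 38L)
  expect_equal(tab$length_bp, tpl$length_bp)
  expect_equal(tab$intergenic, tpl$spacing)
  pcg <- tab$category == "PCG"
  expect_equal(tab$start_codon[pcg], tpl$start_codon[pcg])
  expect_equal(tab$stop_codon[pcg], tpl$stop_codon[pcg])
  expect_equal(attr(tab, "genome_length"), 16570L)
  # circular wrap-around gap reported separately, not as a row
  expect_equal(attr(tab, "circular_gap"), 0L)
})

test_that("non-ATN starts warn instead of erroring", {
  feats <- tibble::tibble(name = "odd", category = "PCG", from = 1L, to = 9L,
                          anticodon = NA_character_, strand = "H")
  g <- mitogenome("g", "GTGAAATAA", feats)
  expect_warning(tab <- characterize(g), "GTG",
                 class = "mitochar_start_codon_warning")
  expect_equal(tab$start_codon, "GTG")
})

test_that("strand/category counts match the reference annotation", {
  counts <- count_by_strand_and_category(mpp_features())
  get <- function(cat, str) counts$n[counts$category == cat & counts$strand == str]
  expect_equal(get("PCG", "H"), 12L)
  expect_equal(get("PCG", "L"), 1L) # ND6
  expect_equal(sum(counts$n[counts$category == "tRNA"]), 22L)
  expect_equal(get("rRNA", "H"), 2L)
  empty <- count_by_strand_and_category(mpp_features()[0, ])
  expect_true(all(empty$n == 0L))
})
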