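usage_error <- function(msg) abort(msg, class = "mitochar_usage_error")

config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

# run.log content is timestamp-free so identical runs are byte-identical
write_run_log <- function(out_dir, stage, config, warnings) {
  lines <- c(
    paste0("stage: ", stage),
    paste0("mitochar version: ",
           as.character(utils::packageVersion("mitochar"))),
    paste0("config hash: ", config_hash(config)),
    paste0("config: ", jsonlite::toJSON(config, auto_unbox = TRUE,
                                        null = "null", force = TRUE)),
    if (length(warnings)) paste0("warning: ", warnings) else "warnings: none"
  )
  writeLines(lines, file.path(out_dir, "run.log"))
}

collect_warnings <- function(expr) {
  msgs <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = msgs)
}

load_annotated_genome <- function(genome_fasta, features_tsv, id = NULL) {
  if (is.null(genome_fasta) || is.null(features_tsv)) {
    usage_error("both a genome FASTA and a feature table are required")
  }
  if (!file.exists(genome_fasta)) {
    usage_error(paste0("genome FASTA not found: ", genome_fasta))
  }
  if (!file.exists(features_tsv)) {
    usage_error(paste0("feature table not found: ", features_tsv))
  }
  fa <- read_fasta(genome_fasta)
  feats <- read_feature_table(features_tsv)
  mitogenome(id %||% fa$id[1], fa$sequence[1], feats)
}

#' Run the characterization stage
#'
#' The paper-shaped characterization workflow on one annotated genome:
#' annotation-table metrics, per-region composition/skew, codon usage and tRNA
#' cloverleaf structures, written as TSVs plus a `run.log` carrying the
#' package version, a config hash and any warnings. Outputs are deterministic:
#' the same inputs give byte-identical files.
#'
#' @param genome_fasta Path to the genome FASTA (first record used), or `NULL`
#'   when `genome` is given.
#' @param features_tsv Path to the feature TSV, or `NULL` when `genome` is
#'   given.
#' @param out_dir Output directory (created if needed).
#' @param genome Optionally, a ready [mitogenome()] instead of the two paths.
#' @param digits_pct,digits_skew Display rounding for the composition table.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_characterize <- function(genome_fasta = NULL, features_tsv = NULL,
                             out_dir = "mitochar_out", genome = NULL,
                             digits_pct = 2, digits_skew = 4) {
  config <- list(stage = "characterize", genome_fasta = genome_fasta,
                 features_tsv = features_tsv, digits_pct = digits_pct,
                 digits_skew = digits_skew)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genome)) {
    genome <- load_annotated_genome(genome_fasta, features_tsv)
  }
  res <- collect_warnings({
    table1 <- characterize(genome)
    table2 <- composition_report(genome, digits_pct, digits_skew)
    usage <- genome_codon_usage(genome)
    folds <- fold_genome_trnas(genome)
    list(table1 = table1, table2 = table2, usage = usage,
         trna = structure_report(folds))
  })
  paths <- list(
    table1 = file.path(out_dir, "table1.tsv"),
    table2 = file.path(out_dir, "table2.tsv"),
    codon_usage = file.path(out_dir, "codon_usage.tsv"),
    trna_structures = file.path(out_dir, "trna_structures.tsv"),
    run_log = file.path(out_dir, "run.log")
  )
  write_characterization_table(res$value$table1, paths$table1)
  write.table(as.data.frame(res$value$table2), paths$table2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(res$value$usage), paths$codon_usage, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(res$value$trna), paths$trna_structures,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, "characterize", config, res$warnings)
  invisible(paths)
}

#' Run the phylogenetic stage
#'
#' Aligns homologous sequences (per-gene for `genes = "pcg13"`, whole genome
#' for `genes = "full"`, or a pre-aligned FASTA), fits a GTR+F+I+G4
#' maximum-likelihood tree with NNI search, optionally bootstraps, and
#' classifies requested groups as mono-/para-/polyphyletic. Writes
#' `alignment.fasta`, `tree.nwk`, `model.tsv`, optionally `monophyly.tsv`,
#' and `run.log`.
#'
#' @param genomes Named list of [mitogenome()] objects (>= 4), or `NULL` when
#'   `aligned_fasta` is given.
#' @param aligned_fasta Path to a pre-aligned multi-FASTA.
#' @param out_dir Output directory.
#' @param genes `"pcg13"` (concatenate the 13 protein-coding genes, aligned
#'   per gene) or `"full"` (whole genome sequences).
#' @param settings [ml_settings()].
#' @param bootstrap Bootstrap replicates (0 = skip).
#' @param seed Seed for bootstrap resampling.
#' @param groups Named list of taxon vectors to classify.
#' @param outgroup Outgroup taxon (or taxa) used to root for classification.
#' @return Invisibly, a list with the fit, the alignment and the file paths.
#' @export
run_phylo <- function(genomes = NULL, aligned_fasta = NULL,
                      out_dir = "mitochar_out", genes = c("pcg13", "full"),
                      settings = ml_settings(), bootstrap = 0L, seed = 1L,
                      groups = NULL, outgroup = NULL) {
  genes <- match.arg(genes)
  config <- list(stage = "phylo", genes = genes, bootstrap = bootstrap,
                 seed = seed, aligned_fasta = aligned_fasta,
                 groups = groups, outgroup = outgroup)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings({
    if (!is.null(aligned_fasta)) {
      fa <- read_fasta(aligned_fasta)
      aln <- dna_alignment(setNames(fa$sequence, fa$id))
    } else {
      if (is.null(genomes) || length(genomes) < 4L) {
        usage_error("phylo stage needs >= 4 genomes (or a pre-aligned FASTA)")
      }
      if (is.null(names(genomes))) {
        names(genomes) <- vapply(genomes, function(g) g$id, character(1))
      }
      aln <- if (genes == "full") {
        progressive_align(vapply(genomes, function(g) g$sequence, character(1)))
      } else {
        pcg_names <- genomes[[1]]$features$name[
          genomes[[1]]$features$category == "PCG"]
        blocks <- lapply(pcg_names, function(gene) {
          seqs <- vapply(genomes, function(g) {
            row <- g$features[g$features$name == gene, ]
            if (nrow(row) == 0L) {
              abort(paste0("taxon '", g$id, "' lacks gene '", gene, "'"),
                    class = "mitochar_validation_error")
            }
            extract_feature(g, row[1, ])
          }, character(1))
          if (length(unique(nchar(seqs))) == 1L) {
            dna_alignment(seqs)
          } else {
            progressive_align(seqs)
          }
        })
        names(blocks) <- pcg_names
        concatenate_genes(blocks)
      }
    }
    if (nrow(aln) < 4L) {
      abort("phylogeny needs >= 4 taxa", class = "mitochar_validation_error")
    }
    fit <- if (bootstrap > 0L) {
      bootstrap_support(aln, settings, replicates = bootstrap, seed = seed)
    } else {
      fit_and_search(aln, settings)
    }
    mono <- NULL
    if (!is.null(groups)) {
      mono <- purrr::imap(groups, function(members, label) {
        cls <- classify_group(fit$tree, members, outgroup)
        tibble(group = label, taxa = paste(members, collapse = ","),
               classification = cls)
      }) |> bind_rows()
    }
    list(aln = aln, fit = fit, mono = mono)
  })
  paths <- list(
    alignment = file.path(out_dir, "alignment.fasta"),
    tree = file.path(out_dir, "tree.nwk"),
    model = file.path(out_dir, "model.tsv"),
    run_log = file.path(out_dir, "run.log")
  )
  write_fasta(aln_strings(res$value$aln), paths$alignment)
  write_newick(res$value$fit$tree, paths$tree)
  write.table(as.data.frame(tidy(res$value$fit)), paths$model, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$value$mono)) {
    paths$monophyly <- file.path(out_dir, "monophyly.tsv")
    write.table(as.data.frame(res$value$mono), paths$monophyly, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_run_log(out_dir, "phylo", config, res$warnings)
  invisible(list(fit = res$value$fit, alignment = res$value$aln,
                 monophyly = res$value$mono, files = paths))
}

#' Run the simulation stage
#'
#' Generates a synthetic annotated mitogenome from a template and writes
#' `genome.fasta`, `features.tsv`, `truth.json` and `run.log`. The truth file
#' (template + seed) regenerates the identical genome.
#'
#' @param template A [genome_template()]; default the packaged 38-feature
#'   plan.
#' @param seed Integer seed; if `NULL`, one is drawn and recorded in the
#'   truth file.
#' @param out_dir Output directory.
#' @return Invisibly, list with the generated genome, truth and paths.
#' @export
run_simulate <- function(template = default_genome_template(), seed = 1L,
                         out_dir = "mitochar_out") {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  config <- list(stage = "simulate", seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- collect_warnings(generate_mitogenome(template, seed = seed))
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    features = file.path(out_dir, "features.tsv"),
    truth = file.path(out_dir, "truth.json"),
    run_log = file.path(out_dir, "run.log")
  )
  write_fasta(setNames(res$value$genome$sequence, res$value$genome$id),
              paths$genome)
  write_feature_table(res$value$genome$features, paths$features)
  jsonlite::write_json(res$value$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  write_run_log(out_dir, "simulate", config, res$warnings)
  invisible(list(genome = res$value$genome, truth = res$value$truth,
                 files = paths))
}

#' Run the tRNA folding stage on a FASTA of tRNA sequences
#'
#' @param trna_fasta Path to a FASTA of tRNA sequences.
#' @param out_dir Output directory.
#' @param geometry [cloverleaf_geometry()] bounds.
#' @return Invisibly, the structure report and file paths.
#' @export
run_fold_trna <- function(trna_fasta, out_dir = "mitochar_out",
                          geometry = cloverleaf_geometry()) {
  if (is.null(trna_fasta) || !file.exists(trna_fasta)) {
    usage_error(paste0("tRNA FASTA not found: ", trna_fasta))
  }
  config <- list(stage = "fold-trna", trna_fasta = trna_fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- read_fasta(trna_fasta)
  res <- collect_warnings({
    folds <- lapply(fa$sequence, fold_cloverleaf, geometry = geometry)
    names(folds) <- fa$id
    structure_report(folds)
  })
  paths <- list(structures = file.path(out_dir, "trna_structures.tsv"),
                run_log = file.path(out_dir, "run.log"))
  write.table(as.data.frame(res$value), paths$structures, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, "fold-trna", config, res$warnings)
  invisible(list(report = res$value, files = paths))
}
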