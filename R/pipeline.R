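# Orchestration: simulate (or load) -> trim/assign -> quantify -> test ->
# report, with a run manifest recording configuration, record counts and
# output digests. All outputs are plain TSV/FASTA/GFF3/JSON text.

#' Write a synthetic reference to FASTA + GFF3
#'
#' @param reference A `sim_reference` from [generate_reference()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fasta")
  gff <- file.path(dir, "annotations.gff3")
  Biostrings::writeXStringSet(reference$catalog$contigs, fa)
  fx <- reference$catalog$features
  gr <- reference$catalog$granges
  S4Vectors::mcols(gr)$ID <- fx$feature_id
  S4Vectors::mcols(gr)$rna_class <- fx$rna_class
  # rtracklayer wants Parent as a CharacterList with empty elements for roots
  plist <- as.list(fx$parent)
  plist[is.na(fx$parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- methods::as(plist, "CharacterList")
  S4Vectors::mcols(gr)$type <- ifelse(is.na(fx$parent), "ncRNA_gene", "ncRNA")
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}

#' Read a pipeline configuration file
#'
#' A plain-text key-value (YAML) file governing all stages: seeds,
#' simulation overrides, matching parameters, thresholds and the tested
#' contrast. Every threshold defaults to the analysis values (18/1/2
#' mismatch budget, 10^6 normalization, 300 cpm filter, alpha 0.05).
#'
#' @param path Path to the YAML config.
#' @return A named list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

#' Default pipeline configuration
#'
#' @return Named list of defaults; see [read_pipeline_config()].
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       mode = "simulate",
       simulate = list(),
       inputs = NULL,
       match = list(seed_len = 18L, seed_mismatch_max = 1L,
                    tail_mismatch_max = 2L, min_trimmed_len = 15L,
                    max_trimmed_len = 50L),
       min_cpm = 300,
       alpha = 0.05,
       pseudocount = 0.5,
       contrast = NULL,
       write_reads = FALSE,
       census = TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> trim/assign -> quantify -> differential
#' test -> census -> report, writing all tables and a JSON run manifest to
#' `out_dir`. Re-running with the same configuration reproduces identical
#' tables. Stage record counts must satisfy conservation (reads in =
#' too-short + unmapped + mapped) or the run fails.
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a YAML file.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results: `catalog`,
#'   `assignments`, `counts`, `diff`, `top`, `census`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mirsolid] ", ...)
  manifest <- list(tool = "mirsolid",
                   version = as.character(utils::packageVersion("mirsolid")),
                   seed = config$seed,
                   config = config, stages = list(), files = list())
  outputs <- character(0)

  ## stage 1: inputs
  census_candidates <- NULL
  truth <- NULL
  if (identical(config$mode, "simulate")) {
    say("simulating study (seed ", config$seed, ")")
    sim_args <- c(list(seed = config$seed), config$simulate)
    scn <- do.call(default_study_scenario, sim_args)
    catalog <- scn$reference$catalog
    samples <- scn$reads$samples
    sheet <- scn$reads$sample_sheet
    adapter <- scn$config$adapter
    truth <- scn$reads$truth
    if (isTRUE(config$census))
      census_candidates <- scn$reference$sequences
    refpaths <- write_reference(scn$reference, out_dir)
    outputs <- c(outputs, refpaths)
    outputs <- c(outputs, .write_tsv(truth, file.path(out_dir, "truth_units.tsv")))
    if (isTRUE(config$write_reads)) {
      for (s in names(samples)) {
        fp <- file.path(out_dir, paste0(s, ".csfasta"))
        qp <- file.path(out_dir, paste0(s, ".qual"))
        write_csfasta(samples[[s]], fp, qp)
        outputs <- c(outputs, fp, qp)
      }
    }
  } else {
    ins <- config$inputs
    if (is.null(ins$genome) || is.null(ins$gff3) || is.null(ins$sample_sheet))
      stop("inputs mode requires 'genome', 'gff3' and 'sample_sheet' paths")
    for (p in c(ins$genome, ins$gff3, ins$sample_sheet))
      if (!file.exists(p)) stop("missing input: ", p)
    say("loading catalog from ", ins$genome)
    catalog <- load_catalog(ins$genome, ins$gff3)
    sheet <- utils::read.delim(ins$sample_sheet, stringsAsFactors = FALSE)
    need <- c("file", "sample", "condition", "replicate", "direction")
    if (!all(need %in% names(sheet)))
      stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    samples <- list()
    for (i in seq_len(nrow(sheet))) {
      if (!file.exists(sheet$file[i])) stop("missing input: ", sheet$file[i])
      qf <- if (!is.null(sheet$qual_file)) sheet$qual_file[i] else NULL
      samples[[sheet$sample[i]]] <- read_csfasta(sheet$file[i], qf,
                                                 sheet$direction[i])
    }
    adapter <- ins$adapter
    if (!is.null(ins$census_fasta)) {
      cs <- Biostrings::readDNAStringSet(ins$census_fasta)
      census_candidates <- stats::setNames(as.character(cs), names(cs))
    }
  }
  manifest$stages$inputs <- list(samples = length(samples),
                                 reads = vapply(samples, nrow, 0L),
                                 features = nrow(catalog$features))

  ## stage 2: trim + match + assign
  say("assigning ", length(samples), " sample(s)")
  params <- do.call(match_params, config$match)
  aset <- assign_all(samples, catalog, params, adapter = adapter)
  conserve <- with(aset$counts, reads_in == too_short + unmapped + mapped)
  if (!all(conserve))
    stop("read conservation violated in sample(s): ",
         paste(aset$counts$sample[!conserve], collapse = ", "))
  outputs <- c(outputs, .write_tsv(aset$counts,
                                   file.path(out_dir, "stage_counts.tsv")))
  outputs <- c(outputs, .write_tsv(aset$class_fractions,
                                   file.path(out_dir, "class_fractions.tsv")))
  asg_all <- do.call(rbind, aset$assignments)
  rownames(asg_all) <- NULL
  outputs <- c(outputs, .write_tsv(asg_all,
                                   file.path(out_dir, "assignments.tsv")))
  manifest$stages$assign <- as.list(stats::setNames(aset$counts$mapped,
                                                    aset$counts$sample))

  ## stage 3: quantify
  say("quantifying miRNAs")
  cm <- count_features(aset, catalog, sheet)
  cm <- normalize_cpm(cm)
  raw_df <- data.frame(feature = rownames(cm$raw), cm$raw, check.names = FALSE)
  norm_df <- data.frame(feature = rownames(cm$norm), round(cm$norm, 4),
                        check.names = FALSE)
  outputs <- c(outputs, .write_tsv(raw_df, file.path(out_dir, "counts_raw.tsv")))
  outputs <- c(outputs, .write_tsv(norm_df, file.path(out_dir, "counts_cpm.tsv")))
  manifest$stages$quantify <- list(features = nrow(cm$raw),
                                   mirna_reads = as.list(colSums(cm$raw)))

  ## stage 4: differential expression
  contrast <- config$contrast
  if (is.null(contrast)) {
    cc <- unique(sheet$condition)
    contrast <- c(cc[length(cc)], cc[1L])
  }
  diff <- NULL; top <- NULL
  if (length(unique(sheet$condition)) >= 2L) {
    say("differential expression: ", contrast[1L], " vs ", contrast[2L])
    diff <- fit_moderated_t(cm, contrast, pseudocount = config$pseudocount,
                            min_cpm = config$min_cpm)
    top <- top_table(diff, alpha = config$alpha)
    dd <- diff
    num <- vapply(dd, is.numeric, TRUE)
    dd[num] <- lapply(dd[num], signif, 6)
    outputs <- c(outputs, .write_tsv(dd, file.path(out_dir, "diffexp.tsv")))
    outputs <- c(outputs, .write_tsv(top$table,
                                     file.path(out_dir, "top_regulated.tsv")))
    manifest$stages$differential <- list(
      tested = sum(diff$passes_filter), significant = nrow(top$table),
      up = top$n_up, down = top$n_down)
  }

  ## stage 5: census of near-identical candidates
  census <- NULL
  if (!is.null(census_candidates) && length(census_candidates)) {
    say("color-space census of ", length(census_candidates), " candidate(s)")
    census <- perfect_match_census(samples, census_candidates)
    cdf <- data.frame(candidate = rownames(census$counts), census$counts,
                      check.names = FALSE)
    outputs <- c(outputs, .write_tsv(cdf, file.path(out_dir, "census.tsv")))
    manifest$stages$census <- as.list(rowSums(census$counts))
  }

  ## manifest
  outputs <- unname(outputs)
  manifest$files <- as.list(tools::md5sum(outputs))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  say("done: ", length(outputs) + 1L, " files in ", out_dir)
  invisible(list(catalog = catalog, assignments = aset, counts = cm,
                 diff = diff, top = top, census = census, truth = truth,
                 sample_sheet = sheet, manifest = manifest))
}
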