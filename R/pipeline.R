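## Stage orchestration: one flat (namespaced) config, derived per-stage
## seeds, TSV outputs and a JSON run manifest with output checksums.

#' Default pipeline configuration
#'
#' A nested key-value list covering every stage parameter; values are the
#' thresholds of the radish EST analysis or this package's documented
#' defaults. Unknown keys are rejected by [validatePipelineConfig()].
#'
#' @return Named list of stage sections.
#' @export
pipelineDefaults <- function() {
  list(
    seed = 1L,
    stages = list(preprocess = TRUE, ssr = TRUE, snp = TRUE,
                  phylo = TRUE, ks = TRUE),
    input = list(est_fasta_dir = NULL, unigene_fasta = NULL,
                 membership_tsv = NULL, aligned_dir = NULL,
                 cds_fasta = NULL),
    preprocess = list(max_n_fraction = 0.03),
    ssr = list(min_di = 6L, min_tri = 5L, min_tetra = 5L, min_penta = 5L,
               min_hexa = 5L, max_gap = 100, min_flank = 50L),
    snp = list(min_coverage = 2L),
    phylo = list(bootstrap = 1000L, distance = "p"),
    ks = list(min_protein_len = 100L, min_codons = 30L, topn = 3L,
              bandwidth = 0.03, grid_n = 600L, min_height_frac = 0.1,
              calibration_ks = 1.475, calibration_t_min = 54,
              calibration_t_max = 90)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Fills missing keys from [pipelineDefaults()] and rejects unknown keys
#' at either level.
#'
#' @param config Nested list (possibly partial).
#' @return The completed configuration.
#' @export
validatePipelineConfig <- function(config = list()) {
  def <- pipelineDefaults()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk)) {
        stop("unknown keys in section '", sec, "': ",
             paste(badk, collapse = ", "))
      }
    }
  }
  modifyList(def, config)
}

#' Read / write a pipeline configuration as YAML
#'
#' `parse -> serialize -> parse` is the identity on completed
#' configurations.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `readPipelineConfig` returns the validated configuration.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(validatePipelineConfig(config), path)
  invisible(path)
}

#' Generate the demonstration dataset
#'
#' Writes a synthetic dataset exercising every stage: duplicated gene
#' families at the configured Ks targets (for the Ks/WGD stage) and a
#' multi-accession EST set with planted SSRs and tree-structured SNPs (for
#' the preprocessing, SSR, SNP and phylogeny stages), plus all truth
#' tables.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @param params A [SimulationParams-class]; the default plants 60 SSRs
#'   and simulates 600 families (300 per Ks target) over 8 accessions.
#' @return Invisibly, the named vector of written paths.
#' @export
generateDemo <- function(dir, seed = 1L,
                         params = SimulationParams(
                           seed = seed,
                           ssrSpec = data.frame(
                             unit = c("AG", "TC", "AAG", "TCT", "ACGT",
                                      "AACGT", "AACGTC"),
                             repeats = c(6L, 7L, 5L, 6L, 5L, 5L, 5L),
                             count = c(15L, 15L, 10L, 10L, 4L, 3L, 3L)))) {
  sim <- simulateAccessionAlignments(params)
  paths <- writeSimulation(sim, dir)
  fams <- simulateFamilies(params)
  p <- file.path(dir, "families.fasta")
  Biostrings::writeXStringSet(fams$sequences, p)
  paths["families"] <- p
  p <- file.path(dir, "truth_families.tsv")
  writeTsv(fams$truth, p)
  paths["truth_families"] <- p
  invisible(paths)
}

#' @keywords internal
stageLog <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (preprocess, then
#' SSR / SNP in parallel order, phylogeny after SNP, Ks independently),
#' writing per-stage TSV outputs under `outDir` and a JSON run manifest
#' with the configuration echo, per-output MD5 checksums and the package
#' version. Failures abort with a stage-attributed error. Deterministic
#' stages yield identical checksums when re-run with the same
#' configuration and inputs.
#'
#' @param config Configuration (see [pipelineDefaults()]); input paths
#'   must point to existing files/directories for the enabled stages.
#' @param outDir Output directory.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
runPipeline <- function(config, outDir) {
  cfg <- validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(outDir, name)
    writeTsv(x, p)
    outputs[[name]] <<- p
    p
  }
  needInput <- function(key) {
    p <- cfg$input[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop("missing input '", key, "' (", if (is.null(p)) "unset" else p,
           ")", call. = FALSE)
    }
    p
  }
  runStage <- function(stage, expr) {
    stageLog(stage, "running")
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  unigenes <- NULL
  membership <- NULL

  if (isTRUE(cfg$stages$preprocess)) {
    runStage("preprocess", {
      dirIn <- needInput("est_fasta_dir")
      files <- list.files(dirIn, pattern = "\\.fasta$", full.names = TRUE)
      ests <- do.call(c, lapply(files, Biostrings::readDNAStringSet))
      flt <- filterLowQuality(ests, cfg$preprocess$max_n_fraction)
      membership <- readTsv(needInput("membership_tsv"))
      keptMemb <- membership[membership$est_id %in% names(flt$kept), ,
                             drop = FALSE]
      unigenes <- Biostrings::readDNAStringSet(needInput("unigene_fasta"))
      dist <- membershipDistribution(keptMemb)
      emit(dist, "membership_distribution.tsv")
      st <- unigeneStats(unigenes, keptMemb)
      emit(data.frame(metric = names(st), value = unlist(st)),
           "unigene_stats.tsv")
      emit(data.frame(est_id = names(flt$rejected)), "rejected_ests.tsv")
      stageLog("preprocess", length(flt$kept), " ESTs kept, ",
               length(flt$rejected), " rejected")
    })
  }

  if (isTRUE(cfg$stages$ssr)) {
    runStage("ssr", {
      if (is.null(unigenes)) {
        unigenes <- Biostrings::readDNAStringSet(needInput("unigene_fasta"))
      }
      thr <- c(`2` = cfg$ssr$min_di, `3` = cfg$ssr$min_tri,
               `4` = cfg$ssr$min_tetra, `5` = cfg$ssr$min_penta,
               `6` = cfg$ssr$min_hexa)
      motifs <- scanSSRs(unigenes, thresholds = thr)
      motifs <- mergeCompound(motifs, maxGap = cfg$ssr$max_gap)
      simple <- motifs$nt_type != "compound"
      motifs$flank_ok <- NA
      motifs$flank_ok[simple] <-
        checkFlanks(motifs[simple, , drop = FALSE], unigenes,
                    cfg$ssr$min_flank)
      emit(motifs, "ssr_motifs.tsv")
      sm <- summarizeSSRs(motifs)
      emit(data.frame(nt_type = names(sm$by_type),
                      n = as.integer(sm$by_type),
                      pct = as.integer(sm$pct_type)),
           "ssr_summary.tsv")
      stageLog("ssr", sm$n_total, " SSRs in ", sm$n_unigenes_with_ssr,
               " unigenes")
    })
  }

  snps <- NULL
  if (isTRUE(cfg$stages$snp)) {
    runStage("snp", {
      alnDir <- needInput("aligned_dir")
      files <- list.files(alnDir, pattern = "\\.afa$", full.names = TRUE)
      alns <- lapply(files, readAlignedFasta)
      names(alns) <- sub("\\.afa$", "", basename(files))
      if (is.null(membership)) {
        membership <- readTsv(needInput("membership_tsv"))
      }
      snps <- callSNPs(alns, membership, cfg$snp$min_coverage)
      emit(snps, "snps.tsv")
      gm <- buildGenotypeMatrix(snps)
      gmOut <- data.frame(site = colnames(alleleMatrix(gm)),
                          t(alleleMatrix(gm)), check.names = FALSE)
      emit(gmOut, "genotype_matrix.tsv")
      stageLog("snp", nrow(snps), " SNPs, ",
               ncol(alleleMatrix(gm)), " complete sites")
    })
  }

  if (isTRUE(cfg$stages$phylo)) {
    runStage("phylo", {
      if (is.null(snps)) stop("phylo stage requires the snp stage")
      gm <- buildGenotypeMatrix(snps)
      bs <- bootstrapSupport(gm, replicates = cfg$phylo$bootstrap,
                             seed = deriveSeed(cfg$seed, 41L),
                             correction = cfg$phylo$distance)
      p <- file.path(outDir, "accessions.nwk")
      writeNewickTree(bs$tree, p)
      outputs[["accessions.nwk"]] <- p
      emit(bs$splits, "splits.tsv")
      stageLog("phylo", nrow(bs$splits), " internal splits")
    })
  }

  if (isTRUE(cfg$stages$ks)) {
    runStage("ks", {
      cds <- Biostrings::readDNAStringSet(needInput("cds_fasta"))
      genes <- list()
      for (i in seq_along(cds)) {
        orf <- translateLongestOrf(cds[[i]],
                                   minAa = cfg$ks$min_protein_len)
        if (!is.null(orf)) genes[[names(cds)[i]]] <- orf
      }
      stageLog("ks", length(genes), " of ", length(cds),
               " sequences yield a protein >= ", cfg$ks$min_protein_len,
               " aa")
      pairs <- paralogKs(genes, topN = cfg$ks$topn,
                         minCodons = cfg$ks$min_codons)
      emit(pairs, "ks_pairs.tsv")
      kd <- ksDensityPeaks(pairs$ks, bandwidth = cfg$ks$bandwidth,
                           gridN = cfg$ks$grid_n,
                           minHeightFrac = cfg$ks$min_height_frac)
      emit(data.frame(ks = kd@x, density = kd@y), "ks_density.tsv")
      rate <- calibrateRate(cfg$ks$calibration_ks,
                            cfg$ks$calibration_t_min,
                            cfg$ks$calibration_t_max)
      pk <- ksPeaks(kd)
      if (nrow(pk)) {
        ev <- dateEvent(pk$ks, rate,
                        label = paste0("WGD_", seq_len(nrow(pk))))
        emit(ev, "dated_events.tsv")
        stageLog("ks", "peaks at ",
                 paste(sprintf("%.3f", pk$ks), collapse = ", "))
      }
    })
  }

  manifest <- list(
    package = "ESTevo",
    version = as.character(utils::packageVersion("ESTevo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
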