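## End-to-end orchestration: simulate (or load) -> filter -> windowed
## stats -> LD -> PCA/admixture -> tree -> effects -> sweep scan ->
## core collection, with a machine-readable JSON manifest per stage.

#' Pipeline configuration
#'
#' Exactly one of `inputPaths` (list with `vcf`, `sampleTable` and
#' optionally `gff3`, `fasta`) or `sim` (a [simConfig()]) must be
#' given. Stage parameter blocks are validated before any stage runs.
#'
#' @param outDir output directory.
#' @param sim a [simConfig()], or NULL.
#' @param inputPaths list of input file paths, or NULL.
#' @param filter a [filterSpec()].
#' @param windows a [windowSpec()].
#' @param populations population labels used for per-population stats.
#' @param ld list: `maxDistance`, `binWidth`, `maxPairsPerBin`.
#' @param structure list: `kRange`, `nFolds`, `maskFraction`, `thinTo`.
#' @param tree list: `nBootstrap`.
#' @param sweep list: `quantile`.
#' @param core list: `size`, `quotas` (or NULL).
#' @param seed global seed, split per stage via [deriveSeed()].
#' @export
pipelineConfig <- function(outDir,
                           sim = simConfig(),
                           inputPaths = NULL,
                           filter = filterSpec(),
                           windows = windowSpec(),
                           populations = c("POP1", "POP2", "POP3"),
                           ld = list(maxDistance = 300000L,
                                     binWidth = 5000L,
                                     maxPairsPerBin = 400L),
                           structure = list(kRange = 2:5, nFolds = 5L,
                                            maskFraction = 0.1,
                                            thinTo = 5000L),
                           tree = list(nBootstrap = 100L),
                           sweep = list(quantile = 0.95),
                           core = list(size = 26L, quotas = NULL),
                           seed = 1L) {
  if (!is.null(inputPaths) && !is.null(sim)) {
    stop("give either inputPaths or sim, not both")
  }
  if (is.null(inputPaths) && is.null(sim)) {
    stop("one of inputPaths or sim is required")
  }
  if (!is.null(inputPaths)) {
    needed <- c("vcf", "sampleTable")
    if (!all(needed %in% names(inputPaths))) {
      stop("inputPaths requires elements: ", paste(needed, collapse = ", "))
    }
  }
  stopifnot(is.numeric(seed), length(populations) >= 1)
  structure(list(outDir = outDir, sim = sim, inputPaths = inputPaths,
                 filter = filter, windows = windows,
                 populations = populations, ld = ld,
                 structure = structure, tree = tree, sweep = sweep,
                 core = core, seed = seed),
            class = "pipelineConfig")
}

.serializableConfig <- function(config) {
  cf <- unclass(config)
  cf$sim <- if (!is.null(cf$sim)) unclass(cf$sim)
  cf$filter <- unclass(cf$filter)
  cf$windows <- unclass(cf$windows)
  cf
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' under `outDir` and a cumulative JSON manifest (`manifest.json`:
#' parameters, seed, per-file md5 hashes). A failing stage aborts with
#' its name; partial outputs of the failed stage are moved to
#' `outDir/quarantine`. Rerunning with the same config and seed
#' reproduces identical hashes for the deterministic stages.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log stage progression.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = .serializableConfig(config),
                   stages = list())
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S"),
                                            " [pipeline] ", ...)
  stageFiles <- character(0)
  runStage <- function(name, fn) {
    say("stage ", name)
    before <- list.files(outDir, recursive = TRUE)
    res <- tryCatch(fn(), error = function(e) {
      after <- list.files(outDir, recursive = TRUE)
      newFiles <- setdiff(after, before)
      if (length(newFiles)) {
        qdir <- file.path(outDir, "quarantine")
        dir.create(qdir, showWarnings = FALSE)
        file.rename(file.path(outDir, newFiles),
                    file.path(qdir, basename(newFiles)))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    after <- list.files(outDir, recursive = TRUE)
    newFiles <- setdiff(after, before)
    hashes <- as.list(tools::md5sum(file.path(outDir, newFiles)))
    names(hashes) <- newFiles
    manifest$stages[[name]] <<- list(outputs = hashes,
                                     seed = deriveSeed(config$seed,
                                                       length(manifest$stages) + 1L))
    res
  }

  ## acquire
  data <- runStage("acquire", function() {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- deriveSeed(config$seed, 1L)
      out <- simulatePanel(sim)
      writeVCF(out$panel, file.path(outDir, "panel.vcf"))
      writeSampleTable(out$sampleInfo, file.path(outDir, "samples.tsv"))
      writeGFF3(out$genes, file.path(outDir, "genes.gff3"))
      writeFASTA(out$reference, file.path(outDir, "reference.fa"))
      jsonlite::write_json(
        list(admixedIds = out$truth$admixedIds,
             popDrift = as.list(out$truth$popDrift)),
        file.path(outDir, "truth.json"), auto_unbox = TRUE)
      out
    } else {
      list(panel = readVCF(config$inputPaths$vcf),
           sampleInfo = readSampleTable(config$inputPaths$sampleTable,
                                        config$populations),
           genes = if (!is.null(config$inputPaths$gff3))
             readGFF3(config$inputPaths$gff3),
           reference = if (!is.null(config$inputPaths$fasta))
             readFASTA(config$inputPaths$fasta))
    }
  })
  pops <- intersect(config$populations, unique(data$sampleInfo$population))
  if (length(pops) < 1L) stop("no configured population label found in metadata")

  panel <- runStage("filter", function() {
    p <- filterVariants(data$panel, config$filter)
    writeVCF(p, file.path(outDir, "panel.filtered.vcf"))
    p
  })

  tracks <- runStage("stats", function() {
    piT <- lapply(pops, function(pp) {
      tr <- windowedPi(panel, data$sampleInfo, pp, config$windows)
      writeTrack(tr, file.path(outDir, paste0("pi.", pp, ".tsv")))
      tr
    })
    names(piT) <- pops
    dT <- lapply(pops, function(pp) {
      tr <- tajimasD(panel, data$sampleInfo, pp, config$windows)
      writeTrack(tr, file.path(outDir, paste0("tajimaD.", pp, ".tsv")))
      tr
    })
    names(dT) <- pops
    fstT <- list()
    if (length(pops) >= 2) {
      prs <- utils::combn(pops, 2L, simplify = FALSE)
      for (pr in prs) {
        f <- wcFst(panel, data$sampleInfo, pr[1], pr[2], config$windows)
        nm <- paste(pr, collapse = "-")
        writeTrack(f$track, file.path(outDir, paste0("fst.", nm, ".tsv")))
        fstT[[nm]] <- f
      }
    }
    list(pi = piT, tajimaD = dT, fst = fstT)
  })

  runStage("ld", function() {
    for (pp in pops) {
      pr <- pairwiseR2(panel, data$sampleInfo, pp,
                       maxDistance = config$ld$maxDistance,
                       binWidth = config$ld$binWidth,
                       maxPairsPerBin = config$ld$maxPairsPerBin,
                       seed = deriveSeed(config$seed, 31L))
      curve <- binCurve(pr, config$ld$binWidth, config$ld$maxDistance)
      utils::write.table(curve,
                         file.path(outDir, paste0("ld.", pp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  })

  structRes <- runStage("structure", function() {
    thin <- min(config$structure$thinTo, nVariants(panel))
    set.seed(deriveSeed(config$seed, 41L))
    keep <- sort(sample.int(nVariants(panel), thin))
    sub <- panel[keep, ]
    pc <- pcaPanel(sub, 4L)
    utils::write.table(
      data.frame(sample_id = rownames(pc$coordinates), pc$coordinates),
      file.path(outDir, "pca.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ks <- selectK(sub, config$structure$kRange, config$structure$nFolds,
                  config$structure$maskFraction,
                  seed = deriveSeed(config$seed, 42L))
    fit <- admixtureEM(sub, ks$chosenK, seed = deriveSeed(config$seed, 43L))
    qdf <- data.frame(sample_id = rownames(fit@Q), fit@Q)
    utils::write.table(qdf, file.path(outDir, "admixture.Q.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(kRange = ks$kRange, cvError = ks$cvError, chosenK = ks$chosenK),
      file.path(outDir, "kselection.json"), auto_unbox = TRUE, digits = NA)
    list(kSelection = ks, fit = fit)
  })

  runStage("tree", function() {
    set.seed(deriveSeed(config$seed, 51L))
    thin <- min(2000L, nVariants(panel))
    keep <- sort(sample.int(nVariants(panel), thin))
    tr <- bootstrapSupport(panel[keep, ], config$tree$nBootstrap,
                           seed = deriveSeed(config$seed, 52L))
    writeNewick(tr, file.path(outDir, "nj.nwk"))
    NULL
  })

  if (!is.null(data$genes) && !is.null(data$reference)) {
    runStage("effects", function() {
      ann <- annotateEffects(panel, data$genes, data$reference)
      utils::write.table(ann, file.path(outDir, "effects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- effectSummary(ann, data$sampleInfo, panel)
      utils::write.table(summ, file.path(outDir, "effects.summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  runStage("sweep", function() {
    geneSets <- list()
    for (nm in names(tracks$fst)) {
      pr <- strsplit(nm, "-")[[1]]
      piA <- tracks$pi[[pr[1]]]
      piB <- tracks$pi[[pr[2]]]
      ## orient ROD so the lower-diversity population is the swept candidate
      if (genomeWideMean(piA) < genomeWideMean(piB)) {
        tmp <- piA; piA <- piB; piB <- tmp
      }
      rod <- rodTrack(piA, piB)
      jo <- jointOutliers(tracks$fst[[nm]]$track, rod,
                          config$sweep$quantile)
      utils::write.table(jo$candidates,
                         file.path(outDir, paste0("sweep.", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(data$genes)) {
        geneSets[[nm]] <- windowsToGenes(jo$merged, data$genes)
      }
    }
    if (length(geneSets) >= 2) {
      venn <- sharedSelectionGenes(geneSets)
      jsonlite::write_json(
        list(sharedAll = venn$sharedAll, counts = as.list(venn$counts)),
        file.path(outDir, "sweep.genes.json"), auto_unbox = TRUE)
    }
    NULL
  })

  runStage("core", function() {
    core <- greedyCore(panel, config$core$size, config$core$quotas,
                       data$sampleInfo)
    utils::write.table(
      data.frame(order = seq_along(core$selected),
                 sample_id = core$selected,
                 retention = core$retentionCurve),
      file.path(outDir, "core.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    core
  })

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done")
  invisible(manifest)
}
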