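## pipeline_cli: config-driven orchestration of the analysis stages with
## per-stage text outputs and a run manifest. Stages: qc -> roh -> blocks
## -> zscan -> region diversity -> selection (sequence data) -> dating
## (reference panels).

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are rejected.
#' Defaults mirror the standard parameterization of each stage: QC at
#' 95% call rates / MAF 0.01 / HWE 1e-6 with 50/10/0.5 pruning, the
#' 5,000-kb ROH screen, a |Z| > 3 scan threshold, 10-kb selection
#' windows, 5,000 null replicates, and 33 years per generation.
#'
#' @param config YAML path or named list; see Details for keys.
#' @details Recognized keys: `genotypes`, `dosages`, `dosageLoci`,
#'   `map`, `centromeres` (input paths or in-memory objects), `outDir`,
#'   `seed`, `stages` (character subset of qc, roh, blocks, zscan,
#'   diversity, selection, dating), `qc` / `roh` (parameter lists
#'   forwarded to [qcConfig()] / [rohConfig()]), `scanThreshold`,
#'   `windowBp`, `nullReplicates`, `msCommand`, `thetaHat`, `rhoHat`,
#'   `selectionRegions` (data.frame chrom/start/end), `refPairs`,
#'   `ancestries`, `proportions`, `yearsPerGeneration`.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("genotypes", "dosages", "dosageLoci", "map", "centromeres",
             "outDir", "seed", "stages", "qc", "roh", "scanThreshold",
             "windowBp", "nullReplicates", "msCommand", "thetaHat",
             "rhoHat", "selectionRegions", "refPairs", "ancestries",
             "proportions", "yearsPerGeneration")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(outDir = tempfile("islescan_run_"), seed = 1,
                   stages = c("qc", "roh", "blocks", "zscan", "diversity"),
                   qc = list(), roh = list(), scanThreshold = 3,
                   windowBp = 10000, nullReplicates = 5000,
                   yearsPerGeneration = 33,
                   proportions = c(EUR = 0.75, NAF = 0.22, SSA = 0.03))
  cfg <- modifyList(defaults, config)
  needs <- list(qc = "genotypes", roh = "genotypes", blocks = "dosages",
                zscan = "dosages", diversity = "genotypes",
                selection = "genotypes", dating = "refPairs")
  for (st in cfg$stages) {
    req <- needs[[st]]
    if (!is.null(req) && is.null(cfg[[req]]))
      stop("config error: stage '", st, "' requires '", req, "'")
  }
  structure(cfg, class = "PipelineConfig")
}

#' @importFrom utils modifyList packageVersion
NULL

loadInput <- function(x, loader) {
  if (is.character(x)) loader(x) else x
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing per-stage TSV/BED/JSON
#' outputs plus a run manifest (package version, seed, config hash) into
#' `outDir`. A stage failure halts the run with a stage-named error;
#' outputs of completed stages are preserved.
#'
#' @param config a [pipelineConfig()] (or list / YAML path accepted by
#'   it).
#' @return list with the per-stage results and `manifest`.
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else pipelineConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  ## hash the scalar parameters; in-memory input objects contribute their
  ## class tag only (file inputs contribute their path)
  hashable <- lapply(cfg[setdiff(names(cfg), "outDir")], function(x)
    if (is.atomic(x)) x else class(x)[1])
  tf <- tempfile()
  writeLines(yaml::as.yaml(hashable), tf)
  cfgHash <- unname(tools::md5sum(tf)); unlink(tf)
  manifest <- list(package = "islescan",
                   version = as.character(packageVersion("islescan")),
                   seed = cfg$seed, configHash = cfgHash,
                   stages = character(0))
  results <- list()
  out <- function(...) file.path(cfg$outDir, ...)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    r
  }
  set.seed(cfg$seed)

  vt <- if (!is.null(cfg$genotypes))
    loadInput(cfg$genotypes, readVcfTable) else NULL
  dt <- NULL
  if (!is.null(cfg$dosages)) {
    dt <- if (is.character(cfg$dosages))
      readDosage(cfg$dosages, cfg$dosageLoci,
                 K = length(cfg$ancestries %||% c("EUR", "NAF", "SSA")),
                 ancestries = cfg$ancestries)$tensor
    else cfg$dosages
  }
  map <- if (!is.null(cfg$map)) loadInput(cfg$map, readGeneticMap)
         else NULL
  centromeres <- if (!is.null(cfg$centromeres))
    loadInput(cfg$centromeres, readBedRegions) else hg19Centromeres()

  if ("qc" %in% cfg$stages) {
    results$qc <- stage("qc", {
      q <- filterGenotypes(vt, do.call(qcConfig, cfg$qc))
      write.table(q$report, out("qc_report.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      q
    })
    vt <- results$qc$table
  }
  if ("roh" %in% cfg$stages) {
    results$roh <- stage("roh", {
      segs <- callRoh(vt, do.call(rohConfig, cfg$roh))
      writeRohTsv(segs, out("roh_segments.tsv"))
      summ <- summarizeRoh(segs, sampleSheet(vt))
      write.table(summ$perGroup, out("roh_by_group.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(segments = segs, summary = summ)
    })
  }
  if ("blocks" %in% cfg$stages) {
    results$blocks <- stage("blocks", {
      rd <- roundDosages(dt)
      blocks <- segmentBlocks(rd$calls, rd$ambiguous, dt@chrom, dt@pos,
                              ancestries(dt), centromeres)
      writeBlocksBed(blocks, out("ancestry_blocks.bed"))
      props <- cfg$proportions
      names(props) <- cfg$ancestries %||% names(props) %||% ancestries(dt)
      bs <- blockStats(blocks, props)
      write.table(bs$stats, out("block_stats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(blocks = blocks, stats = bs)
    })
  }
  if ("zscan" %in% cfg$stages) {
    results$zscan <- stage("zscan", {
      zs <- zscoreScan(dt)
      writeZTracks(zs, out("zscan_tracks.tsv"))
      regions <- callRegions(zs, threshold = cfg$scanThreshold)
      if (nrow(regions) > 0)
        writeBedRegions(data.frame(chrom = regions$chrom,
                                   start = regions$start,
                                   end = regions$end,
                                   name = regions$ancestry,
                                   score = round(regions$leadZ, 2)),
                        out("zscan_regions.bed"))
      write.table(regions, out("zscan_regions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(scan = zs, regions = regions)
    })
  }
  if ("diversity" %in% cfg$stages) {
    results$diversity <- stage("diversity", {
      roh <- if (!is.null(results$roh)) results$roh$segments
             else callRoh(vt)
      regions <- results$zscan$regions
      dv <- regionDiversity(vt, roh, regions)
      write.table(dv$perRegion, out("region_diversity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      dv
    })
  }
  if ("selection" %in% cfg$stages) {
    results$selection <- stage("selection", {
      model <- parseMsCommand(cfg$msCommand)
      null <- buildNullEnsemble(model, nreps = cfg$nullReplicates,
                                thetaHat = cfg$thetaHat,
                                rhoHat = cfg$rhoHat, seed = cfg$seed)
      regs <- cfg$selectionRegions
      winAll <- do.call(rbind, lapply(seq_len(nrow(regs)), function(r)
        windowStats(vt, regs$chrom[r], regs$start[r], regs$end[r],
                    windowBp = cfg$windowBp)))
      scan <- selectionScan(winAll, nullD = null)
      write.table(scan, out("selection_windows.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(null = null, windows = scan)
    })
  }
  if ("dating" %in% cfg$stages) {
    results$dating <- stage("dating", {
      dres <- dateAdmixture(vt, cfg$refPairs, map,
                            yearsPerGeneration = cfg$yearsPerGeneration)
      jsonlite::write_json(
        list(perPair = dres$perPair, combined = dres$combined),
        out("dating.json"), auto_unbox = TRUE, digits = NA, na = "null")
      dres
    })
  }
  manifest$completed <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
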