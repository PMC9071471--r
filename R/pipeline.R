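#' Run a YAML-configured analysis pipeline
#'
#' Executes a sequence of named stages over shared inputs, writing outputs
#' and a run manifest into `outdir`. The configuration is a YAML file (or an
#' equivalent list) with keys:
#'
#' * `outdir` — output directory (created if absent).
#' * `seed` — integer; required whenever a stochastic stage (`simulate`)
#'   is present.
#' * `genome` — path to a genome-config YAML ([readGenomeConfig()]);
#'   optional when a `simulate` stage supplies its own geometry.
#' * `stages` — list of single-key maps, executed in order. Supported
#'   stages and their parameters:
#'   * `simulate`: fields of [syntheticGenomeSpec()] (snake_case, e.g.
#'     `n_tus`, `reads_per_sample`); writes TU annotation, ground truth and
#'     per-replicate count TSVs.
#'   * `enrich`: `pulldown`/`input` (vectors of count TSV paths) or
#'     `from_simulation: true`; writes per-replicate and mean enrichment
#'     bedGraphs.
#'   * `consensus_fit`: `tus` (BED path; defaults to simulated ribosomal
#'     units), `half_width_kb`, `start_kb`; writes the consensus profile
#'     TSV and domain fits JSON.
#'   * `model`: `tus` (BED path or simulated), twin-domain parameter
#'     overrides, optional `reference` track; writes the modeled bedGraph.
#'   * `slide_corr`: `window_kb`; correlates the model with the mean
#'     enrichment; writes a correlation bedGraph.
#'   * `symmetry`: `skew_min`, `skew_max`, `step_deg`, `smoothing_kb`;
#'     writes the skew scan TSV and optimum JSON.
#'   * `regions`: `source` = `"macrodomains"`, `"hemi_genomes"` or
#'     `"classified"`; writes region means/tests TSVs.
#'
#' Unknown stage names or missing required inputs fail immediately, naming
#' the offending key. A `manifest.json` (command, resolved parameters, input
#' checksums, seed, package version, timestamp) is written alongside the
#' outputs; data outputs are deterministic given the config.
#'
#' @param config path to a YAML file, or a list with the schema above.
#' @return (invisibly) a list with the in-memory results of each stage and
#'   the manifest.
#' @export
runPipeline <- function(config) {
  cfgFile <- NULL
  if (is.character(config)) {
    cfgFile <- config
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$outdir)) stop("config key 'outdir' is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config key 'stages' is required")

  known <- c("simulate", "enrich", "consensus_fit", "model", "slide_corr",
             "symmetry", "regions")
  stageNames <- vapply(stages, function(s) names(s)[1], character(1))
  bad <- setdiff(stageNames, known)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if ("simulate" %in% stageNames && is.null(config$seed))
    stop("config key 'seed' is required for the stochastic 'simulate' stage")

  state <- list(config = NULL, dataset = NULL, enrichment = NULL,
                meanEnrichment = NULL, model = NULL, tus = NULL)
  if (!is.null(config$genome)) state$config <- readGenomeConfig(config$genome)
  inputFiles <- if (!is.null(config$genome)) config$genome else character()
  results <- list()
  logMsg <- function(...) message("[PsoraSeq] ", ...)

  for (st in stages) {
    nm <- names(st)[1]
    p <- st[[1]]
    if (is.null(p)) p <- list()
    logMsg("stage ", nm)

    if (nm == "simulate") {
      args <- list(rngSeed = config$seed)
      map <- c(genome_length_bp = "genomeLength", bin_size_bp = "binSize",
               n_tus = "nTus", n_ribosomal = "nRibosomal",
               expression_meanlog = "expressionMeanlog",
               expression_sdlog = "expressionSdlog",
               ori_ter_copy_ratio = "oriTerCopyRatio",
               reads_per_sample = "readsPerSample",
               bin_noise_sd = "binNoiseSd", n_replicates = "nReplicates",
               symmetry_skew_deg = "symmetrySkewDeg",
               rifampicin_factor = "rifampicinFactor")
      for (k in names(p)) {
        if (!k %in% names(map)) stop("unknown simulate parameter: ", k)
        args[[map[[k]]]] <- p[[k]]
      }
      spec <- do.call(syntheticGenomeSpec, args)
      ds <- generateDataset(spec)
      state$dataset <- ds
      state$config <- ds$config
      state$tus <- ds$tus
      writeGenomeConfig(ds$config, file.path(outdir, "genome.yaml"))
      writeTranscriptionUnits(ds$tus, file.path(outdir, "tus.bed"))
      writeTrackBedGraph(ds$groundTruth$profile,
                         file.path(outdir, "ground_truth.bedgraph"))
      for (k in seq_along(ds$replicates)) {
        writeTrackTSV(ds$replicates[[k]]$pulldown,
                      file.path(outdir, sprintf("pulldown_%d.tsv", k)))
        writeTrackTSV(ds$replicates[[k]]$input,
                      file.path(outdir, sprintf("input_%d.tsv", k)))
      }
      logMsg("  simulated ", length(ds$replicates), " replicate pairs over ",
             nBins(ds$config), " bins")
      results$simulate <- ds

    } else if (nm == "enrich") {
      if (isTRUE(p$from_simulation) || (is.null(p$pulldown) && !is.null(state$dataset))) {
        pairs <- state$dataset$replicates
        tracks <- lapply(pairs, function(pr)
          psoraEnrichment(pr$pulldown, pr$input))
      } else {
        if (is.null(p$pulldown) || is.null(p$input))
          stop("enrich stage requires 'pulldown' and 'input' file lists")
        if (is.null(state$config))
          stop("enrich stage requires a 'genome' config")
        inputFiles <- c(inputFiles, unlist(p$pulldown), unlist(p$input))
        tracks <- mapply(function(pd, ip) {
          psoraEnrichment(readTrackTSV(pd, state$config, "count"),
                          readTrackTSV(ip, state$config, "count"))
        }, unlist(p$pulldown), unlist(p$input), SIMPLIFY = FALSE)
      }
      state$enrichment <- tracks
      state$meanEnrichment <- averageTracks(tracks)
      for (k in seq_along(tracks))
        writeTrackBedGraph(tracks[[k]],
                           file.path(outdir, sprintf("enrichment_%d.bedgraph", k)))
      writeTrackBedGraph(state$meanEnrichment,
                         file.path(outdir, "enrichment_mean.bedgraph"))
      logMsg("  ", length(tracks), " enrichment tracks")
      results$enrich <- tracks

    } else if (nm == "consensus_fit") {
      if (is.null(state$enrichment)) stop("consensus_fit requires an 'enrich' stage")
      tus <- if (!is.null(p$tus)) {
        inputFiles <- c(inputFiles, p$tus)
        readTranscriptionUnits(p$tus, state$config)
      } else if (!is.null(state$tus)) {
        state$tus[tuRibosomal(state$tus)]
      } else stop("consensus_fit requires 'tus' (BED path)")
      hw <- if (!is.null(p$half_width_kb)) p$half_width_kb else 40
      startKb <- if (!is.null(p$start_kb)) p$start_kb else 10
      windows <- unlist(lapply(state$enrichment, function(tr)
        lapply(seq_along(tus), function(i)
          extractOrientedWindow(tr, tus[i], hw))), recursive = FALSE)
      prof <- consensusProfile(windows)
      fits <- list(upstream = fitDomainRegression(prof, "upstream", startKb),
                   downstream = fitDomainRegression(prof, "downstream", startKb))
      utils::write.table(
        data.frame(position_kb = prof@positionsKb,
                   value = .fmtVal(prof@values), sem = .fmtVal(prof@sem)),
        file.path(outdir, "consensus.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      fitJson <- lapply(fits, function(f) list(
        side = f@side, detected = f@detected, amplitude = f@amplitude,
        magnitude_kb = f@magnitudeKb, window_kb = f@windowKb,
        pearson_r = f@pearsonR, amplitude_range = f@amplitudeRange,
        magnitude_range = f@magnitudeRange, n_points = f@nPoints))
      jsonlite::write_json(fitJson, file.path(outdir, "domain_fits.json"),
                           auto_unbox = TRUE, digits = NA)
      logMsg("  consensus over ", length(windows), " windows; amplitudes ",
             sprintf("%.3f / %.3f", fits$upstream@amplitude,
                     fits$downstream@amplitude))
      results$consensus_fit <- list(profile = prof, fits = fits)

    } else if (nm == "model") {
      tus <- if (!is.null(p$tus)) {
        inputFiles <- c(inputFiles, p$tus)
        readTranscriptionUnits(p$tus, state$config)
      } else if (!is.null(state$tus)) state$tus
      else stop("model stage requires 'tus' (BED path)")
      params <- twinDomainParams(
        ampPerUnitExpression = if (!is.null(p$amplitude)) p$amplitude else 0.38,
        negMagnitudeKb = if (!is.null(p$neg_magnitude_kb)) p$neg_magnitude_kb else 23,
        posMagnitudeKb = if (!is.null(p$pos_magnitude_kb)) p$pos_magnitude_kb else 25,
        referenceExpression = if (!is.null(p$reference_expression))
          p$reference_expression else NA_real_)
      model <- composeGenomeModel(tus, params, state$config)
      if (!is.null(p$reference)) {
        inputFiles <- c(inputFiles, p$reference)
        ref <- readTrackBedGraph(p$reference, state$config)
        model <- scaleToReference(model, ref)
      } else if (!is.null(state$meanEnrichment)) {
        model <- scaleToReference(model, state$meanEnrichment)
      }
      state$model <- model
      writeTrackBedGraph(model, file.path(outdir, "model.bedgraph"))
      results$model <- model

    } else if (nm == "slide_corr") {
      if (is.null(state$model) || is.null(state$meanEnrichment))
        stop("slide_corr requires 'model' and 'enrich' stages")
      wkb <- if (!is.null(p$window_kb)) p$window_kb else 300
      corr <- slidingWindowCorrelation(state$model, state$meanEnrichment, wkb)
      writeTrackBedGraph(corr, file.path(outdir, "sliding_correlation.bedgraph"))
      fitness <- modelFitnessSummary(state$model, state$enrichment)
      jsonlite::write_json(
        list(mean_r = fitness$meanR, sem_r = fitness$semR,
             per_replicate = fitness$perReplicate),
        file.path(outdir, "model_fitness.json"), auto_unbox = TRUE, digits = NA)
      logMsg(sprintf("  genome-wide fitness r = %.3f +/- %.3f",
                     fitness$meanR, fitness$semR))
      results$slide_corr <- list(track = corr, fitness = fitness)

    } else if (nm == "symmetry") {
      if (is.null(state$meanEnrichment)) stop("symmetry requires an 'enrich' stage")
      lo <- if (!is.null(p$skew_min)) p$skew_min else -90
      hi <- if (!is.null(p$skew_max)) p$skew_max else 90
      stepDeg <- if (!is.null(p$step_deg)) p$step_deg else 1
      smoothKb <- if (!is.null(p$smoothing_kb)) p$smoothing_kb else 100
      scan <- skewScan(state$meanEnrichment, c(lo, hi), stepDeg, smoothKb)
      utils::write.table(
        data.frame(skew_deg = scan@skewDeg, r = .fmtVal(scan@r)),
        file.path(outdir, "skew_scan.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(optimal_skew_deg = scan@optSkewDeg, r = scan@optR),
        file.path(outdir, "symmetry.json"), auto_unbox = TRUE, digits = NA)
      logMsg(sprintf("  optimal skew %+g deg (r = %.3f)",
                     scan@optSkewDeg, scan@optR))
      results$symmetry <- scan

    } else if (nm == "regions") {
      if (is.null(state$enrichment)) stop("regions requires an 'enrich' stage")
      src <- if (!is.null(p$source)) p$source else "hemi_genomes"
      regions <- switch(src,
        macrodomains = macrodomainRegions(state$config),
        hemi_genomes = hemiGenomeRegions(state$config),
        classified = classifySupercoiledRegions(state$meanEnrichment),
        stop("unknown regions source: ", src))
      stats <- regionMeansAndTests(state$enrichment, regions)
      utils::write.table(stats$means, file.path(outdir, "region_means.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(stats$comparisons,
                         file.path(outdir, "region_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$regions <- stats
    }
  }

  manifest <- list(
    command = "runPipeline",
    config_file = cfgFile,
    parameters = config,
    input_checksums = as.list(tools::md5sum(
      unique(inputFiles[file.exists(inputFiles)]))),
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("PsoraSeq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
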