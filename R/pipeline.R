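.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.logStage <- function(...) message(sprintf(...))

#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a named list and fills defaults. Recognized
#' fields: \code{calls} (variant TSV path or data frame), \code{regions}
#' (biopsy declaration TSV path or data frame with \code{patient_id},
#' \code{region_id}), or alternatively \code{presence_dir} (directory of
#' per-patient presence-matrix TSVs named \code{<patient>.tsv}, skipping
#' the filter stage); \code{gene_panel}; \code{min_vaf}, \code{min_depth},
#' \code{exclude_dbsnp}, \code{exclude_synonymous}, \code{min_alt_reads};
#' \code{target} (default 0.9), \code{n_max} (default 10); \code{outdir};
#' \code{seed}.
#'
#' @param config YAML path or named list.
#' @return Resolved configuration list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  defaults <- list(
    gene_panel = defaultGenePanel(), min_vaf = 0.05, min_depth = 10,
    exclude_dbsnp = TRUE, exclude_synonymous = TRUE, min_alt_reads = 0,
    target = 0.9, n_max = 10, seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (config$target <= 0 || config$target >= 1) {
    stop("target must lie in (0, 1)", call. = FALSE)
  }
  config
}

#' Run the full multi-region heterogeneity pipeline
#'
#' Orchestrates the stages in order: ingest variant calls (or pre-made
#' presence matrices), filter, build per-tumor presence matrices and
#' shared/nonshared labels, reconstruct clone trees, summarize cohort
#' frequencies and topology categories, estimate per-gene prevalence, and
#' tabulate biopsy detection power. All outputs are plain text (TSV, Newick,
#' DOT, JSON manifest); identical config + inputs + seed give identical
#' outputs. Per-stage counters are logged to stderr.
#'
#' @param config YAML path or list (see \code{\link{pipelineConfig}}).
#' @param outdir Output directory (overrides config; required in one of
#'   the two).
#' @return Invisibly, a list with the cohort, trees, summaries, prevalence
#'   estimates, power curve and the manifest.
#' @export
runPipeline <- function(config, outdir = NULL) {
  config <- pipelineConfig(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "MultiRegionHet",
    version = as.character(utils::packageVersion("MultiRegionHet")),
    seed = config$seed,
    config = config[setdiff(names(config), c("calls", "regions"))]
  )

  fromPresence <- !is.null(config$presence_dir)
  if (fromPresence) {
    profList <- .stage("ingest", {
      files <- sort(list.files(config$presence_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (length(files) == 0L) {
        stop("no presence matrices found in ", config$presence_dir)
      }
      setNames(
        lapply(files, function(f) {
          readPresenceTSV(f, sub("\\.tsv$", "", basename(f)))
        }),
        sub("\\.tsv$", "", basename(files))
      )
    })
    manifest$counts <- list(n_input_calls = NA_integer_,
                            retained_calls = NA_integer_)
    .logStage("ingest: %d presence matrices", length(profList))
  } else {
    calls <- .stage("ingest", {
      if (is.null(config$calls)) stop("config needs 'calls' or 'presence_dir'")
      if (is.character(config$calls)) readVariantTSV(config$calls) else
        validateVariantCalls(config$calls)
    })
    regionTable <- .stage("ingest", {
      if (is.null(config$regions)) stop("config needs a 'regions' table")
      if (is.character(config$regions)) {
        read.delim(config$regions, sep = "\t", stringsAsFactors = FALSE)
      } else {
        config$regions
      }
    })
    .logStage("ingest: %d calls, %d declared biopsies",
              nrow(calls), nrow(regionTable))

    filt <- .stage("filter", filterVariants(
      calls, minVAF = config$min_vaf, minDepth = config$min_depth,
      excludeDbsnp = config$exclude_dbsnp,
      excludeSynonymous = config$exclude_synonymous,
      minAltReads = config$min_alt_reads
    ))
    manifest$counts <- list(
      n_input_calls = nrow(calls),
      retained_calls = nrow(filt$retained),
      excluded_by_rule = as.list(filt$tally)
    )
    .logStage("filter: retained %d/%d (excluded: %s)",
              nrow(filt$retained), nrow(calls),
              paste(names(filt$tally), filt$tally, sep = "=",
                    collapse = ", "))
    writeVariantTSV(filt$retained, file.path(outdir, "retained_calls.tsv"))

    profList <- .stage("profiles",
                       buildPresenceMatrix(filt$retained, regionTable))
  }

  cohort <- .stage("profiles", cohortData(profList,
                                          genePanel = config$gene_panel))
  profDir <- file.path(outdir, "profiles")
  dir.create(profDir, showWarnings = FALSE)
  for (p in cohort@profiles) {
    writePresenceTSV(p, file.path(profDir, paste0(p@patientId, ".tsv")))
  }
  .logStage("profiles: %d tumors", length(cohort@profiles))

  trees <- .stage("trees", {
    treeDir <- file.path(outdir, "trees")
    dir.create(treeDir, showWarnings = FALSE)
    lapply(cohort@profiles, function(p) {
      tr <- buildCloneTree(p)
      writeLines(renderTree(tr, "newick"),
                 file.path(treeDir, paste0(p@patientId, ".nwk")))
      writeLines(renderTree(tr, "dot"),
                 file.path(treeDir, paste0(p@patientId, ".dot")))
      tr
    })
  })

  summaries <- .stage("summaries", {
    topo <- data.frame(
      patient_id = vapply(cohort@profiles, patientId, character(1)),
      n_mutations = vapply(cohort@profiles,
                           function(p) nrow(p@presence), integer(1)),
      category = vapply(cohort@profiles, classifyTopology, character(1))
    )
    write.table(topo, file.path(outdir, "topology.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    freq <- cohortFrequencies(cohort)
    write.table(freq, file.path(outdir, "frequencies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mpt <- mutationsPerTumor(cohort)
    write.table(
      data.frame(n_mutations = names(mpt), n_tumors = mpt),
      file.path(outdir, "mutations_per_tumor.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    ubiq <- do.call(rbind, lapply(config$gene_panel, function(g) {
      u <- tryCatch(ubiquityFraction(cohort, g), undefinedEstimate =
                      function(e) NULL)
      if (is.null(u)) return(NULL)
      data.frame(gene = g, ubiquity = u$fraction,
                 n_ubiquitous = u$n_ubiquitous,
                 n_mutant_tumors = u$n_mutant_tumors)
    }))
    if (!is.null(ubiq)) {
      write.table(ubiq, file.path(outdir, "ubiquity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(topology = topo, frequencies = freq, mutations_per_tumor = mpt,
         ubiquity = ubiq)
  })
  .logStage("summaries: categories %s",
            paste(names(table(summaries$topology$category)),
                  table(summaries$topology$category),
                  sep = "=", collapse = ", "))

  prevPower <- .stage("power", {
    ests <- list()
    for (g in config$gene_panel) {
      e <- tryCatch(estimatePrevalence(cohort, g),
                    undefinedEstimate = function(e) NULL)
      if (!is.null(e)) ests[[g]] <- e
    }
    prevDf <- do.call(rbind, lapply(ests, function(e) {
      data.frame(gene = e@gene, p = e@p, n_positive = e@nPositive,
                 n_total = e@nTotal, n_patients = e@nPatients)
    }))
    if (!is.null(prevDf)) {
      write.table(prevDf, file.path(outdir, "prevalence.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      pMap <- setNames(prevDf$p, prevDf$gene)
      curve <- powerCurve(pMap, nMax = config$n_max)
      write.table(powerTable(curve), file.path(outdir, "power.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      minN <- minBiopsiesForGeneSet(pMap, config$target)
    } else {
      curve <- NULL
      minN <- NA_integer_
    }
    list(estimates = ests, prevalence = prevDf, curve = curve,
         min_biopsies = minN)
  })
  if (!is.na(prevPower$min_biopsies)) {
    .logStage("power: %d biopsies reach %.0f%% certainty for all genes",
              prevPower$min_biopsies, 100 * config$target)
  }

  manifest$counts$n_tumors <- length(cohort@profiles)
  manifest$counts$n_biopsies <- sum(vapply(
    cohort@profiles, function(p) length(p@regions), integer(1)
  ))
  manifest$min_biopsies_for_target <- prevPower$min_biopsies
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    cohort = cohort, trees = trees, summaries = summaries,
    prevalence = prevPower$estimates, curve = prevPower$curve,
    min_biopsies = prevPower$min_biopsies, manifest = manifest
  ))
}
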