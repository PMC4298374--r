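## gene coordinates used to mint realistic variant keys (GRCh37-like starts)
.geneLoci <- data.frame(
  gene = c("VHL", "PBRM1", "SETD2", "BAP1", "KDM5C"),
  chrom = c("3", "3", "3", "3", "X"),
  start = c(10183000L, 52584000L, 47057000L, 52436000L, 53220500L),
  stringsAsFactors = FALSE
)

.geneLocus <- function(gene) {
  i <- match(gene, .geneLoci$gene)
  if (is.na(i)) list(chrom = "1", start = 1000000L) else
    list(chrom = .geneLoci$chrom[i], start = .geneLoci$start[i])
}

#' Build a simulation configuration
#'
#' Defaults emulate the study cohort: 14 tumors sampled at 3--5 regions on
#' the five-gene panel at mean depth 950x. Default per-gene truncal and
#' subclonal rates are the cohort per-patient mutation rates split by the
#' observed ubiquity fractions (VHL mutations ubiquitous when present; the
#' chromatin modulators ubiquitous in 60/33/33/25\% of mutant tumors).
#'
#' @param nPatients Number of tumors (default 14).
#' @param biopsiesPerPatient Integer range of regions per tumor (default
#'   \code{c(3, 5)}); a scalar fixes the count.
#' @param genePanel Gene symbols (default \code{\link{defaultGenePanel}()}).
#' @param truncalRate,subclonalRate Named per-gene probabilities; defaults
#'   as described above.
#' @param meanDepth Mean sequencing depth; per-site depth is Poisson,
#'   floored at 1 read. Default 950.
#' @param purity Tumor purity; expected heterozygous VAF is
#'   \code{0.5 * purity}. Default 1.
#' @param errorRate Per-base sequencing error rate (default 1e-3).
#' @param decoyRates Named Poisson rates per biopsy for \code{germline},
#'   \code{synonymous} and \code{artifact} decoy calls (default 0.5/0.3/0.3).
#' @param doubleMutationRate Probability of emitting a second distinct
#'   mutation of the same gene in a disjoint region set for tumors with
#'   subclonal mutations (default 0).
#' @param seed Default RNG seed (default 1).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nPatients = 14,
                             biopsiesPerPatient = c(3, 5),
                             genePanel = defaultGenePanel(),
                             truncalRate = NULL,
                             subclonalRate = NULL,
                             meanDepth = 950,
                             purity = 1,
                             errorRate = 1e-3,
                             decoyRates = c(germline = 0.5,
                                            synonymous = 0.3,
                                            artifact = 0.3),
                             doubleMutationRate = 0,
                             seed = 1L) {
  if (length(biopsiesPerPatient) == 1L) {
    biopsiesPerPatient <- rep(biopsiesPerPatient, 2L)
  }
  if (is.null(truncalRate)) {
    truncalRate <- c(VHL = 9 / 14, PBRM1 = 0.6 * 5 / 14,
                     SETD2 = (1 / 3) * 3 / 14, BAP1 = (1 / 3) * 3 / 14,
                     KDM5C = 0.25 * 4 / 14)
    truncalRate <- truncalRate[names(truncalRate) %in% genePanel]
    missing <- setdiff(genePanel, names(truncalRate))
    truncalRate[missing] <- 0.1
    truncalRate <- truncalRate[genePanel]
  }
  if (is.null(subclonalRate)) {
    subclonalRate <- c(VHL = 0, PBRM1 = 0.4 * 5 / 14,
                       SETD2 = (2 / 3) * 3 / 14, BAP1 = (2 / 3) * 3 / 14,
                       KDM5C = 0.75 * 4 / 14)
    subclonalRate <- subclonalRate[names(subclonalRate) %in% genePanel]
    missing <- setdiff(genePanel, names(subclonalRate))
    subclonalRate[missing] <- 0.1
    subclonalRate <- subclonalRate[genePanel]
  }
  obj <- new("SimulationConfig",
    nPatients = .checkCount(nPatients, "nPatients"),
    biopsiesPerPatient = as.integer(biopsiesPerPatient),
    genePanel = genePanel,
    truncalRate = truncalRate[genePanel],
    subclonalRate = subclonalRate[genePanel],
    meanDepth = meanDepth,
    purity = purity,
    errorRate = errorRate,
    decoyRates = decoyRates,
    doubleMutationRate = doubleMutationRate,
    seed = as.integer(seed)
  )
  validObject(obj)
  obj
}

## all proper sub-clusters of a random hierarchical (binary) partition of
## the region set; any selection of these is a laminar family
.randomLaminarClusters <- function(regs) {
  if (length(regs) <= 1L) return(list())
  k <- sample.int(length(regs) - 1L, 1L)
  idx <- sample.int(length(regs), k)
  a <- regs[idx]
  b <- regs[-idx]
  c(list(a, b), .randomLaminarClusters(a), .randomLaminarClusters(b))
}

.mintVariant <- function(gene, counterEnv, indelOk = TRUE) {
  locus <- .geneLocus(gene)
  counterEnv$i <- counterEnv$i + 1L
  pos <- locus$start + counterEnv$i
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1L)
  csq <- sample(
    if (indelOk) c("missense", "nonsense", "frameshift_indel") else
      c("missense", "nonsense"),
    1L, prob = if (indelOk) c(0.6, 0.2, 0.2) else c(0.75, 0.25)
  )
  isIndel <- csq == "frameshift_indel"
  alt <- if (isIndel) paste0(ref, sample(bases, 1L)) else
    sample(setdiff(bases, ref), 1L)
  list(
    chrom = locus$chrom, pos = pos, ref = ref, alt = alt,
    key = paste(locus$chrom, pos, ref, alt, sep = ":"),
    consequence = csq, is_indel = isIndel
  )
}

#' Simulate ground-truth clonal structures for a cohort
#'
#' For each tumor: draws a region count uniformly from the configured range,
#' assigns truncal mutations (present in all regions) per gene with the
#' truncal rate, and subclonal mutations whose region-sets are drawn from a
#' random hierarchical partition of the regions, so that all region-sets
#' within a tumor are pairwise nested or disjoint (a laminar family — the
#' condition for a perfect phylogeny). With positive
#' \code{doubleMutationRate}, a tumor carrying a subclonal mutation may gain
#' a second distinct mutation of the same gene in a disjoint region set
#' (the double-mutant pattern).
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param seed RNG seed (default: the config's seed).
#' @return A \code{SyntheticTruth}: list with \code{patients} (each holding
#'   \code{patientId}, \code{regions} and a \code{mutations} data frame with
#'   variant key, gene, truncal/subclonal class, coordinates and the
#'   comma-separated region set) and \code{genePanel}.
#' @export
simulateTumorTruth <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(seed)
  counter <- new.env(); counter$i <- 0L
  patients <- lapply(seq_len(config@nPatients), function(i) {
    pid <- sprintf("S%02d", i)
    k <- sample(seq(config@biopsiesPerPatient[1],
                    config@biopsiesPerPatient[2]), 1L)
    regs <- sprintf("R%d", seq_len(k))
    clusters <- if (k > 1L) .randomLaminarClusters(regs) else list()
    rows <- list()
    for (g in config@genePanel) {
      if (runif(1) < config@truncalRate[[g]]) {
        v <- .mintVariant(g, counter)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_key = v$key, gene = g, class = "truncal",
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          consequence = v$consequence, is_indel = v$is_indel,
          region_set = paste(regs, collapse = ",")
        )
      }
      if (length(clusters) && runif(1) < config@subclonalRate[[g]]) {
        cl <- clusters[[sample.int(length(clusters), 1L)]]
        v <- .mintVariant(g, counter)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_key = v$key, gene = g, class = "subclonal",
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          consequence = v$consequence, is_indel = v$is_indel,
          region_set = paste(sort(cl), collapse = ",")
        )
        if (runif(1) < config@doubleMutationRate) {
          disjoint <- Filter(function(x) !any(x %in% cl), clusters)
          if (length(disjoint)) {
            cl2 <- disjoint[[sample.int(length(disjoint), 1L)]]
            v2 <- .mintVariant(g, counter)
            rows[[length(rows) + 1L]] <- data.frame(
              variant_key = v2$key, gene = g, class = "subclonal",
              chrom = v2$chrom, pos = v2$pos, ref = v2$ref, alt = v2$alt,
              consequence = v2$consequence, is_indel = v2$is_indel,
              region_set = paste(sort(cl2), collapse = ",")
            )
          }
        }
      }
    }
    mutations <- if (length(rows)) do.call(rbind, rows) else
      data.frame(
        variant_key = character(), gene = character(), class = character(),
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), consequence = character(), is_indel = logical(),
        region_set = character()
      )
    list(patientId = pid, regions = regs, mutations = mutations)
  })
  structure(
    list(patients = patients, genePanel = config@genePanel, seed = seed),
    class = "SyntheticTruth"
  )
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  nm <- sum(vapply(x$patients, function(p) nrow(p$mutations), integer(1)))
  cat(sprintf(
    "SyntheticTruth: %d patient(s), %d mutation(s), panel: %s\n",
    length(x$patients), nm, paste(x$genePanel, collapse = ", ")
  ))
  invisible(x)
}

#' Ground-truth tumor profiles from a SyntheticTruth
#'
#' Converts the simulated truth directly into \linkS4class{TumorProfile}
#' objects (bypassing read-count simulation and filtering), for use as the
#' reference in recovery tests.
#'
#' @param truth A \code{SyntheticTruth}.
#' @return A \linkS4class{CohortData}.
#' @export
truthProfiles <- function(truth) {
  profs <- lapply(truth$patients, function(p) {
    if (nrow(p$mutations) == 0L) return(tumorProfile(p$patientId, p$regions))
    m <- matrix(0L, nrow = nrow(p$mutations), ncol = length(p$regions),
                dimnames = list(p$mutations$variant_key, p$regions))
    for (i in seq_len(nrow(p$mutations))) {
      m[i, strsplit(p$mutations$region_set[i], ",", fixed = TRUE)[[1]]] <- 1L
    }
    tumorProfile(p$patientId, p$regions, m,
                 setNames(p$mutations$gene, p$mutations$variant_key))
  })
  cohortData(profs, genePanel = truth$genePanel)
}

.emptyCallTable <- function() {
  data.frame(
    patient_id = character(), region_id = character(), gene = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), depth = integer(), alt_reads = integer(),
    consequence = character(), in_dbsnp = logical(), is_indel = logical(),
    origin = character()
  )
}

.simDepth <- function(n, meanDepth) pmax(1L, rpois(n, meanDepth))

#' Simulate per-biopsy variant call tables from a ground truth
#'
#' Adds the read-count layer on top of a \code{SyntheticTruth}. For a biopsy
#' inside a mutation's region set, depth is Poisson around the mean depth
#' (floored at 1) and alt reads are binomial with expected VAF
#' \code{0.5 * purity} (heterozygous diploid, single-clone core); biopsies
#' outside the region set accrue alt reads only at the sequencing error
#' rate, and a call row is emitted only when at least one alt read is seen.
#' Decoy calls — dbSNP-flagged germline SNVs (VAF ~ 0.5), synonymous calls,
#' and sub-threshold artifacts (expected VAF 2\%) — are injected per biopsy
#' at the configured Poisson rates; all are recoverable by the filter rules.
#' An \code{origin} column tags each row (\code{somatic}, \code{error},
#' \code{germline_decoy}, \code{synonymous_decoy}, \code{artifact_decoy})
#' for validation; it is ignored by the filter.
#'
#' @param truth A \code{SyntheticTruth}.
#' @param config The \linkS4class{SimulationConfig} used to generate it.
#' @param seed RNG seed (default: config's seed + 1).
#' @return Data frame of variant calls across all patients and biopsies.
#' @export
simulateVariantCalls <- function(truth, config, seed = config@seed + 1L) {
  validObject(config)
  if (!identical(truth$genePanel, config@genePanel)) {
    stop("truth and config disagree on the gene panel", call. = FALSE)
  }
  set.seed(seed)
  counter <- new.env(); counter$i <- 500000L  # decoy coordinate space
  vafTrue <- 0.5 * config@purity
  rows <- list()
  for (p in truth$patients) {
    muts <- p$mutations
    for (region in p$regions) {
      if (nrow(muts)) {
        inSet <- vapply(
          strsplit(muts$region_set, ",", fixed = TRUE),
          function(rs) region %in% rs, logical(1)
        )
        depth <- .simDepth(nrow(muts), config@meanDepth)
        pDet <- ifelse(inSet, vafTrue, config@errorRate)
        alt <- rbinom(nrow(muts), depth, pDet)
        keep <- alt >= 1L
        if (any(keep)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = p$patientId, region_id = region,
            gene = muts$gene[keep], chrom = muts$chrom[keep],
            pos = muts$pos[keep], ref = muts$ref[keep],
            alt = muts$alt[keep], depth = depth[keep],
            alt_reads = alt[keep], consequence = muts$consequence[keep],
            in_dbsnp = FALSE, is_indel = muts$is_indel[keep],
            origin = ifelse(inSet[keep], "somatic", "error")
          )
        }
      }
      ## decoys
      for (type in c("germline", "synonymous", "artifact")) {
        nDecoy <- rpois(1L, config@decoyRates[[type]])
        if (nDecoy == 0L) next
        for (d in seq_len(nDecoy)) {
          g <- sample(config@genePanel, 1L)
          v <- .mintVariant(g, counter, indelOk = FALSE)
          depth <- .simDepth(1L, config@meanDepth)
          vafDecoy <- switch(type,
            germline = 0.5, synonymous = 0.5, artifact = 0.02
          )
          alt <- rbinom(1L, depth, vafDecoy)
          if (alt < 1L) next
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = p$patientId, region_id = region, gene = g,
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            depth = depth, alt_reads = alt,
            consequence = if (type == "synonymous") "synonymous" else
              v$consequence,
            in_dbsnp = type == "germline", is_indel = FALSE,
            origin = paste0(type, "_decoy")
          )
        }
      }
    }
  }
  if (length(rows) == 0L) return(.emptyCallTable())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region declaration table of a SyntheticTruth
#'
#' @param truth A \code{SyntheticTruth}.
#' @return Data frame with \code{patient_id}, \code{region_id} for every
#'   sampled biopsy (including biopsies that yield no calls).
#' @export
truthRegions <- function(truth) {
  do.call(rbind, lapply(truth$patients, function(p) {
    data.frame(patient_id = p$patientId, region_id = p$regions)
  }))
}

#' Simulate a cohort of independent Bernoulli biopsy detections
#'
#' The sampling model behind the power calculation: biopsies are independent
#' and randomly placed within the tumor, so for a patient carrying a
#' mutation in a gene with intratumor prevalence p, each biopsy detects it
#' independently with probability p. Each patient is first marked
#' mutant/non-mutant per gene (with probability \code{carrierRate}); each
#' biopsy of a mutant patient is then positive independently with
#' probability \code{pByGene[gene]}.
#'
#' @param pByGene Named numeric vector of per-gene detection probabilities.
#' @param nPatients Number of patients.
#' @param biopsiesPerPatient Biopsies per patient (scalar).
#' @param seed RNG seed.
#' @param carrierRate Probability a patient is mutant per gene (default 1:
#'   an all-mutant cohort, the regime for estimator validation).
#' @return List with \code{cohort} (a \linkS4class{CohortData}; each
#'   detected gene contributes one synthetic mutation whose region set is
#'   the positive biopsies) and \code{truth} (data frame of
#'   patient-by-gene carrier flags and positive-biopsy counts).
#' @export
simulateBernoulliCohort <- function(pByGene, nPatients, biopsiesPerPatient,
                                    seed = 1L, carrierRate = 1) {
  .checkProb(unlist(pByGene), "pByGene")
  .checkProb(carrierRate, "carrierRate")
  nPatients <- .checkCount(nPatients, "nPatients")
  nb <- .checkCount(biopsiesPerPatient, "biopsiesPerPatient")
  if (is.null(names(pByGene)) || any(!nzchar(names(pByGene)))) {
    stop("pByGene must be a named vector", call. = FALSE)
  }
  set.seed(seed)
  genes <- names(pByGene)
  regs <- sprintf("R%d", seq_len(nb))
  truthRows <- list()
  profs <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    pid <- sprintf("B%05d", i)
    keys <- character(); rowsets <- list(); geneMap <- character()
    for (g in genes) {
      carrier <- runif(1) < carrierRate
      hits <- if (carrier) rbinom(nb, 1L, pByGene[[g]]) else integer(nb)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        patient_id = pid, gene = g, carrier = carrier,
        n_positive = sum(hits), n_biopsies = nb
      )
      if (sum(hits) > 0L) {
        key <- sprintf("%s:%s:sim", g, pid)
        keys <- c(keys, key)
        rowsets[[key]] <- hits
        geneMap[key] <- g
      }
    }
    m <- if (length(keys)) {
      matrix(unlist(rowsets[keys]), nrow = length(keys), byrow = TRUE,
             dimnames = list(keys, regs))
    } else NULL
    profs[[i]] <- tumorProfile(pid, regs, m, geneMap)
  }
  list(
    cohort = cohortData(profs, genePanel = genes),
    truth = do.call(rbind, truthRows)
  )
}
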