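#' Construct a TumorProfile from a presence matrix
#'
#' @param patientId Patient/tumor identifier.
#' @param regions Ordered region identifiers (biopsy cores).
#' @param presence 0/1 matrix (mutations x regions) or NULL/0-row for a
#'   tumor with no detected mutations; rownames are variant keys.
#' @param genes Named character vector mapping variant keys to gene symbols.
#' @return A \linkS4class{TumorProfile} with shared/nonshared labels set.
#' @export
tumorProfile <- function(patientId, regions, presence = NULL,
                         genes = character()) {
  regions <- as.character(regions)
  if (is.null(presence)) {
    presence <- matrix(integer(), nrow = 0L, ncol = length(regions),
                       dimnames = list(NULL, regions))
  }
  storage.mode(presence) <- "integer"
  colnames(presence) <- regions
  prof <- new("TumorProfile",
    patientId = as.character(patientId), regions = regions,
    presence = presence, genes = genes, labels = character()
  )
  prof@labels <- classifyShared(prof)
  validObject(prof)
  prof
}

#' Build per-tumor presence matrices from filtered variant calls
#'
#' Aggregates filtered per-biopsy calls into one binary mutation-by-region
#' matrix per patient. Identical variant keys (same chrom:pos:ref:alt)
#' observed in several regions collapse to one row; two distinct mutations of
#' the same gene stay distinct rows. Declared regions with zero calls are
#' kept as all-zero columns — a fully wild-type biopsy is informative and
#' still counts in denominators.
#'
#' @param calls Data frame of (filtered) variant calls carrying
#'   \code{patient_id}, \code{region_id}, \code{gene} and coordinate
#'   columns.
#' @param regionTable Data frame declaring the sampled biopsies:
#'   columns \code{patient_id}, \code{region_id}, in sampling order. Every
#'   call's region must be declared here.
#' @return Named list of \linkS4class{TumorProfile}, one per declared
#'   patient.
#' @export
buildPresenceMatrix <- function(calls, regionTable) {
  if (!all(c("patient_id", "region_id") %in% names(regionTable))) {
    stop("regionTable needs patient_id and region_id columns", call. = FALSE)
  }
  patients <- unique(as.character(regionTable$patient_id))
  if (nrow(calls)) {
    known <- paste(regionTable$patient_id, regionTable$region_id, sep = "\r")
    seen <- paste(calls$patient_id, calls$region_id, sep = "\r")
    bad <- !(seen %in% known)
    if (any(bad)) {
      stop("call(s) in undeclared region: ",
           paste(unique(gsub("\r", "/", seen[bad])), collapse = ", "),
           call. = FALSE)
    }
    calls$.key <- variantKey(calls)
  }
  out <- lapply(patients, function(pid) {
    regs <- as.character(
      regionTable$region_id[regionTable$patient_id == pid]
    )
    pc <- if (nrow(calls)) {
      calls[calls$patient_id == pid, , drop = FALSE]
    } else {
      calls
    }
    if (nrow(pc) == 0L) {
      return(tumorProfile(pid, regs))
    }
    keys <- unique(pc$.key)
    m <- matrix(0L, nrow = length(keys), ncol = length(regs),
                dimnames = list(keys, regs))
    m[cbind(match(pc$.key, keys), match(pc$region_id, regs))] <- 1L
    genes <- setNames(
      as.character(pc$gene[match(keys, pc$.key)]), keys
    )
    tumorProfile(pid, regs, m, genes)
  })
  names(out) <- patients
  out
}

#' Classify mutations as shared (truncal) or nonshared (subclonal)
#'
#' A shared mutation is one detected in every biopsy core of the tumor; a
#' nonshared mutation is absent from at least one core. In a single-region
#' tumor every mutation is trivially shared.
#'
#' @param profile A \linkS4class{TumorProfile}.
#' @return Named character vector (\code{"shared"}/\code{"nonshared"}) per
#'   variant key.
#' @export
classifyShared <- function(profile) {
  p <- profile@presence
  if (nrow(p) == 0L) return(setNames(character(), character()))
  setNames(
    ifelse(rowSums(p) == ncol(p), "shared", "nonshared"),
    rownames(p)
  )
}

#' Assemble a cohort from tumor profiles
#'
#' @param profiles List of \linkS4class{TumorProfile}.
#' @param genePanel Genes targeted by the assay; defaults to
#'   \code{\link{defaultGenePanel}()} extended by any gene seen in the
#'   profiles.
#' @return A \linkS4class{CohortData}.
#' @export
cohortData <- function(profiles, genePanel = NULL) {
  seen <- unique(unlist(lapply(profiles, function(p) unname(p@genes))))
  if (is.null(genePanel)) {
    genePanel <- canonicalGeneOrder(union(defaultGenePanel(), seen))
  }
  obj <- new("CohortData", profiles = unname(profiles), genePanel = genePanel)
  validObject(obj)
  obj
}

## per-patient gene-level biopsy positivity: for one profile, named integer
## vector (per gene in panel) of regions with >= 1 mutation in the gene
.genePositiveRegions <- function(profile, panel) {
  p <- profile@presence
  out <- setNames(integer(length(panel)), panel)
  if (nrow(p) == 0L) return(out)
  for (g in panel) {
    rows <- which(unname(profile@genes[rownames(p)]) == g)
    if (length(rows)) {
      out[g] <- sum(colSums(p[rows, , drop = FALSE]) > 0L)
    }
  }
  out
}

#' Per-gene mutation rates by patient and by biopsy core
#'
#' For each gene in the panel: the patient-level rate (patients with at
#' least one mutation in the gene over all patients) and the biopsy-level
#' rate (cores with at least one mutation in the gene over all cores).
#' Numerators and denominators are returned alongside the rates.
#'
#' @param cohort A \linkS4class{CohortData} with at least one profile.
#' @return Data frame with one row per panel gene: \code{gene},
#'   \code{n_patients_mutant}, \code{n_patients}, \code{patient_rate},
#'   \code{n_biopsies_mutant}, \code{n_biopsies}, \code{biopsy_rate}.
#' @export
cohortFrequencies <- function(cohort) {
  profs <- cohort@profiles
  if (length(profs) == 0L) stop("empty cohort", call. = FALSE)
  panel <- cohort@genePanel
  posReg <- vapply(profs, .genePositiveRegions, integer(length(panel)),
                   panel = panel)
  posReg <- matrix(posReg, nrow = length(panel),
                   dimnames = list(panel, NULL))
  nBiopsies <- sum(vapply(profs, function(p) length(p@regions), integer(1)))
  data.frame(
    gene = panel,
    n_patients_mutant = as.integer(rowSums(posReg > 0L)),
    n_patients = length(profs),
    patient_rate = rowSums(posReg > 0L) / length(profs),
    n_biopsies_mutant = as.integer(rowSums(posReg)),
    n_biopsies = nBiopsies,
    biopsy_rate = rowSums(posReg) / nBiopsies,
    row.names = NULL
  )
}

#' Ubiquity fraction of a gene's mutations across mutant tumors
#'
#' Among tumors carrying at least one mutation in the gene, the fraction in
#' which every biopsy core carries a mutation in that gene (i.e. the gene's
#' mutation is ubiquitous/shared at gene level).
#'
#' @param cohort A \linkS4class{CohortData}.
#' @param gene Gene symbol.
#' @return List with \code{fraction}, \code{n_ubiquitous} and
#'   \code{n_mutant_tumors}. A gene mutated in no tumor has no defined
#'   ubiquity: an error of class \code{undefinedEstimate} is signalled
#'   rather than returning 0.
#' @export
ubiquityFraction <- function(cohort, gene) {
  profs <- cohort@profiles
  pos <- vapply(profs, function(p) {
    .genePositiveRegions(p, gene)[[1]]
  }, integer(1))
  k <- vapply(profs, function(p) length(p@regions), integer(1))
  mutant <- pos > 0L
  if (!any(mutant)) {
    .undefined(sprintf(
      "ubiquity of '%s' is undefined: no mutant tumor in cohort", gene
    ))
  }
  list(
    fraction = sum(pos[mutant] == k[mutant]) / sum(mutant),
    n_ubiquitous = sum(pos[mutant] == k[mutant]),
    n_mutant_tumors = sum(mutant)
  )
}

#' Histogram of unique mutation counts per tumor
#'
#' Counts distinct variant keys (not genes: a tumor with two distinct
#' mutations of one gene contributes two) per tumor and tabulates the
#' cohort into bins 0, 1, 2, ...
#'
#' @param cohort A \linkS4class{CohortData}.
#' @return Named integer vector; names are mutation counts ("0", "1", ...),
#'   values are numbers of tumors. Empty cohort gives an empty vector.
#' @export
mutationsPerTumor <- function(cohort) {
  profs <- cohort@profiles
  if (length(profs) == 0L) return(setNames(integer(), character()))
  counts <- vapply(profs, function(p) nrow(p@presence), integer(1))
  tab <- table(factor(counts, levels = 0:max(counts)))
  setNames(as.integer(tab), names(tab))
}
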