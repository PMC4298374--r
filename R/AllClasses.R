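#' @import methods
NULL

#' TumorProfile: binary mutation-by-region presence for one tumor
#'
#' One tumor sampled at k spatially distinct biopsy cores (regions). Each row
#' of \code{presence} is one distinct somatic mutation (identified by its
#' variant key, \code{chrom:pos:ref:alt}), each column one region; entries are
#' 0/1 detection calls after filtering. A mutation detected in every region is
#' labelled \code{shared} (truncal); one absent from at least one region is
#' \code{nonshared} (subclonal).
#'
#' @slot patientId Single patient/tumor identifier.
#' @slot regions Ordered character vector of region identifiers (the biopsy
#'   cores); a region with no mutations is retained as an all-zero column.
#' @slot presence Integer 0/1 matrix, rows = variant keys, cols = regions.
#' @slot genes Named character vector mapping variant key to gene symbol; two
#'   distinct variant keys may share a gene.
#' @slot labels Named character vector (\code{"shared"}/\code{"nonshared"})
#'   per variant key.
#'
#' @export
setClass("TumorProfile",
  representation(
    patientId = "character",
    regions = "character",
    presence = "matrix",
    genes = "character",
    labels = "character"
  )
)

setValidity("TumorProfile", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be length 1")
  if (length(object@regions) < 1L) msg <- c(msg, "at least one region required")
  if (anyDuplicated(object@regions)) msg <- c(msg, "region ids must be unique")
  p <- object@presence
  if (ncol(p) != length(object@regions) ||
      !identical(colnames(p), object@regions)) {
    msg <- c(msg, "presence columns must match regions")
  }
  if (nrow(p) > 0L) {
    if (is.null(rownames(p)) || anyDuplicated(rownames(p))) {
      msg <- c(msg, "presence rows must have unique variant keys")
    }
    if (!all(p %in% c(0L, 1L))) msg <- c(msg, "presence must be 0/1")
    if (any(rowSums(p) == 0L)) {
      msg <- c(msg, "every mutation must be present in at least one region")
    }
    if (!all(rownames(p) %in% names(object@genes))) {
      msg <- c(msg, "every variant key needs a gene assignment")
    }
    if (length(object@labels)) {
      if (!setequal(names(object@labels), rownames(p))) {
        msg <- c(msg, "labels must cover exactly the variant keys")
      } else {
        shared <- rowSums(p) == ncol(p)
        bad <- (object@labels[rownames(p)] == "shared") != shared
        if (any(bad)) msg <- c(msg, "label 'shared' must equal all-ones row")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' CohortData: a collection of tumor profiles
#'
#' @slot profiles List of \linkS4class{TumorProfile}, one per patient;
#'   patient ids are unique.
#' @slot genePanel Character vector of genes targeted by the assay.
#'
#' @export
setClass("CohortData",
  representation(profiles = "list", genePanel = "character")
)

setValidity("CohortData", function(object) {
  msg <- character()
  ok <- vapply(object@profiles, is, logical(1), class2 = "TumorProfile")
  if (!all(ok)) msg <- c(msg, "profiles must all be TumorProfile")
  ids <- vapply(object@profiles, function(p) p@patientId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "patient ids must be unique")
  if (length(msg)) msg else TRUE
})

#' CloneTree: rooted clonal phylogeny of one tumor
#'
#' Perfect-phylogeny reconstruction from a \linkS4class{TumorProfile}: each
#' mutation arises exactly once and is never lost, the ancestral state is
#' all-wild-type, and a tree exists iff mutation region-sets are pairwise
#' nested or disjoint. Nodes are clones; the root's incoming edge carries the
#' shared (truncal) mutations; biopsy regions attach as leaves to the clone
#' whose accumulated mutation set equals that region's observed mutations.
#'
#' The \code{root} slot is a recursive list of nodes, each with elements
#' \code{mutations} (variant keys gained on the incoming edge),
#' \code{regions} (regions attached as leaves at this clone), and
#' \code{children} (list of child nodes).
#'
#' @slot patientId Patient/tumor identifier.
#' @slot root Recursive node list (see Details).
#' @slot genes Named character vector, variant key to gene symbol (may be
#'   empty for trees parsed from text).
#'
#' @export
setClass("CloneTree",
  representation(patientId = "character", root = "list", genes = "character")
)

#' PrevalenceEstimate: pooled intratumor mutation prevalence for one gene
#'
#' The intratumor prevalence p of a gene's mutation, operationalized as the
#' proportion of all biopsies carrying a mutation in the gene, pooled across
#' the patients who have at least one positive biopsy. Patients with zero
#' positive biopsies are excluded from numerator and denominator (they are
#' assumed not to carry the mutation).
#'
#' @slot gene Gene symbol.
#' @slot p Prevalence in (0, 1].
#' @slot nPositive Positive biopsies over included patients.
#' @slot nTotal Total biopsies over included patients.
#' @slot nPatients Number of included (mutation-positive) patients.
#'
#' @export
setClass("PrevalenceEstimate",
  representation(
    gene = "character", p = "numeric",
    nPositive = "integer", nTotal = "integer", nPatients = "integer"
  )
)

setValidity("PrevalenceEstimate", function(object) {
  msg <- character()
  if (object@nTotal < 1L || object@nPositive < 1L ||
      object@nPositive > object@nTotal) {
    msg <- c(msg, "need 1 <= nPositive <= nTotal")
  }
  if (abs(object@p - object@nPositive / object@nTotal) > 1e-12) {
    msg <- c(msg, "p must equal nPositive/nTotal")
  }
  if (length(msg)) msg else TRUE
})

#' PowerCurve: biopsy detection probability per gene
#'
#' Detection probability 1 - (1 - p)^n for n = 1..nMax biopsies per gene,
#' under the binomial model with independent, randomly placed biopsies.
#'
#' @slot p Named numeric vector of per-gene prevalences.
#' @slot nMax Largest number of biopsies tabulated.
#' @slot values Numeric matrix, genes x n (columns n = 1..nMax).
#'
#' @export
setClass("PowerCurve",
  representation(p = "numeric", nMax = "integer", values = "matrix")
)

setValidity("PowerCurve", function(object) {
  msg <- character()
  v <- object@values
  if (ncol(v) != object@nMax) msg <- c(msg, "values must have nMax columns")
  if (!identical(rownames(v), names(object@p))) {
    msg <- c(msg, "value rows must match the prevalence map")
  }
  if (any(v < 0 | v > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (ncol(v) > 1L && any(v[, -1L, drop = FALSE] + 1e-12 <
                          v[, -ncol(v), drop = FALSE])) {
    msg <- c(msg, "detection probability must be nondecreasing in n")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic multi-region cohort
#'
#' Defaults emulate a cohort of 14 primary clear cell renal carcinomas,
#' each sampled at 3--5 regions, sequenced on a five-gene panel at a mean
#' depth of 950x. Per-gene truncal and subclonal mutation rates default to
#' the product of the cohort's per-patient mutation rate and its observed
#' ubiquity/non-ubiquity split (see the package vignette).
#'
#' @slot nPatients Number of tumors.
#' @slot biopsiesPerPatient Integer range (min, max) of regions per tumor.
#' @slot genePanel Genes assayed.
#' @slot truncalRate Named per-gene probability of a truncal mutation.
#' @slot subclonalRate Named per-gene probability of a subclonal mutation.
#' @slot meanDepth Mean sequencing depth (reads); per-site depth is Poisson.
#' @slot purity Tumor purity in [0, 1]; expected heterozygous VAF is
#'   0.5 * purity.
#' @slot errorRate Per-base sequencing error rate (alt reads at wild-type
#'   sites).
#' @slot decoyRates Named Poisson rates per biopsy for decoy calls:
#'   \code{germline} (dbSNP-flagged SNVs), \code{synonymous}, and
#'   \code{artifact} (sub-threshold VAF).
#' @slot doubleMutationRate Probability that a tumor with a subclonal
#'   mutation gains a second, distinct mutation of the same gene in a
#'   disjoint region set (the double-mutant pattern).
#' @slot seed Default RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nPatients = "integer",
    biopsiesPerPatient = "integer",
    genePanel = "character",
    truncalRate = "numeric",
    subclonalRate = "numeric",
    meanDepth = "numeric",
    purity = "numeric",
    errorRate = "numeric",
    decoyRates = "numeric",
    doubleMutationRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  b <- object@biopsiesPerPatient
  if (length(b) != 2L || b[1] < 1L || b[2] < b[1]) {
    msg <- c(msg, "biopsiesPerPatient must be a valid range with min >= 1")
  }
  for (nm in c("truncalRate", "subclonalRate")) {
    r <- slot(object, nm)
    if (!setequal(names(r), object@genePanel)) {
      msg <- c(msg, sprintf("%s must be named by the gene panel", nm))
    }
    if (any(r < 0 | r > 1)) msg <- c(msg, sprintf("%s must be in [0, 1]", nm))
  }
  if (object@meanDepth < 1) msg <- c(msg, "meanDepth must be >= 1")
  if (object@purity < 0 || object@purity > 1) msg <- c(msg, "purity in [0, 1]")
  if (object@errorRate < 0 || object@errorRate > 1) {
    msg <- c(msg, "errorRate in [0, 1]")
  }
  if (!all(c("germline", "synonymous", "artifact") %in%
           names(object@decoyRates)) || any(object@decoyRates < 0)) {
    msg <- c(msg, "decoyRates needs nonnegative germline/synonymous/artifact")
  }
  if (object@doubleMutationRate < 0 || object@doubleMutationRate > 1) {
    msg <- c(msg, "doubleMutationRate in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
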