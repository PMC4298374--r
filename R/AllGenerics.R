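#' Accessors for package classes
#'
#' @param x A \linkS4class{TumorProfile}, \linkS4class{CohortData},
#'   \linkS4class{CloneTree}, \linkS4class{PrevalenceEstimate} or
#'   \linkS4class{PowerCurve} as appropriate.
#'
#' @return \code{patientId}: the patient identifier; \code{regions}: region
#'   ids; \code{presence}: the 0/1 mutation-by-region matrix;
#'   \code{mutationGenes}: named variant-key-to-gene map;
#'   \code{mutationLabels}: named shared/nonshared labels; \code{profiles}:
#'   list of profiles; \code{genePanel}: gene panel; \code{prevalence}: the
#'   numeric prevalence; \code{powerValues}: the gene-by-n probability
#'   matrix.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname accessors
#' @export
setGeneric("mutationGenes", function(x) standardGeneric("mutationGenes"))
#' @rdname accessors
#' @export
setGeneric("mutationLabels", function(x) standardGeneric("mutationLabels"))
#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("genePanel", function(x) standardGeneric("genePanel"))
#' @rdname accessors
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))
#' @rdname accessors
#' @export
setGeneric("powerValues", function(x) standardGeneric("powerValues"))

#' @rdname accessors
#' @export
setMethod("patientId", "TumorProfile", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "CloneTree", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("regions", "TumorProfile", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("presence", "TumorProfile", function(x) x@presence)
#' @rdname accessors
#' @export
setMethod("mutationGenes", "TumorProfile", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("mutationGenes", "CloneTree", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("mutationLabels", "TumorProfile", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("profiles", "CohortData", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("genePanel", "CohortData", function(x) x@genePanel)
#' @rdname accessors
#' @export
setMethod("genePanel", "SimulationConfig", function(x) x@genePanel)
#' @rdname accessors
#' @export
setMethod("prevalence", "PrevalenceEstimate", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("powerValues", "PowerCurve", function(x) x@values)

setMethod("show", "TumorProfile", function(object) {
  cat(sprintf(
    "TumorProfile '%s': %d mutation(s) x %d region(s)\n",
    object@patientId, nrow(object@presence), length(object@regions)
  ))
  if (nrow(object@presence)) {
    lab <- object@labels[rownames(object@presence)]
    cat(sprintf(
      "  shared: %d, nonshared: %d\n",
      sum(lab == "shared"), sum(lab == "nonshared")
    ))
    print(object@presence)
  }
})

setMethod("show", "CohortData", function(object) {
  nb <- sum(vapply(object@profiles, function(p) length(p@regions), integer(1)))
  cat(sprintf(
    "CohortData: %d tumor(s), %d biopsy core(s), panel: %s\n",
    length(object@profiles), nb, paste(object@genePanel, collapse = ", ")
  ))
})

setMethod("show", "PrevalenceEstimate", function(object) {
  cat(sprintf(
    "PrevalenceEstimate %s: p = %.3f (%d/%d biopsies over %d patient(s))\n",
    object@gene, object@p, object@nPositive, object@nTotal, object@nPatients
  ))
})

setMethod("show", "PowerCurve", function(object) {
  cat(sprintf(
    "PowerCurve: %d gene(s), n = 1..%d\n", length(object@p), object@nMax
  ))
  print(round(object@values, 3))
})

setMethod("show", "CloneTree", function(object) {
  cat(sprintf("CloneTree '%s':\n", object@patientId))
  cat(renderTree(object, format = "newick"), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0(
      "SimulationConfig: %d patients, %d-%d biopsies each, depth %gx, ",
      "purity %.2f, error %g\n"
    ),
    object@nPatients, object@biopsiesPerPatient[1],
    object@biopsiesPerPatient[2], object@meanDepth, object@purity,
    object@errorRate
  ))
})
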