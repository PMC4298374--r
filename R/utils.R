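#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default five-gene renal tumor suppressor panel
#'
#' The canonical targeted panel for clear cell renal cell carcinoma:
#' \emph{VHL}, \emph{PBRM1}, \emph{SETD2}, \emph{BAP1}, \emph{KDM5C}.
#'
#' @return Character vector of gene symbols.
#' @export
defaultGenePanel <- function() {
  c("VHL", "PBRM1", "SETD2", "BAP1", "KDM5C")
}

## canonical display order: panel genes first, anything else alphabetical
canonicalGeneOrder <- function(genes, panel = defaultGenePanel()) {
  genes <- unique(genes)
  known <- panel[panel %in% genes]
  extra <- sort(setdiff(genes, panel))
  c(known, extra)
}

.checkProb <- function(p, what = "probability") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must be numeric in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

.checkCount <- function(n, what = "count", min = 1L) {
  if (!is.numeric(n) || anyNA(n) || any(n != floor(n)) || any(n < min)) {
    stop(sprintf("%s must be an integer >= %d", what, min), call. = FALSE)
  }
  invisible(as.integer(n))
}

## explicit signal for quantities that are undefined on the given input
## (e.g. prevalence of a gene never detected), distinguishable from 0
.undefined <- function(msg) {
  cond <- structure(
    class = c("undefinedEstimate", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

## set-of-regions key, invariant to input order
.setKey <- function(regions) paste(sort(regions), collapse = "\r")
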