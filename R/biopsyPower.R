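#' Estimate pooled intratumor mutation prevalence for one gene
#'
#' The intratumor prevalence p of a gene's mutation — the proportion of the
#' tumor carrying it — is operationalized as the proportion of all biopsy
#' cores with a mutation in the gene, pooled across the patients who have at
#' least one positive core. Patients with no positive core are excluded from
#' numerator and denominator under the working assumption that they do not
#' carry the mutation; biopsies are assumed independent and randomly placed.
#'
#' @param cohort A \linkS4class{CohortData}.
#' @param gene Gene symbol.
#' @return A \linkS4class{PrevalenceEstimate}. If no patient has a positive
#'   biopsy for the gene, prevalence is undefined and an error of class
#'   \code{undefinedEstimate} is signalled.
#' @examples
#' ## two mutant patients with 2/3 and 3/4 positive cores pool to 5/7
#' @export
estimatePrevalence <- function(cohort, gene) {
  profs <- cohort@profiles
  if (length(profs) == 0L) stop("empty cohort", call. = FALSE)
  pos <- vapply(profs, function(p) .genePositiveRegions(p, gene)[[1]],
                integer(1))
  tot <- vapply(profs, function(p) length(p@regions), integer(1))
  keep <- pos > 0L
  if (!any(keep)) {
    .undefined(sprintf(
      "prevalence of '%s' undefined: no patient has a positive biopsy", gene
    ))
  }
  new("PrevalenceEstimate",
    gene = gene,
    p = sum(pos[keep]) / sum(tot[keep]),
    nPositive = sum(pos[keep]),
    nTotal = sum(tot[keep]),
    nPatients = sum(keep)
  )
}

#' Probability of detecting a mutation in n biopsies
#'
#' Under the binomial sampling model with intratumor prevalence p and
#' independent, randomly placed biopsies, the probability that at least one
#' of n biopsies samples a mutation-bearing region is
#' \deqn{P(n) = 1 - (1 - p)^n.}
#'
#' @param p Prevalence in [0, 1].
#' @param n Number of biopsies (nonnegative integer; vectorized).
#' @return Detection probability; \code{P(0) = 0}, \code{P(1) = p}.
#' @examples
#' detectionProbability(0.41, 3)  # 0.7946...
#' @export
detectionProbability <- function(p, n) {
  .checkProb(p, "p")
  .checkCount(n, "n", min = 0L)
  1 - (1 - p)^n
}

#' Minimum number of biopsies for a target detection certainty
#'
#' Smallest n >= 1 with \code{detectionProbability(p, n) >= target}
#' (inclusive comparison: reaching the target counts). Computed in closed
#' form as \code{ceil(log(1 - target) / log(1 - p))} with a guard against
#' floating-point edge effects, which always agrees with a linear search.
#'
#' @param p Prevalence in (0, 1].
#' @param target Detection certainty in (0, 1).
#' @return Integer number of biopsies. \code{p = 0} can never attain the
#'   target: an error of class \code{undefinedEstimate} is signalled.
#' @examples
#' minBiopsies(0.41, 0.90)  # 5
#' @export
minBiopsies <- function(p, target) {
  .checkProb(p, "p")
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop("target must lie in (0, 1)", call. = FALSE)
  }
  if (p == 0) {
    .undefined("prevalence 0: no number of biopsies attains the target")
  }
  if (p == 1) return(1L)
  n <- as.integer(ceiling(log(1 - target) / log(1 - p)))
  n <- max(n, 1L)
  ## guard rounding at the boundary
  while (n > 1L && detectionProbability(p, n - 1L) >= target) n <- n - 1L
  while (detectionProbability(p, n) < target) n <- n + 1L
  n
}

#' Minimum biopsies so every gene in a set reaches the target
#'
#' Each gene must individually reach the detection certainty, so the answer
#' is the maximum of per-gene \code{\link{minBiopsies}} — the lowest
#' prevalence gene binds.
#'
#' @param pByGene Named numeric vector of per-gene prevalences, all in
#'   (0, 1].
#' @param target Detection certainty in (0, 1).
#' @return Integer number of biopsies.
#' @examples
#' minBiopsiesForGeneSet(
#'   c(PBRM1 = 0.75, SETD2 = 0.70, BAP1 = 0.58, KDM5C = 0.55), 0.90
#' )  # 3
#' @export
minBiopsiesForGeneSet <- function(pByGene, target) {
  p <- unlist(pByGene)
  if (length(p) == 0L) stop("empty prevalence map", call. = FALSE)
  max(vapply(p, minBiopsies, integer(1), target = target))
}

#' Tabulate detection probability curves per gene
#'
#' @param pByGene Named numeric vector of per-gene prevalences in [0, 1].
#' @param nMax Largest number of biopsies to tabulate (default 10).
#' @return A \linkS4class{PowerCurve}.
#' @export
powerCurve <- function(pByGene, nMax = 10) {
  p <- unlist(pByGene)
  .checkProb(p, "pByGene")
  nMax <- .checkCount(nMax, "nMax")
  if (is.null(names(p))) names(p) <- sprintf("gene%d", seq_along(p))
  v <- outer(p, seq_len(nMax), function(pp, nn) 1 - (1 - pp)^nn)
  dimnames(v) <- list(names(p), as.character(seq_len(nMax)))
  new("PowerCurve", p = p, nMax = nMax, values = v)
}

#' Power curve as a long data frame
#'
#' @param curve A \linkS4class{PowerCurve}.
#' @return Data frame with \code{gene}, \code{n_biopsies},
#'   \code{detection_probability}.
#' @export
powerTable <- function(curve) {
  v <- curve@values
  data.frame(
    gene = rep(rownames(v), times = ncol(v)),
    n_biopsies = rep(seq_len(ncol(v)), each = nrow(v)),
    detection_probability = as.vector(v)
  )
}

#' Plot per-gene detection power against number of biopsies
#'
#' @param curve A \linkS4class{PowerCurve}.
#' @param target Optional horizontal reference line (e.g. 0.9).
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the curve.
#' @importFrom graphics matplot legend abline
#' @export
plotPowerCurve <- function(curve, target = NULL, ...) {
  v <- curve@values
  graphics::matplot(
    seq_len(ncol(v)), t(v), type = "b", pch = 19, lty = 1,
    xlab = "Number of biopsies", ylab = "Detection probability",
    ylim = c(0, 1), ...
  )
  if (!is.null(target)) graphics::abline(h = target, lty = 2)
  graphics::legend(
    "bottomright",
    legend = sprintf("%s: %d%%", rownames(v), round(100 * curve@p)),
    col = seq_len(nrow(v)), pch = 19, bty = "n"
  )
  invisible(curve)
}

#' Round a fraction to a percentage, half away from zero
#'
#' @param x Fraction(s) in [0, 1].
#' @param nearest Round to the nearest this-many percentage points
#'   (default 1).
#' @return Percentage(s).
#' @export
percentRound <- function(x, nearest = 1) {
  pct <- 100 * x / nearest
  nearest * sign(pct) * floor(abs(pct) + 0.5)
}
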