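## consequence classes retained by the inclusion rule
.includedConsequences <- c(
  "missense", "nonsense", "frameshift_indel", "inframe_indel"
)
.allConsequences <- c(.includedConsequences, "synonymous", "other")

.variantCallColumns <- c(
  "patient_id", "region_id", "gene", "chrom", "pos", "ref", "alt",
  "depth", "alt_reads", "consequence", "in_dbsnp", "is_indel"
)

#' Validate a table of raw variant calls
#'
#' Checks that a data frame is a well-formed per-biopsy variant call table:
#' the required columns are present, coordinates are 1-based, alt read
#' support does not exceed depth, and consequence classes are from the
#' recognized set (\code{missense}, \code{nonsense}, \code{frameshift_indel},
#' \code{inframe_indel}, \code{synonymous}, \code{other}).
#'
#' @param calls Data frame of variant calls.
#' @return The calls, invisibly, with logical columns coerced.
#' @export
validateVariantCalls <- function(calls) {
  if (!is.data.frame(calls)) stop("calls must be a data.frame", call. = FALSE)
  missing <- setdiff(.variantCallColumns, names(calls))
  if (length(missing)) {
    stop("missing variant call column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls) == 0L) return(invisible(calls))
  calls$in_dbsnp <- as.logical(calls$in_dbsnp)
  calls$is_indel <- as.logical(calls$is_indel)
  if (any(calls$alt_reads > calls$depth)) {
    stop("malformed call: alt_reads exceeds depth", call. = FALSE)
  }
  if (any(calls$alt_reads < 0) || any(calls$depth < 0)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  if (any(calls$pos < 1)) stop("pos must be >= 1 (1-based)", call. = FALSE)
  bad <- setdiff(unique(calls$consequence), .allConsequences)
  if (length(bad)) {
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(calls)
}

#' Variant key (chrom:pos:ref:alt) for each call
#'
#' @param calls Data frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} columns.
#' @return Character vector of keys.
#' @export
variantKey <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Filter raw variant calls by consequence, depth, VAF and dbSNP membership
#'
#' Applies the study inclusion/exclusion rules to per-biopsy variant calls.
#' A call is retained when all of the following hold:
#' \itemize{
#'   \item its consequence is missense, nonsense, or an indel
#'     (frameshift/inframe); synonymous calls are excluded unless
#'     \code{excludeSynonymous = FALSE}, and \code{other} is always excluded;
#'   \item sequencing depth at the site is at least \code{minDepth}
#'     (default 10 reads);
#'   \item the variant allele fraction \code{alt_reads/depth} is at least
#'     \code{minVAF} (default 5\%, inclusive);
#'   \item it is not a single-base substitution present in dbSNP (the
#'     germline-SNP exclusion applies to SNVs only, never to indels).
#' }
#' Each excluded call is attributed to its first failing rule in the fixed
#' order consequence, depth, VAF, dbSNP (then the optional minimum
#' alt-read-count rule), so tallies are reproducible.
#'
#' @param calls Data frame of variant calls (see
#'   \code{\link{validateVariantCalls}}); extra columns are passed through.
#' @param minVAF Minimum variant allele fraction, inclusive. Default 0.05.
#' @param minDepth Minimum depth, inclusive. Default 10.
#' @param excludeDbsnp Drop dbSNP-flagged single-base substitutions.
#'   Default TRUE.
#' @param excludeSynonymous Drop synonymous calls. Default TRUE.
#' @param minAltReads Optional stricter QC on supporting reads (default 0 =
#'   off).
#'
#' @return A list with \code{retained} (data frame of surviving calls, input
#'   order preserved) and \code{tally} (named integer vector of exclusions
#'   per rule: \code{consequence}, \code{depth}, \code{vaf}, \code{dbsnp},
#'   \code{alt_reads}). \code{nrow(retained) + sum(tally)} always equals
#'   \code{nrow(calls)}.
#'
#' @examples
#' calls <- data.frame(
#'   patient_id = "T1", region_id = "R1", gene = "VHL", chrom = "3",
#'   pos = c(10183736, 10183737), ref = "C", alt = "T",
#'   depth = c(100, 20), alt_reads = c(4, 1),
#'   consequence = "missense", in_dbsnp = FALSE, is_indel = FALSE
#' )
#' filterVariants(calls)$tally  # first call fails the 5% VAF rule
#' @export
filterVariants <- function(calls, minVAF = 0.05, minDepth = 10,
                           excludeDbsnp = TRUE, excludeSynonymous = TRUE,
                           minAltReads = 0) {
  .checkProb(minVAF, "minVAF")
  if (minDepth < 0 || minAltReads < 0) {
    stop("minDepth and minAltReads must be nonnegative", call. = FALSE)
  }
  validateVariantCalls(calls)
  rules <- c("consequence", "depth", "vaf", "dbsnp", "alt_reads")
  tally <- setNames(integer(length(rules)), rules)
  if (nrow(calls) == 0L) {
    return(list(retained = calls, tally = tally))
  }

  keepCsq <- .includedConsequences
  if (!excludeSynonymous) keepCsq <- c(keepCsq, "synonymous")
  failCsq <- !(calls$consequence %in% keepCsq)
  failDepth <- calls$depth < minDepth
  failVaf <- calls$alt_reads / calls$depth < minVAF
  failDbsnp <- excludeDbsnp & as.logical(calls$in_dbsnp) &
    !as.logical(calls$is_indel)
  failAlt <- calls$alt_reads < minAltReads

  ## first failing rule attribution
  firstFail <- rep(NA_character_, nrow(calls))
  for (rule in rev(rules)) {
    fail <- switch(rule,
      consequence = failCsq, depth = failDepth, vaf = failVaf,
      dbsnp = failDbsnp, alt_reads = failAlt
    )
    firstFail[fail] <- rule
  }
  excluded <- !is.na(firstFail)
  counts <- table(factor(firstFail[excluded], levels = rules))
  tally[rules] <- as.integer(counts)

  list(retained = calls[!excluded, , drop = FALSE], tally = tally)
}
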