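#' Read and write variant call tables as TSV
#'
#' The TSV dialect is tab-separated with a header row and columns exactly
#' matching the variant call fields (\code{patient_id}, \code{region_id},
#' \code{gene}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{depth}, \code{alt_reads}, \code{consequence}, \code{in_dbsnp},
#' \code{is_indel}); extra columns are preserved.
#'
#' @param path File path.
#' @param calls Data frame of variant calls.
#' @return \code{readVariantTSV}: validated data frame of calls.
#' @export
readVariantTSV <- function(path) {
  if (!file.exists(path)) {
    stop("variant table not found: ", path, call. = FALSE)
  }
  calls <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  calls$in_dbsnp <- as.logical(calls$in_dbsnp)
  calls$is_indel <- as.logical(calls$is_indel)
  validateVariantCalls(calls)
  calls
}

#' @rdname readVariantTSV
#' @export
writeVariantTSV <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one biopsy's calls as a minimal VCF
#'
#' Emits VCF 4.2 with one sample column named \code{<patient>_<region>},
#' genotype fields \code{GT:AD:DP} (allelic depths ref,alt and total depth)
#' and INFO keys \code{GENE} and \code{CSQ}; dbSNP membership is flagged by
#' a non-missing ID column.
#'
#' @param calls Calls of a single patient/region.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeVariantVCF <- function(calls, path) {
  if (length(unique(paste(calls$patient_id, calls$region_id))) > 1L) {
    stop("writeVariantVCF expects calls from a single biopsy", call. = FALSE)
  }
  sample <- sprintf("%s_%s", calls$patient_id[1], calls$region_id[1])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=MultiRegionHet",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- if (nrow(calls)) {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, , drop = FALSE]
    paste(
      calls$chrom, calls$pos,
      ifelse(calls$in_dbsnp, sprintf("rs%d", calls$pos), "."),
      calls$ref, calls$alt, ".", "PASS",
      sprintf("GENE=%s;CSQ=%s", calls$gene, calls$consequence),
      "GT:AD:DP",
      sprintf("0/1:%d,%d:%d", calls$depth - calls$alt_reads,
              calls$alt_reads, calls$depth),
      sep = "\t"
    )
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-biopsy VCF into a variant call table
#'
#' Parses depth and alt support from the AD/DP genotype fields, gene and
#' consequence from the GENE/CSQ INFO keys, and dbSNP membership from a
#' non-missing ID. Requires the \pkg{vcfR} package.
#'
#' @param path VCF path.
#' @param patientId,regionId Identifiers for the biopsy; by default parsed
#'   from the sample name \code{<patient>_<region>}.
#' @return Data frame of variant calls.
#' @export
readVariantVCF <- function(path, patientId = NULL, regionId = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("readVariantVCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(.emptyCallTable()[, .variantCallColumns])
  sample <- colnames(v@gt)[2]
  if (is.null(patientId)) {
    patientId <- sub("_[^_]+$", "", sample)
    regionId <- sub("^.*_", "", sample)
  }
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  dp <- as.integer(vcfR::extract.gt(v, element = "DP")[, 1])
  altReads <- as.integer(vapply(
    strsplit(ad, ",", fixed = TRUE), `[`, character(1), 2L
  ))
  info <- vcfR::getINFO(v)
  getKey <- function(key) {
    m <- regmatches(info, regexpr(sprintf("%s=[^;]+", key), info))
    sub(sprintf("^%s=", key), "", m)
  }
  out <- data.frame(
    patient_id = patientId, region_id = regionId,
    gene = getKey("GENE"), chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, depth = dp, alt_reads = altReads,
    consequence = getKey("CSQ"),
    in_dbsnp = !is.na(fix$ID) & fix$ID != ".",
    is_indel = nchar(fix$REF) != nchar(fix$ALT)
  )
  validateVariantCalls(out)
  out
}

#' Read and write presence matrices as TSV
#'
#' Rows are mutations, columns regions, values 0/1; the first column is the
#' variant key and the second the gene symbol.
#'
#' @param profile A \linkS4class{TumorProfile}.
#' @param path File path.
#' @param patientId Patient id for the profile read back.
#' @return \code{readPresenceTSV}: a \linkS4class{TumorProfile}.
#' @export
writePresenceTSV <- function(profile, path) {
  p <- profile@presence
  df <- data.frame(
    variant_key = rownames(p) %||% character(),
    gene = if (nrow(p)) unname(profile@genes[rownames(p)]) else character(),
    p, check.names = FALSE
  )
  ## header keeps region columns even for an empty matrix
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePresenceTSV
#' @export
readPresenceTSV <- function(path, patientId) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  regs <- setdiff(names(df), c("variant_key", "gene"))
  if (nrow(df) == 0L) return(tumorProfile(patientId, regs))
  m <- as.matrix(df[, regs, drop = FALSE])
  rownames(m) <- df$variant_key
  tumorProfile(patientId, regs, m, setNames(df$gene, df$variant_key))
}

#' Write a SyntheticTruth as JSON
#'
#' @param truth A \code{SyntheticTruth}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTruthJSON <- function(truth, path) {
  payload <- list(
    genePanel = truth$genePanel,
    seed = truth$seed,
    patients = lapply(truth$patients, function(p) {
      list(
        patientId = p$patientId,
        regions = p$regions,
        mutations = p$mutations
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
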