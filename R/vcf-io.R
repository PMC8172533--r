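#' Write variant calls as a minimal VCF v4.2 file
#'
#' One bi-allelic record per call, with INFO fields `GENE` and `CAT`
#' (functional category) and per-sample FORMAT fields `AD` (ref,alt read
#' counts) and `DP` (depth). Positions are 1-based; indels use the anchored
#' VCF representation.
#'
#' @param calls tibble with `chrom`, `pos`, `ref`, `alt`, `alt_reads`,
#'   `depth`, `gene`, `category`, `sample`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  sample_id <- if (nrow(calls) > 0) calls$sample[1] else "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Functional category\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  records <- if (nrow(calls) > 0) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          paste0("GENE=", calls$gene, ";CAT=", calls$category),
          "AD:DP",
          paste0(calls$depth - calls$alt_reads, ",", calls$alt_reads, ":",
                 calls$depth),
          sep = "\t")
  } else character(0)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a VCF variant table into a call tibble
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}), splits multi-allelic records,
#' computes per-call VAF from the AD/DP genotype fields, and flags calls in
#' cancer-related genes. Records without usable AD and DP evidence are
#' rejected with a warning naming their location.
#'
#' @param path VCF file path.
#' @param sample_label `"FF"` or `"FFPE"`, attached to every call.
#' @param gene_list character vector of cancer-related gene symbols.
#' @return tibble of calls: `chrom`, `pos`, `ref`, `alt`, `alt_reads`,
#'   `depth`, `vaf` (percent), `gene`, `category`, `sample`,
#'   `cancer_related`.
#' @export
read_variant_table <- function(path, sample_label = c("FF", "FFPE"),
                               gene_list = character()) {
  sample_label <- match.arg(sample_label)
  if (!file.exists(path)) {
    stop("cannot read variant table: no such file `", path, "`",
         call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), alt_reads = integer(), depth = integer(),
    vaf = double(), gene = character(), category = character(),
    sample = character(), cancer_related = logical()
  )
  if (nrow(vcf@fix) == 0) return(empty)

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gene <- vcfR::extract.info(vcf, element = "GENE")
  category <- vcfR::extract.info(vcf, element = "CAT")
  category[is.na(category)] <- "other"

  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[, 1]

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_i <- suppressWarnings(
      as.integer(strsplit(ad[i] %||% NA_character_, ",", fixed = TRUE)[[1]])
    )
    if (is.na(dp[i]) || length(ad_i) < 1 + length(alts) ||
        anyNA(ad_i)) {
      warning("record rejected (missing AD/DP evidence) at ",
              fix$CHROM[i], ":", fix$POS[i], call. = FALSE)
      next
    }
    rows[[i]] <- tibble::tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      alt_reads = ad_i[1 + seq_along(alts)], depth = as.integer(dp[i]),
      gene = gene[i], category = category[i]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out$vaf <- compute_wes_vaf(out$alt_reads, out$depth)
  out$sample <- sample_label
  out <- flag_cancer_related(out, gene_list)
  out[, c("chrom", "pos", "ref", "alt", "alt_reads", "depth", "vaf",
          "gene", "category", "sample", "cancer_related")]
}

#' Read a cancer-related gene list
#'
#' Plain text, one symbol per line; blank lines and surrounding whitespace
#' are dropped. Matching downstream is case-insensitive exact.
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read gene list: no such file `", path, "`", call. = FALSE)
  }
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write a tibble as a tab-separated table
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#'
#' @param path file path.
#' @return tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
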