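#' Round half away from zero
#'
#' Commercial rounding (0.5 rounds up) used for all displayed percentages,
#' as opposed to [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(48.67, 81.5, 3.45), 0)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Variant identity key
#'
#' Builds the (chrom, pos, ref, alt) identity string used to match variants
#' across samples, assays and measurement tables. Inputs are assumed
#' pre-normalized (left-aligned, anchored indels).
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# valid allele string: non-empty, A/C/G/T only
is_valid_allele <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

# order chromosomes naturally: chr1..chr22, chrX, chrY, then others
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  ord <- suppressWarnings(as.numeric(core))
  ord[core %in% c("X", "x")] <- 23
  ord[core %in% c("Y", "y")] <- 24
  ord[core %in% c("M", "MT", "m", "mt")] <- 25
  ord[is.na(ord)] <- 26
  ord
}

`%||%` <- function(a, b) if (is.null(a)) b else a
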