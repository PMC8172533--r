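#' WES variant allele frequency in percent
#'
#' @param alt_reads variant-supporting read count.
#' @param depth total read depth, > 0.
#' @return `100 * alt_reads / depth` (raw; display rounds to one decimal).
#' @export
#' @examples
#' compute_wes_vaf(15, 382)  # 3.93..., displays as 3.9%
compute_wes_vaf <- function(alt_reads, depth) {
  if (any(depth == 0)) {
    stop("VAF is undefined at depth 0", call. = FALSE)
  }
  if (any(alt_reads < 0) || any(depth < 0) || any(alt_reads > depth)) {
    stop("need 0 <= alt_reads <= depth", call. = FALSE)
  }
  100 * alt_reads / depth
}

# pyrimidine-first collapse of the 12 substitutions into 6 classes
SBS_CLASSES <- c(
  "C>T" = "C>T/G>A", "G>A" = "C>T/G>A",
  "C>A" = "C>A/G>T", "G>T" = "C>A/G>T",
  "C>G" = "C>G/G>C", "G>C" = "C>G/G>C",
  "A>G" = "A>G/T>C", "T>C" = "A>G/T>C",
  "A>C" = "A>C/T>G", "T>G" = "A>C/T>G",
  "A>T" = "A>T/T>A", "T>A" = "A>T/T>A"
)

#' Collapse a ref/alt pair into its strand-complement alteration class
#'
#' Single-base substitutions map to one of the six classes
#' C>T/G>A, C>A/G>T, C>G/G>C, A>G/T>C, A>C/T>G, A>T/T>A (a substitution and
#' its reverse complement are the same biological event); length-changing
#' alleles map to `"indel"`; equal-length multi-base substitutions to
#' `"other"`.
#'
#' @param ref,alt allele strings over A/C/G/T (anchored VCF style for
#'   indels); vectorized.
#' @return character vector of class labels.
#' @export
#' @examples
#' classify_alteration("G", "A")      # deamination class C>T/G>A
#' classify_alteration("ACA", "A")    # 2-bp deletion -> "indel"
classify_alteration <- function(ref, alt) {
  if (any(!is_valid_allele(ref)) || any(!is_valid_allele(alt))) {
    stop("alleles must be non-empty strings over A/C/G/T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  out <- character(length(ref))
  snv <- nchar(ref) == 1 & nchar(alt) == 1
  out[snv] <- SBS_CLASSES[paste0(ref[snv], ">", alt[snv])]
  out[!snv & nchar(ref) != nchar(alt)] <- "indel"
  out[!snv & nchar(ref) == nchar(alt)] <- "other"
  out
}

#' Select candidates for confirmatory BDA qPCR/Sanger testing
#'
#' Every call below the VAF cutoff in a cancer-related gene is selected
#' unconditionally; `n_random` further low-VAF calls outside the
#' cancer-related list are added by uniform sampling without replacement.
#' Ordering is stable by (chrom, pos).
#'
#' @param calls tibble of variant calls (needs `chrom`, `pos`, `ref`,
#'   `alt`, `vaf` in percent, `gene`).
#' @param gene_list character vector of cancer-related gene symbols
#'   (matching is case-insensitive exact).
#' @param vaf_cutoff percent, strict upper bound; default 5.
#' @param n_random number of non-cancer-related calls to add.
#' @param seed integer seed for the random draw.
#' @return a `candidate_set` list: `candidates` tibble (with
#'   `cancer_related` flag), `selection_seed`, `n_cancer_related`,
#'   `n_random`.
#' @export
select_candidates <- function(calls, gene_list, vaf_cutoff = 5,
                              n_random = 0, seed = 1L) {
  if (vaf_cutoff <= 0) stop("`vaf_cutoff` must be > 0", call. = FALSE)
  calls <- flag_cancer_related(calls, gene_list)
  low <- dplyr::filter(calls, .data$vaf < vaf_cutoff)
  cancer <- dplyr::filter(low, .data$cancer_related)
  pool <- dplyr::filter(low, !.data$cancer_related)
  if (n_random > nrow(pool)) {
    stop("`n_random` (", n_random, ") exceeds the available pool of ",
         nrow(pool), " non-cancer-related low-VAF calls", call. = FALSE)
  }
  random <- withr::with_seed(seed, dplyr::slice_sample(pool, n = n_random))
  candidates <- dplyr::bind_rows(cancer, random)
  candidates <- dplyr::arrange(candidates, chrom_rank(.data$chrom),
                               .data$pos, .data$ref, .data$alt)
  structure(
    list(candidates = candidates, selection_seed = as.integer(seed),
         n_cancer_related = nrow(cancer), n_random = n_random),
    class = "candidate_set"
  )
}

#' Flag calls in cancer-related genes
#'
#' @param calls tibble with a `gene` column.
#' @param gene_list character vector of symbols; case-insensitive match.
#' @return `calls` with a logical `cancer_related` column.
#' @export
flag_cancer_related <- function(calls, gene_list) {
  dplyr::mutate(calls,
                cancer_related = toupper(.data$gene) %in%
                  toupper(gene_list))
}

#' Cross-sample call concordance split at a VAF threshold
#'
#' Partitions `calls_a` into VAF above vs at-or-below the threshold and
#' reports, for each partition, how many calls are also present in
#' `calls_b` under exact (chrom, pos, ref, alt) identity. Inputs are
#' assumed pre-normalized (left-aligned indels).
#'
#' @param calls_a,calls_b variant-call tibbles.
#' @param vaf_threshold percent; default 20.
#' @return tibble with rows `above` / `at_or_below`: `n`, `n_concordant`,
#'   `fraction`, `percent` (rounded half-up to integer).
#' @export
concordance <- function(calls_a, calls_b, vaf_threshold = 20) {
  key_a <- variant_key(calls_a$chrom, calls_a$pos, calls_a$ref, calls_a$alt)
  key_b <- variant_key(calls_b$chrom, calls_b$pos, calls_b$ref, calls_b$alt)
  part <- ifelse(calls_a$vaf > vaf_threshold, "above", "at_or_below")
  hit <- key_a %in% key_b
  out <- tibble::tibble(partition = c("above", "at_or_below"))
  out$n <- vapply(out$partition, function(p) sum(part == p), integer(1),
                  USE.NAMES = FALSE)
  out$n_concordant <- vapply(out$partition,
                             function(p) sum(hit[part == p]), integer(1),
                             USE.NAMES = FALSE)
  out$fraction <- ifelse(out$n > 0, out$n_concordant / out$n, 0)
  out$percent <- round_half_up(100 * out$fraction)
  out
}
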