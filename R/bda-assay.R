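#' Define a blocker displacement amplification (BDA) assay
#'
#' A BDA assay targets one locus: a blocker oligo overlapping the forward
#' primer suppresses amplification of the wildtype allele, so templates
#' carrying a variant amplify with a higher per-cycle yield. The assay is
#' modelled abstractly by its per-cycle yields (not blocker thermodynamics,
#' which belong to the oligo-design software upstream) and by the
#' blocker-overhead cycles of its 100% VAF gBlock positive control.
#'
#' @param chrom,pos,ref,expected_alt target locus and the allele the assay
#'   was designed to interrogate.
#' @param mutant_efficiency per-cycle yield of variant template with
#'   blocker, in (1, 2]; 2 means perfect doubling. Default 2.
#' @param wildtype_efficiency per-cycle yield of wildtype template with
#'   blocker, in \[1, mutant_efficiency). Default 1.5.
#' @param selective_cycles number of cycles over which the yield difference
#'   compounds. Default 30 (with the default yields this exceeds the
#'   1000-fold enrichment expected of a working assay).
#' @param blocker_overhead_cycles delta-Cq of the pure-variant positive
#'   control (extra cycles the blocker costs even a 100% VAF template);
#'   >= 0. Default 3.
#' @param validated has the assay passed control validation (see
#'   [validate_assay()]).
#' @return a `bda_assay` list.
#' @export
#' @examples
#' a <- bda_assay("chr7", 2944337, "G", "A")
#' enrichment_fold(a$mutant_efficiency, a$wildtype_efficiency,
#'                 a$selective_cycles)
bda_assay <- function(chrom, pos, ref, expected_alt,
                      mutant_efficiency = 2,
                      wildtype_efficiency = 1.5,
                      selective_cycles = 30,
                      blocker_overhead_cycles = 3,
                      validated = TRUE) {
  if (mutant_efficiency <= 1 || mutant_efficiency > 2) {
    stop("`mutant_efficiency` must be in (1, 2]", call. = FALSE)
  }
  if (wildtype_efficiency < 1 || wildtype_efficiency >= mutant_efficiency) {
    stop("`wildtype_efficiency` must be in [1, mutant_efficiency)",
         call. = FALSE)
  }
  if (blocker_overhead_cycles < 0) {
    stop("`blocker_overhead_cycles` must be >= 0", call. = FALSE)
  }
  structure(
    list(chrom = chrom, pos = pos, ref = ref, expected_alt = expected_alt,
         mutant_efficiency = mutant_efficiency,
         wildtype_efficiency = wildtype_efficiency,
         selective_cycles = selective_cycles,
         blocker_overhead_cycles = blocker_overhead_cycles,
         validated = isTRUE(validated)),
    class = "bda_assay"
  )
}

#' Mutant-over-wildtype enrichment fold of a BDA reaction
#'
#' With per-cycle yields `m` for mutant and `w` for wildtype template, each
#' cycle multiplies the mutant:wildtype abundance ratio by `m/w`; over `n`
#' cycles the ratio gains `(m/w)^n` relative to cycle 0.
#'
#' @param mutant_efficiency,wildtype_efficiency per-cycle yields in (0, 2].
#' @param cycles non-negative cycle count.
#' @return enrichment fold (>= 1 when the mutant amplifies faster).
#' @export
#' @examples
#' enrichment_fold(2, 1.5, 30)  # ~5600-fold
enrichment_fold <- function(mutant_efficiency, wildtype_efficiency, cycles) {
  if (any(wildtype_efficiency <= 0)) {
    stop("`wildtype_efficiency` must be positive", call. = FALSE)
  }
  if (any(mutant_efficiency <= 0) || any(mutant_efficiency > 2) ||
      any(wildtype_efficiency > 2)) {
    stop("per-cycle yields must lie in (0, 2]", call. = FALSE)
  }
  if (any(cycles < 0)) stop("`cycles` must be >= 0", call. = FALSE)
  (mutant_efficiency / wildtype_efficiency)^cycles
}

#' Allele fraction after selective enrichment
#'
#' If a fraction `vaf` of templates is variant and enrichment multiplies
#' variant abundance `fold` times relative to wildtype, the post-enrichment
#' variant fraction is `vaf*fold / (vaf*fold + 1 - vaf)`. This is what a
#' Sanger trace of the enriched amplicon sees: a 1% variant enriched
#' 1000-fold reads as ~91% of the trace.
#'
#' @param vaf variant allele fraction in \[0, 1\].
#' @param fold enrichment fold, >= 1.
#' @return post-enrichment fraction in \[0, 1\].
#' @export
#' @examples
#' post_enrichment_fraction(0.01, 1000)
post_enrichment_fraction <- function(vaf, fold) {
  if (any(vaf < 0) || any(vaf > 1)) {
    stop("`vaf` must lie in [0, 1]", call. = FALSE)
  }
  if (any(fold < 1)) stop("`fold` must be >= 1", call. = FALSE)
  vaf * fold / (vaf * fold + 1 - vaf)
}

#' Validate a BDA assay against its matched controls
#'
#' An assay goes to sample testing only if, with blocker, the wildtype
#' genomic-DNA negative control amplifies strictly more than `min_delta`
#' cycles later than the copy-matched pure-variant gBlock positive control.
#' The comparison is meaningful only when the two controls were adjusted to
#' the same amplifiable copy number.
#'
#' @param negative_cq with-blocker Cq of the 0% VAF gDNA control; a
#'   no-amplification sentinel (e.g. 45) is allowed and maximal.
#' @param positive_cq with-blocker Cq of the 100% VAF gBlock control.
#' @param copies_matched were the control template concentrations equalized
#'   (see [normalize_gblock()]).
#' @param min_delta required Cq separation, strict. Default 10 cycles.
#' @return list with `pass` (logical) and `margin` (negative minus positive
#'   Cq, cycles).
#' @export
#' @examples
#' validate_assay(40, 25)          # pass, margin 15
#' validate_assay(35, 25)$pass     # FALSE: margin exactly 10, gate is strict
validate_assay <- function(negative_cq, positive_cq, copies_matched = TRUE,
                           min_delta = 10) {
  if (missing(positive_cq) || is.null(positive_cq) || is.na(positive_cq)) {
    stop("positive-control Cq is missing: assay cannot be validated",
         call. = FALSE)
  }
  if (is.null(negative_cq) || is.na(negative_cq)) {
    stop("negative-control Cq is missing: assay cannot be validated",
         call. = FALSE)
  }
  margin <- negative_cq - positive_cq
  list(pass = isTRUE(copies_matched) && margin > min_delta, margin = margin)
}

#' Copy-match a gBlock positive control to the gDNA negative control
#'
#' Both controls are quantified with the same blocker-free primers; assuming
#' doubling per cycle, a gBlock Cq that is `d` cycles later than the gDNA Cq
#' means the stock holds `2^-d` times the amplifiable copies of the gDNA
#' input, so the concentration is scaled by `2^d` to equalize amplifiable
#' copy number between the two controls (an earlier gBlock Cq scales it
#' down).
#'
#' @param gblock_cq,gdna_cq no-blocker Cq of the gBlock dilution and of the
#'   genomic DNA input.
#' @param gblock_conc current gBlock concentration (copies/uL), positive.
#' @return adjusted concentration, `gblock_conc * 2^(gblock_cq - gdna_cq)`.
#' @export
#' @examples
#' normalize_gblock(28.32, 25, 3000)  # ~10x more concentrated
normalize_gblock <- function(gblock_cq, gdna_cq, gblock_conc) {
  if (any(gblock_conc <= 0)) {
    stop("`gblock_conc` must be positive", call. = FALSE)
  }
  gblock_conc * 2^(gblock_cq - gdna_cq)
}
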