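#' Construct a Sanger call on an enriched amplicon
#'
#' The dominant base (or inserted base) read off a Sanger trace of the
#' BDA-enriched amplicon, together with how many independent replicate
#' reactions produced the same call. Calls matching neither the reference
#' nor the expected variant require at least three concordant replicates
#' before they can support a "misidentified" verdict.
#'
#' @param called_allele allele string read from the trace.
#' @param reference reference allele at the locus.
#' @param n_replicate_reads number of concordant replicate traces, >= 1.
#' @return a `sanger_call` list with `called_allele`, `matches_reference`,
#'   `n_replicate_reads`.
#' @export
sanger_call <- function(called_allele, reference, n_replicate_reads = 1) {
  if (n_replicate_reads < 1) {
    stop("`n_replicate_reads` must be >= 1", call. = FALSE)
  }
  structure(
    list(called_allele = called_allele,
         matches_reference = identical(called_allele, reference),
         n_replicate_reads = as.integer(n_replicate_reads)),
    class = "sanger_call"
  )
}

#' Simulate the Sanger readout of a BDA-enriched amplicon
#'
#' Computes the post-enrichment allele fraction
#' `f' = f*E / (f*E + 1 - f)` with `f` the variant's true VAF in the tested
#' sample and `E` the assay's enrichment fold; the trace calls the true
#' variant allele when `f'` reaches `dominant_threshold` (raw Sanger needs
#' roughly 20% allele fraction to show a dominant secondary peak), else the
#' reference. Note the *true* allele is what amplifies and gets read — a
#' misidentified WES call therefore shows an allele matching neither the
#' reference nor the reported variant.
#'
#' @param variant one row of a [simulate_truth_set()] table.
#' @param assay a [bda_assay()].
#' @param dominant_threshold fraction in (0, 0.5].
#' @param sample which sample's template was enriched, `"FF"` or `"FFPE"`.
#' @param n_replicate_reads concordant replicate traces to record.
#' @return a [sanger_call()].
#' @export
#' @examples
#' v <- list(ref = "G", true_alt = "A", true_vaf_ff = 0.01,
#'           true_vaf_ffpe = 0.01)
#' simulate_sanger(v, bda_assay("chr1", 1, "G", "A"), 0.2, "FF")
simulate_sanger <- function(variant, assay, dominant_threshold = 0.2,
                            sample = c("FF", "FFPE"),
                            n_replicate_reads = 1) {
  if (dominant_threshold <= 0 || dominant_threshold > 0.5) {
    stop("`dominant_threshold` must be in (0, 0.5]", call. = FALSE)
  }
  sample <- match.arg(sample)
  f <- if (sample == "FF") variant$true_vaf_ff else variant$true_vaf_ffpe
  fold <- enrichment_fold(assay$mutant_efficiency,
                          assay$wildtype_efficiency,
                          assay$selective_cycles)
  f_prime <- post_enrichment_fraction(f, fold)
  called <- if (f_prime >= dominant_threshold) variant$true_alt else
    variant$ref
  sanger_call(called, variant$ref, n_replicate_reads)
}
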