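#' Aggregate replicate Cq values
#'
#' Arithmetic mean of the non-sentinel replicates; the number of dropped
#' (no-amplification) replicates is attached as attribute `n_dropped`.
#' Replicates are averaged on the Cq scale *before* any delta-Cq is formed,
#' the usual qPCR practice.
#'
#' @param measurement a [cq_measurement()].
#' @return mean Cq (cycles) with attribute `n_dropped`.
#' @export
#' @examples
#' m <- cq_measurement("gBlock", "with_blocker", c(30.0, 30.4, 30.2))
#' aggregate_replicates(m)
aggregate_replicates <- function(measurement) {
  stopifnot(inherits(measurement, "cq_measurement"))
  keep <- !measurement$sentinel_flags
  if (!any(keep)) {
    stop("no amplification: all ", length(keep), " replicates of ",
         measurement$template, "/", measurement$condition,
         " are at the sentinel Cq", call. = FALSE)
  }
  structure(mean(measurement$replicate_cqs[keep]),
            n_dropped = sum(!keep))
}

#' Delta-Cq of a blocker/no-blocker reaction pair
#'
#' `dCq = with_blocker Cq - no_blocker Cq` for the same template. The fewer
#' variant templates present, the later the with-blocker reaction crosses
#' threshold, so a smaller dCq indicates a higher probability that the
#' sample contains the variant.
#'
#' @param with_blocker,no_blocker aggregated Cq values (cycles); must be
#'   finite and not at the no-amplification sentinel.
#' @param max_cycles sentinel Cq; default 45.
#' @return dCq in cycles (negative values are allowed but unusual).
#' @export
#' @examples
#' delta_cq(30, 25)
delta_cq <- function(with_blocker, no_blocker, max_cycles = 45) {
  for (nm in c("with_blocker", "no_blocker")) {
    v <- get(nm)
    if (!is.finite(v)) {
      stop("`", nm, "` Cq is not finite", call. = FALSE)
    }
    if (v >= max_cycles) {
      stop("`", nm, "` Cq is at the no-amplification sentinel (",
           max_cycles, "): delta-Cq undefined", call. = FALSE)
    }
  }
  as.numeric(with_blocker) - as.numeric(no_blocker)
}

#' Estimate VAF from sample and gBlock delta-Cq values
#'
#' Assuming the variant allele doubles each cycle in the with-blocker
#' reaction and the no-blocker reaction measures total input, every cycle
#' by which the sample's dCq exceeds the 100% VAF gBlock calibrator's dCq
#' corresponds to one halving of the variant fraction:
#' `VAF = 100% * 2^(dCq_gBlock - dCq_sample)`.
#'
#' The published closed form with the subtraction taken *outside* the
#' exponent, `100% / (2^dCq_sample - 2^dCq_gBlock)`, diverges when the two
#' dCq values coincide (a pure-variant sample) and is negative when the
#' sample amplifies earlier than the calibrator; it is retained behind
#' `literal = TRUE` for comparison only.
#'
#' @param dcq_sample,dcq_gblock aggregated delta-Cq of the sample and of
#'   the matched gBlock positive control (cycles).
#' @param tolerance how far `dcq_sample` may fall below `dcq_gblock`
#'   (replicate noise) before the input is rejected; default 0.45 cycles
#'   (three times the default per-replicate noise sd).
#' @param literal use the as-typeset closed form (see above).
#' @return VAF in percent; estimates above 100% are clamped to 100 with a
#'   warning (noise can push a near-pure sample past the boundary).
#' @export
#' @examples
#' estimate_vaf(9.64, 3.0)   # ~1%
#' estimate_vaf(4.0, 3.0)    # one doubling below pure: 50%
estimate_vaf <- function(dcq_sample, dcq_gblock, tolerance = 0.45,
                         literal = FALSE) {
  if (any(!is.finite(dcq_sample)) || any(!is.finite(dcq_gblock))) {
    stop("delta-Cq inputs must be finite", call. = FALSE)
  }
  if (any(dcq_sample < dcq_gblock - tolerance)) {
    stop("dcq_sample is more than `tolerance` below dcq_gblock: the ",
         "sample cannot contain more variant than the pure positive ",
         "control", call. = FALSE)
  }
  vaf <- if (literal) {
    100 / (2^dcq_sample - 2^dcq_gblock)
  } else {
    100 * 2^(dcq_gblock - dcq_sample)
  }
  if (!literal && any(vaf > 100)) {
    warning("VAF estimate above 100% clamped to 100%", call. = FALSE)
    vaf <- pmin(vaf, 100)
  }
  vaf
}

#' Classify one candidate from its enriched Sanger call
#'
#' Three-outcome rule: the call is *confirmed* when the enriched allele
#' equals the WES-reported alt; *absent* when it equals the reference
#' (the putative variant is not in the sample); *misidentified* when it
#' matches neither, provided at least three concordant replicate reactions
#' agree (repeats rule out random artifacts). A neither-matching call with
#' fewer replicates is held as `failed_qc` with reason
#' `"pending_replicates"`; an unvalidated assay always yields `failed_qc`.
#'
#' @param candidate list or one-row tibble with `ref` and `alt` (the
#'   WES-reported allele).
#' @param sanger a [sanger_call()].
#' @param assay a [bda_assay()] (only its `validated` flag is consulted).
#' @return list with `status` in confirmed/absent/misidentified/failed_qc
#'   and `reason`.
#' @export
classify_confirmation <- function(candidate, sanger, assay) {
  if (!isTRUE(assay$validated)) {
    return(list(status = "failed_qc", reason = "unvalidated_assay"))
  }
  called <- sanger$called_allele
  if (identical(called, candidate$alt)) {
    list(status = "confirmed", reason = "allele_matches_wes_call")
  } else if (identical(called, candidate$ref)) {
    list(status = "absent", reason = "allele_matches_reference")
  } else if (sanger$n_replicate_reads >= 3) {
    list(status = "misidentified", reason = "concordant_novel_allele")
  } else {
    list(status = "failed_qc", reason = "pending_replicates")
  }
}

#' Confirm a candidate set against qPCR measurements and Sanger calls
#'
#' Orchestrates the per-candidate confirmation: looks up the candidate's
#' assay, aggregates replicate Cq values for the four reactions (sample and
#' gBlock, each with and without blocker), forms both delta-Cq values,
#' classifies the Sanger call, and estimates VAF for confirmed variants
#' only. Candidates with missing inputs, an unvalidated assay, or
#' unresolvable sentinel Cq values are reported as `failed_qc` with a
#' reason — never silently dropped. All-sentinel with-blocker amplification
#' together with a reference-matching Sanger call is classified `absent`
#' (complete suppression is what a variant-free template looks like).
#'
#' @param candidates a `candidate_set` from [select_candidates()] or a
#'   plain tibble of calls.
#' @param measurements long tibble of replicate Cq values with columns
#'   `key` (variant identity, see [variant_key()]), `template`,
#'   `condition`, `cq`, `is_sentinel`.
#' @param sanger_calls tibble with columns `key`, `called_allele`,
#'   `n_replicate_reads`.
#' @param assays tibble with columns `key`, `validated`.
#' @param tolerance passed to [estimate_vaf()].
#' @param max_cycles sentinel Cq; default 45.
#' @return tibble with one row per candidate: the candidate columns plus
#'   `alteration`, `dcq_sample`, `dcq_gblock`, `estimated_vaf` (percent, NA
#'   unless confirmed), `status`, `reason`.
#' @export
confirm_candidates <- function(candidates, measurements, sanger_calls,
                               assays, tolerance = 0.45, max_cycles = 45) {
  cand <- if (inherits(candidates, "candidate_set")) {
    candidates$candidates
  } else {
    candidates
  }
  n <- nrow(cand)
  out <- dplyr::mutate(
    cand,
    alteration = if (n > 0) classify_alteration(.data$ref, .data$alt)
    else character(0),
    dcq_sample = NA_real_, dcq_gblock = NA_real_,
    estimated_vaf = NA_real_,
    status = character(n), reason = character(n)
  )
  if (n == 0) return(out)

  keys <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt)
  sample_template <- paste0("sample_", cand$sample)

  agg <- function(key, template, condition) {
    m <- measurements[measurements$key == key &
                        measurements$template == template &
                        measurements$condition == condition, ]
    if (nrow(m) == 0) return(NULL)
    keep <- !m$is_sentinel
    if (!any(keep)) return(NA_real_)   # amplification failed everywhere
    mean(m$cq[keep])
  }

  for (i in seq_len(n)) {
    key <- keys[i]
    arow <- assays[assays$key == key, ]
    if (nrow(arow) == 0) {
      out$status[i] <- "failed_qc"; out$reason[i] <- "missing_assay"
      next
    }
    if (!isTRUE(arow$validated[1])) {
      out$status[i] <- "failed_qc"; out$reason[i] <- "unvalidated_assay"
      next
    }
    srow <- sanger_calls[sanger_calls$key == key, ]
    if (nrow(srow) == 0) {
      out$status[i] <- "failed_qc"; out$reason[i] <- "missing_sanger_call"
      next
    }
    sanger <- sanger_call(srow$called_allele[1], cand$ref[i],
                          srow$n_replicate_reads[1])

    s_wb <- agg(key, sample_template[i], "with_blocker")
    s_nb <- agg(key, sample_template[i], "no_blocker")
    g_wb <- agg(key, "gBlock", "with_blocker")
    g_nb <- agg(key, "gBlock", "no_blocker")
    if (is.null(s_wb) || is.null(s_nb) || is.null(g_wb) || is.null(g_nb)) {
      out$status[i] <- "failed_qc"; out$reason[i] <- "missing_measurements"
      next
    }
    if (is.na(s_wb)) {
      # with-blocker never amplified in the sample
      if (sanger$matches_reference) {
        out$status[i] <- "absent"
        out$reason[i] <- "no_amplification_reference_trace"
      } else {
        out$status[i] <- "failed_qc"
        out$reason[i] <- "sentinel_cq_discordant_trace"
      }
      next
    }
    if (anyNA(c(s_nb, g_wb, g_nb))) {
      out$status[i] <- "failed_qc"; out$reason[i] <- "control_amplification_failure"
      next
    }

    out$dcq_sample[i] <- delta_cq(s_wb, s_nb, max_cycles)
    out$dcq_gblock[i] <- delta_cq(g_wb, g_nb, max_cycles)

    cls <- classify_confirmation(cand[i, ], sanger, list(validated = TRUE))
    out$status[i] <- cls$status
    out$reason[i] <- cls$reason
    if (cls$status == "confirmed") {
      out$estimated_vaf[i] <- estimate_vaf(out$dcq_sample[i],
                                           out$dcq_gblock[i],
                                           tolerance = tolerance)
    }
  }
  out
}

#' Simulate the full confirmation input bundle for a candidate set
#'
#' For every candidate, builds a validated default assay, simulates the
#' four qPCR reactions (tested sample and gBlock, with and without
#' blocker) and the enriched Sanger trace, and returns the three tables
#' [confirm_candidates()] consumes. Sanger reactions whose call matches
#' neither reference nor reported allele are automatically repeated to
#' `config$replicates` concordant reads, mirroring bench practice.
#'
#' @param truth tibble from [simulate_truth_set()].
#' @param candidates `candidate_set` or tibble of candidate calls.
#' @param config a [sim_config()].
#' @return list of tibbles: `measurements`, `sanger_calls`, `assays`.
#' @export
simulate_confirmation_inputs <- function(truth, candidates, config) {
  cand <- if (inherits(candidates, "candidate_set")) {
    candidates$candidates
  } else {
    candidates
  }
  truth_key <- variant_key(truth$chrom, truth$pos, truth$ref,
                           truth$reported_alt)
  keys <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt)

  meas <- vector("list", nrow(cand))
  sang <- vector("list", nrow(cand))
  withr::with_seed(config$seed + 1000L, {
    for (i in seq_len(nrow(cand))) {
      ti <- match(keys[i], truth_key)
      variant <- if (is.na(ti)) {
        # a call with no truth entry behaves as a pure-wildtype locus
        list(chrom = cand$chrom[i], pos = cand$pos[i], ref = cand$ref[i],
             true_alt = cand$alt[i], true_vaf_ff = 0, true_vaf_ffpe = 0)
      } else {
        as.list(truth[ti, ])
      }
      assay <- bda_assay(cand$chrom[i], cand$pos[i], cand$ref[i],
                         cand$alt[i])
      tmpl <- paste0("sample_", cand$sample[i])
      mm <- list(simulate_qpcr(variant, assay, tmpl, config),
                 simulate_qpcr(variant, assay, "gBlock", config))
      meas[[i]] <- dplyr::bind_rows(lapply(unlist(mm, recursive = FALSE),
        function(m) tibble::tibble(
          key = keys[i], template = m$template, condition = m$condition,
          cq = m$replicate_cqs, is_sentinel = m$sentinel_flags
        )))
      sc <- simulate_sanger(variant, assay, config$dominant_threshold,
                            cand$sample[i])
      if (!sc$matches_reference &&
          !identical(sc$called_allele, cand$alt[i])) {
        sc <- simulate_sanger(variant, assay, config$dominant_threshold,
                              cand$sample[i],
                              n_replicate_reads = max(3, config$replicates))
      }
      sang[[i]] <- tibble::tibble(
        key = keys[i], called_allele = sc$called_allele,
        n_replicate_reads = sc$n_replicate_reads
      )
    }
  })
  list(
    measurements = dplyr::bind_rows(meas),
    sanger_calls = dplyr::bind_rows(sang),
    assays = tibble::tibble(key = keys, validated = TRUE)
  )
}
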