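count_stratum <- function(results, label) {
  n_conf <- sum(results$status == "confirmed")
  n_abs <- sum(results$status == "absent")
  n_mis <- sum(results$status == "misidentified")
  n <- n_conf + n_abs + n_mis
  tibble::tibble(
    stratum = as.character(label), n_tested = n,
    n_confirmed = n_conf, n_absent = n_abs, n_misidentified = n_mis,
    disconfirmed_fraction = if (n > 0) (n_abs + n_mis) / n else NA_real_,
    disconfirmed_rate = if (n > 0) round_half_up(100 * (n_abs + n_mis) / n)
    else NA_real_
  )
}

#' Tabulate confirmation outcomes by stratum
#'
#' Counts confirmed / absent / misidentified candidates and the
#' disconfirmed rate (absent + misidentified over tested, rounded half-up
#' to integer percent) per stratum of the chosen grouping. `failed_qc`
#' rows are excluded from all denominators and reported in the
#' `n_failed_qc` attribute.
#'
#' @param results tibble of confirmation results (needs `status` and the
#'   grouping column).
#' @param grouping one of `"overall"`, `"sample"`, `"cancer_related"`,
#'   `"category"`, `"alteration"`, or the name of any column in `results`.
#' @return tibble with one row per stratum: `stratum`, `n_tested`,
#'   `n_confirmed`, `n_absent`, `n_misidentified`,
#'   `disconfirmed_fraction`, `disconfirmed_rate`; attribute `n_failed_qc`.
#' @export
#' @examples
#' res <- tibble::tibble(status = rep(c("confirmed", "absent"), c(61, 33)))
#' summarize_confirmations(res)  # disconfirmed rate 35%
summarize_confirmations <- function(results, grouping = "overall") {
  if (nrow(results) == 0) {
    stop("no confirmation results to summarize", call. = FALSE)
  }
  n_failed <- sum(results$status == "failed_qc")
  kept <- results[results$status != "failed_qc", ]
  if (nrow(kept) == 0) {
    stop("no results left after excluding failed_qc rows", call. = FALSE)
  }
  out <- if (grouping == "overall") {
    count_stratum(kept, "overall")
  } else {
    if (!grouping %in% names(kept)) {
      stop("grouping column `", grouping, "` not present in results",
           call. = FALSE)
    }
    g <- kept[[grouping]]
    dplyr::bind_rows(lapply(
      split(kept, g),
      function(part) count_stratum(part, part[[grouping]][1])
    ))
  }
  attr(out, "n_failed_qc") <- n_failed
  out
}

#' Confirmation outcomes by WES VAF bracket
#'
#' Bins results by their WES VAF (percent) into the supplied brackets
#' (left-closed, right-open; the last bracket closed) and additionally
#' emits the binary split at `split_at` used to contrast low against
#' moderately low VAF calls.
#'
#' @param results confirmation results carrying a `vaf` column (percent).
#' @param bracket_edges strictly increasing numeric edges; default
#'   `c(0.5, 1, 2, 3, 4, 5)`.
#' @param split_at percent for the binary at-or-below / above split;
#'   default 3.
#' @return list of two [summarize_confirmations()]-style tibbles:
#'   `brackets` and `split`.
#' @export
breakdown_by_vaf <- function(results, bracket_edges = c(0.5, 1, 2, 3, 4, 5),
                             split_at = 3) {
  if (any(diff(bracket_edges) <= 0)) {
    stop("`bracket_edges` must be strictly increasing", call. = FALSE)
  }
  if (!"vaf" %in% names(results)) {
    stop("results must carry the WES `vaf` column", call. = FALSE)
  }
  kept <- results[results$status != "failed_qc", ]
  labels <- paste0("[", bracket_edges[-length(bracket_edges)], ",",
                   bracket_edges[-1], ")")
  labels[length(labels)] <- sub("\\)$", "]",  labels[length(labels)])
  bin <- cut(kept$vaf, bracket_edges, labels = labels, right = FALSE,
             include.lowest = TRUE)
  brackets <- dplyr::bind_rows(lapply(levels(bin), function(lv) {
    count_stratum(kept[!is.na(bin) & bin == lv, ], lv)
  }))
  split_lab <- ifelse(kept$vaf > split_at,
                      paste0(">", split_at, "%"),
                      paste0("<=", split_at, "%"))
  split <- dplyr::bind_rows(lapply(
    unique(c(paste0("<=", split_at, "%"), paste0(">", split_at, "%"))),
    function(lv) count_stratum(kept[split_lab == lv, ], lv)
  ))
  list(brackets = brackets, split = split)
}

#' Confirmation outcomes by functional category
#'
#' Strata are the functional categories present in the results; labels
#' outside the known set (nonsynonymous, frameshift, synonymous, intron,
#' regulatory, other) are grouped under `"other"` with a warning.
#'
#' @param results confirmation results carrying a `category` column.
#' @return a [summarize_confirmations()]-style tibble.
#' @export
breakdown_by_category <- function(results) {
  cat <- results$category
  unknown <- !cat %in% CATEGORIES
  if (any(unknown)) {
    warning("unknown category label(s) ",
            paste(unique(cat[unknown]), collapse = ", "),
            " grouped under \"other\"", call. = FALSE)
    results$category[unknown] <- "other"
  }
  summarize_confirmations(results, "category")
}

#' Confirmation outcomes by alteration class
#'
#' Strata are the strand-collapsed substitution classes (plus indel) from
#' [classify_alteration()]. Beyond the usual counts, each class's share of
#' all tested and of all confirmed variants is reported — in an FFPE
#' sample, cytosine deamination concentrates the confirmed calls in the
#' C>T/G>A class.
#'
#' @param results confirmation results carrying `ref`/`alt` or a
#'   pre-computed `alteration` column.
#' @return [summarize_confirmations()]-style tibble with extra columns
#'   `share_of_tested` and `share_of_confirmed` (percent, rounded
#'   half-up; `share_of_confirmed` is NA when nothing was confirmed).
#' @export
breakdown_by_alteration <- function(results) {
  if (!"alteration" %in% names(results)) {
    results$alteration <- classify_alteration(results$ref, results$alt)
  }
  out <- summarize_confirmations(results, "alteration")
  total_tested <- sum(out$n_tested)
  total_confirmed <- sum(out$n_confirmed)
  out$share_of_tested <- round_half_up(100 * out$n_tested / total_tested)
  out$share_of_confirmed <- if (total_confirmed > 0) {
    round_half_up(100 * out$n_confirmed / total_confirmed)
  } else {
    NA_real_
  }
  out
}

#' WES false-negative analysis on the mirrored sample
#'
#' Takes variants called at low VAF in the fresh-frozen sample but absent
#' from the FFPE call set, and their BDA confirmations *run on the FFPE
#' template*: a confirmed result means the variant is actually present in
#' FFPE and WES missed it (a WES false negative); a non-confirmed result
#' means WES was right to not call it (true negative).
#'
#' @param ff_calls,ffpe_calls variant-call tibbles for the two samples.
#' @param ffpe_confirmations confirmation results (on the FFPE template)
#'   for a subset of the FF-only low-VAF calls; any supplied confirmation
#'   whose variant *is* in the FFPE call set is rejected.
#' @param vaf_cutoff percent; only FF calls below it are eligible.
#'   Default 5.
#' @return list: `n_eligible` (FF-only low-VAF calls), `n_tested`,
#'   `n_false_negative` (BDA-positive), `n_true_negative` (BDA-negative).
#' @export
false_negative_analysis <- function(ff_calls, ffpe_calls,
                                    ffpe_confirmations, vaf_cutoff = 5) {
  key_ff <- variant_key(ff_calls$chrom, ff_calls$pos, ff_calls$ref,
                        ff_calls$alt)
  key_ffpe <- variant_key(ffpe_calls$chrom, ffpe_calls$pos, ffpe_calls$ref,
                          ffpe_calls$alt)
  eligible <- key_ff[ff_calls$vaf < vaf_cutoff & !(key_ff %in% key_ffpe)]
  key_conf <- variant_key(ffpe_confirmations$chrom, ffpe_confirmations$pos,
                          ffpe_confirmations$ref, ffpe_confirmations$alt)
  if (any(key_conf %in% key_ffpe)) {
    stop("confirmation supplied for a variant already in the FFPE call ",
         "set: out of scope for the false-negative analysis",
         call. = FALSE)
  }
  tested <- ffpe_confirmations[ffpe_confirmations$status != "failed_qc", ]
  n_pos <- sum(tested$status == "confirmed")
  list(
    n_eligible = length(eligible),
    n_tested = nrow(tested),
    n_false_negative = n_pos,
    n_true_negative = nrow(tested) - n_pos
  )
}
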