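# The step-wise triage cascade applied to annotated panel calls, in the
# order a diagnostic lab applies it: variant fraction -> population
# frequency -> ClinVar assertion -> consequence class / synonymous rescue.
# The four filters are independent per-call predicates, so the survivor
# set does not depend on stage order; the funnel report materializes the
# per-stage in/out bookkeeping.

#' Cascade configuration
#'
#' Defaults encode the published triage protocol: variant fraction kept in
#' the inclusive interval 15-100%, population frequency strictly below
#' 0.1% ("below" is read literally as a strict inequality, while interval
#' bounds are inclusive), a 20-bp splice window, and synonymous variants
#' eliminated only when every available splice predictor agrees they do
#' not affect splicing.
#'
#' @param vaf_min,vaf_max inclusive variant-fraction bounds.
#' @param maf_threshold strict upper bound on population allele frequency.
#' @param splice_window intronic window (bases) around exon-intron
#'   junctions inside which intronic substitutions are retained.
#' @param synonymous_rescue `"all_predictors"` (remove a synonymous call
#'   only when every available predictor says no effect) or
#'   `"any_predictor"` (remove as soon as one predictor says no effect).
#' @param missing_frequency_passes keep calls absent from all three
#'   population databases (a rare-variant triage must not discard
#'   unobserved variants).
#' @return a list of class `cascade_config`.
#' @export
cascade_config <- function(vaf_min = 0.15, vaf_max = 1.0,
                           maf_threshold = 0.001, splice_window = 20,
                           synonymous_rescue = c("all_predictors",
                                                 "any_predictor"),
                           missing_frequency_passes = TRUE) {
  synonymous_rescue <- match.arg(synonymous_rescue)
  stopifnot(vaf_min >= 0, vaf_min <= vaf_max, vaf_max <= 1,
            maf_threshold > 0, maf_threshold < 1, splice_window >= 0)
  structure(list(vaf_min = vaf_min, vaf_max = vaf_max,
                 maf_threshold = maf_threshold,
                 splice_window = splice_window,
                 synonymous_rescue = synonymous_rescue,
                 missing_frequency_passes = missing_frequency_passes),
            class = "cascade_config")
}

#' DNA sample quality control
#'
#' A sample passes when both absorbance purity ratios lie in the
#' inclusive interval [1.8, 2.2] and the DNA mass is at least 100 ng
#' (in the assay's stated volume).
#'
#' @param a260_280,a260_230 absorbance ratios.
#' @param mass_ng double-stranded DNA mass in nanograms.
#' @return a list with `pass` (logical) and `reasons` (character vector of
#'   failed checks, empty when passing).
#' @examples
#' qc_sample(1.9, 2.0, 150)
#' qc_sample(1.7, 2.0, 150)$reasons
#' @export
qc_sample <- function(a260_280, a260_230, mass_ng) {
  vals <- c(a260_280 = a260_280, a260_230 = a260_230, mass_ng = mass_ng)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    ird_stop("QC inputs must be non-negative finite numbers")
  }
  reasons <- character(0)
  if (a260_280 < 1.8 || a260_280 > 2.2) reasons <- c(reasons, "a260_280")
  if (a260_230 < 1.8 || a260_230 > 2.2) reasons <- c(reasons, "a260_230")
  if (mass_ng < 100) reasons <- c(reasons, "mass_ng")
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Internal: ensure calls carry a stable per-row id used by the funnel,
# and materialize absent annotation columns with their "absent" value
# (NA frequencies/VAF, no ClinVar assertion, unavailable predictors).
ensure_call_id <- function(calls) {
  if (!"call_id" %in% names(calls)) {
    calls$call_id <- sprintf("call%04d", seq_len(nrow(calls)))
  }
  na_cols <- c("variant_fraction", "freq_gnomad", "freq_1000g", "freq_esp")
  for (col in na_cols) {
    if (!col %in% names(calls)) calls[[col]] <- rep(NA_real_, nrow(calls))
  }
  if (!"clinvar" %in% names(calls)) {
    calls$clinvar <- rep("none", nrow(calls))
  }
  for (col in c("splice_pred_mt", "splice_pred_hsf")) {
    if (!col %in% names(calls)) calls[[col]] <- rep("unavailable",
                                                    nrow(calls))
  }
  calls
}

# Internal: split calls by a logical keep vector into the (kept, removed)
# pair every filter returns; removed rows carry a reason string.
split_filter <- function(calls, keep, reason) {
  removed <- calls[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$removal_reason <- if (length(reason) == 1) reason
                              else reason[!keep]
  } else {
    removed$removal_reason <- character(0)
  }
  list(kept = calls[keep, , drop = FALSE], removed = removed)
}

#' Filter on variant fraction
#'
#' Keeps calls whose variant fraction lies in the inclusive interval
#' `[vaf_min, vaf_max]` (default 15-100%).  Calls with a missing variant
#' fraction are routed to `removed` with reason `"missing_vaf"`.
#'
#' @param calls annotated-call data.frame with a `variant_fraction`
#'   column.
#' @param config a [cascade_config()].
#' @return list with `kept` and `removed` data.frames.
#' @export
filter_vaf <- function(calls, config = cascade_config()) {
  calls <- ensure_call_id(calls)
  vaf <- calls$variant_fraction
  missing <- is.na(vaf)
  keep <- !missing & vaf >= config$vaf_min & vaf <= config$vaf_max
  reason <- ifelse(missing, "missing_vaf",
                   sprintf("vaf %.3f outside [%.2f, %.2f]", vaf,
                           config$vaf_min, config$vaf_max))
  split_filter(calls, keep, reason)
}

#' Filter on population allele frequency
#'
#' The frequency of a call is the maximum over its available database
#' frequencies (gnomAD, 1000 Genomes, ESP); kept iff that maximum is
#' strictly below the threshold.  Calls absent from every database are
#' kept when `missing_frequency_passes` (the default).
#'
#' @param calls annotated-call data.frame with `freq_gnomad`,
#'   `freq_1000g`, `freq_esp` columns (NA = absent).
#' @param config a [cascade_config()].
#' @return list with `kept` and `removed` data.frames.
#' @export
filter_population_frequency <- function(calls, config = cascade_config()) {
  calls <- ensure_call_id(calls)
  fr <- as.matrix(calls[, c("freq_gnomad", "freq_1000g", "freq_esp")])
  if (any(fr < 0 | fr > 1, na.rm = TRUE)) {
    ird_stop("population frequency outside [0, 1]")
  }
  all_absent <- apply(fr, 1, function(r) all(is.na(r)))
  fmax <- suppressWarnings(apply(fr, 1, max, na.rm = TRUE))
  keep <- ifelse(all_absent, config$missing_frequency_passes,
                 fmax < config$maf_threshold)
  reason <- ifelse(all_absent, "no_population_frequency",
                   sprintf("max frequency %.5f >= %.5f", fmax,
                           config$maf_threshold))
  split_filter(calls, keep, reason)
}

#' Filter on ClinVar assertion
#'
#' Calls asserted Benign or Likely benign in ClinVar are removed;
#' conflicting assertions and calls without an assertion are kept.
#'
#' @param calls annotated-call data.frame with a `clinvar` column over
#'   \{benign, likely_benign, vus, likely_pathogenic, pathogenic,
#'   conflicting, none\}.
#' @return list with `kept` and `removed` data.frames.
#' @export
filter_clinvar <- function(calls) {
  calls <- ensure_call_id(calls)
  cv <- tolower(ifelse(is_blank(calls$clinvar), "none", calls$clinvar))
  keep <- !cv %in% c("benign", "likely_benign")
  split_filter(calls, keep, paste0("clinvar_", cv))
}

#' Filter on consequence class with synonymous rescue
#'
#' Keeps missense, nonsense, frameshift, in-frame indels, delins,
#' deletions, duplications and splice-site calls.  Intronic calls beyond
#' the splice window (`intronic_other`) and calls of unknown consequence
#' are removed.  Synonymous calls are removed only when the splice
#' predictors dismiss them: under the default `all_predictors` policy
#' every available predictor must say `no_effect` (a synonymous call with
#' no available predictor is kept, since nothing demonstrated it inert).
#'
#' @param calls annotated-call data.frame; a `consequence` column is used
#'   when present, otherwise computed from `cdna`/`protein` via
#'   [classify_consequence()].
#' @param config a [cascade_config()].
#' @return list with `kept` and `removed` data.frames.
#' @export
filter_consequence_class <- function(calls, config = cascade_config()) {
  calls <- ensure_call_id(calls)
  if (!"consequence" %in% names(calls) || anyNA(calls$consequence)) {
    calls$consequence <- compute_consequences(calls, config$splice_window)
  }
  kept_classes <- c("missense", "nonsense", "frameshift", "inframe_indel",
                    "delins", "deletion", "duplication", "splice_site")

  syn_removed <- rep(FALSE, nrow(calls))
  syn <- calls$consequence == "synonymous"
  if (any(syn)) {
    preds <- cbind(mt = calls$splice_pred_mt[syn],
                   hsf = calls$splice_pred_hsf[syn])
    preds[is_blank(preds) | preds == "unavailable"] <- NA
    no_eff <- preds == "no_effect"
    syn_removed[syn] <- vapply(seq_len(sum(syn)), function(i) {
      avail <- !is.na(no_eff[i, ])
      if (!any(avail)) return(FALSE)
      if (config$synonymous_rescue == "all_predictors") {
        all(no_eff[i, avail])   # removed only if every predictor dismisses
      } else {
        any(no_eff[i, avail])
      }
    }, logical(1))
  }

  keep <- (calls$consequence %in% kept_classes) | (syn & !syn_removed)
  reason <- ifelse(syn, "synonymous_no_splice_effect",
                   paste0("consequence_", calls$consequence))
  split_filter(calls, keep, reason)
}

# Internal: vectorized consequence computation over a calls table.
compute_consequences <- function(calls, splice_window = 20) {
  vapply(seq_len(nrow(calls)), function(i) {
    classify_consequence(calls$cdna[i],
                         if ("protein" %in% names(calls)) calls$protein[i]
                         else NA_character_,
                         splice_window)
  }, character(1))
}

#' Run the full triage cascade
#'
#' Applies the four filters in protocol order (variant fraction ->
#' population frequency -> ClinVar -> consequence/synonymous) and
#' assembles a funnel report.  Because each filter is an independent
#' per-call predicate, the survivor set is identical under any stage
#' permutation; only the attribution of a multiply-failing call to a
#' stage depends on the order.
#'
#' @param calls annotated-call data.frame (see [read_calls_tsv()] /
#'   [read_vcf_minimal()]).
#' @param config a [cascade_config()].
#' @param order character vector permuting
#'   `c("vaf", "frequency", "clinvar", "consequence")`.
#' @return a list with `survivors` (data.frame) and `funnel` (a
#'   `funnel_report`: per-stage data.frame plus removal records).
#' @export
run_cascade <- function(calls, config = cascade_config(),
                        order = c("vaf", "frequency", "clinvar",
                                  "consequence")) {
  stopifnot(setequal(order, c("vaf", "frequency", "clinvar", "consequence")),
            length(order) == 4)
  calls <- ensure_call_id(calls)
  if (nrow(calls) > 0 &&
      (!"consequence" %in% names(calls) || anyNA(calls$consequence))) {
    calls$consequence <- compute_consequences(calls, config$splice_window)
  } else if (!"consequence" %in% names(calls)) {
    calls$consequence <- character(0)
  }
  n_input <- nrow(calls)

  stage_fun <- list(
    vaf = function(x) filter_vaf(x, config),
    frequency = function(x) filter_population_frequency(x, config),
    clinvar = filter_clinvar,
    consequence = function(x) filter_consequence_class(x, config))

  stages <- data.frame(stage = order, n_in = NA_integer_,
                       n_out = NA_integer_, n_removed = NA_integer_,
                       stringsAsFactors = FALSE)
  removals <- list()
  current <- calls
  for (i in seq_along(order)) {
    res <- stage_fun[[order[i]]](current)
    stages$n_in[i] <- nrow(current)
    stages$n_out[i] <- nrow(res$kept)
    stages$n_removed[i] <- nrow(res$removed)
    removals[[order[i]]] <- res$removed
    current <- res$kept
  }
  removed_all <- do.call(rbind, c(
    lapply(seq_along(order), function(i) {
      r <- removals[[order[i]]]
      if (nrow(r)) r$stage <- order[i] else r$stage <- character(0)
      r
    }), list(make.row.names = FALSE)))

  funnel <- structure(list(stages = stages, removed = removed_all,
                           n_input = n_input, n_survivors = nrow(current)),
                      class = "funnel_report")
  # conservation invariant: removals + survivors partition the input
  stopifnot(nrow(current) + nrow(removed_all) == n_input)
  list(survivors = current, funnel = funnel)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>", x$n_input, "calls in,", x$n_survivors,
      "survivors\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write a funnel report as TSV
#'
#' @param funnel a `funnel_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_funnel_tsv <- function(funnel, path) {
  stopifnot(inherits(funnel, "funnel_report"))
  utils::write.table(funnel$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Select the clinically reportable survivors
#'
#' Classifies each cascade survivor with the ACMG engine and retains only
#' classes P and LP; B, LB and VUS survivors are routed to a
#' non-reportable list together with their class.
#'
#' @param survivors survivor data.frame carrying a `criteria` column.
#' @param config a [combiner_config()].
#' @return a list with `reportable` and `not_reportable` data.frames, each
#'   with an `engine_class` column.
#' @export
report_clinically_relevant <- function(survivors,
                                       config = combiner_config()) {
  stopifnot(is.data.frame(survivors), "criteria" %in% names(survivors))
  cls <- vapply(survivors$criteria, function(s) {
    classify_criteria(parse_criteria_string(if (is.na(s)) "" else s), config)
  }, character(1), USE.NAMES = FALSE)
  survivors$engine_class <- cls
  keep <- cls %in% c("P", "LP")
  list(reportable = survivors[keep, , drop = FALSE],
       not_reportable = survivors[!keep, , drop = FALSE])
}
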