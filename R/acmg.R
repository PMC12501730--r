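# ACMG/AMP evidence combination: the five-tier classification produced
# either by the published combining-rule table ("richards" mode) or by a
# Bayesian-points scheme ("points" mode), plus reconciliation of engine
# output against the classifications a report already carries.
#
# Evidence codes are consumed at face-value strength; strength modulation
# (PM2 as supporting, PVS1 downgrades, ...) is intentionally not modelled
# because reports print only the face-value tokens.

CLASS_LEVELS <- c("B", "LB", "VUS", "LP", "P")

#' Combiner configuration
#'
#' @param mode `"richards"` (combining-rule table) or `"points"`.
#' @param conflict_policy how rule-table mode treats mixed evidence:
#'   `"pathogenic_dominant"` (default) lets a firing pathogenic
#'   combination stand even when benign evidence is present;
#'   `"strict"` returns VUS whenever evidence from both categories
#'   coexists with a firing combination.
#' @param point_weights named integer vector of per-strength points for
#'   points mode; benign strengths carry negative weights and BA1 is
#'   disqualifying (forces class B).
#' @param point_thresholds named integer vector with elements `P` (lower
#'   bound), `LP` (lower bound), `LB` (upper bound), `B` (upper bound);
#'   together they partition the integers into the five tiers.
#' @return a list of class `combiner_config`.
#' @export
combiner_config <- function(mode = c("richards", "points"),
                            conflict_policy = c("pathogenic_dominant",
                                                "strict"),
                            point_weights = c(very_strong = 8L, strong = 4L,
                                              moderate = 2L, supporting = 1L,
                                              benign_strong = -4L,
                                              benign_supporting = -1L),
                            point_thresholds = c(P = 10L, LP = 6L,
                                                 LB = -1L, B = -7L)) {
  mode <- match.arg(mode)
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(all(point_weights[c("very_strong", "strong", "moderate",
                                "supporting")] > 0))
  stopifnot(point_thresholds["P"] > point_thresholds["LP"],
            point_thresholds["LP"] > 0,
            point_thresholds["LB"] < 0,
            point_thresholds["B"] < point_thresholds["LB"])
  structure(list(mode = mode, conflict_policy = conflict_policy,
                 point_weights = point_weights,
                 point_thresholds = point_thresholds),
            class = "combiner_config")
}

#' Combine ACMG evidence by the published rule table
#'
#' Pathogenic fires for: PVS1 with (>=1 strong | >=2 moderate | 1 moderate
#' + 1 supporting | >=2 supporting); >=2 strong; or 1 strong with (>=3
#' moderate | 2 moderate + >=2 supporting | 1 moderate + >=4 supporting).
#' Likely pathogenic fires for: PVS1 + 1 moderate; 1 strong + 1-2
#' moderate; 1 strong + >=2 supporting; >=3 moderate; 2 moderate + >=2
#' supporting; or 1 moderate + >=4 supporting.  Benign fires for BA1 or
#' >=2 benign-strong; likely benign for 1 benign-strong + 1
#' benign-supporting or >=2 benign-supporting.  Anything else is VUS.
#' When P and LP both fire, P wins.  Mixed pathogenic/benign evidence is
#' resolved by the conflict policy (see [combiner_config()]).
#'
#' @param criteria a `criteria_set`, token vector, or criteria string.
#' @param conflict_policy `"pathogenic_dominant"` or `"strict"`.
#' @return one of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @examples
#' combine_richards("PVS1PM2")        # "LP"
#' combine_richards("PVS1PM2PS4PP5")  # "P"
#' @export
combine_richards <- function(criteria,
                             conflict_policy = c("pathogenic_dominant",
                                                 "strict")) {
  conflict_policy <- match.arg(conflict_policy)
  if (is.character(criteria) && length(criteria) == 1 &&
      !inherits(criteria, "criteria_set")) {
    criteria <- parse_criteria_string(criteria)
  }
  k <- criteria_counts(criteria)

  path_P <-
    (k$pvs >= 1 && (k$ps >= 1 || k$pm >= 2 ||
                    (k$pm >= 1 && k$pp >= 1) || k$pp >= 2)) ||
    k$ps >= 2 ||
    (k$ps >= 1 && (k$pm >= 3 ||
                   (k$pm >= 2 && k$pp >= 2) ||
                   (k$pm >= 1 && k$pp >= 4)))
  path_LP <-
    (k$pvs >= 1 && k$pm >= 1) ||
    (k$ps >= 1 && k$pm >= 1) ||
    (k$ps >= 1 && k$pp >= 2) ||
    k$pm >= 3 ||
    (k$pm >= 2 && k$pp >= 2) ||
    (k$pm >= 1 && k$pp >= 4)

  ben_B <- k$ba >= 1 || k$bs >= 2
  ben_LB <- (k$bs >= 1 && k$bp >= 1) || k$bp >= 2

  path_class <- if (path_P) "P" else if (path_LP) "LP" else NULL
  ben_class <- if (ben_B) "B" else if (ben_LB) "LB" else NULL

  if (!is.null(path_class) && !is.null(ben_class)) {
    return(switch(conflict_policy,
                  strict = "VUS",
                  pathogenic_dominant = path_class))
  }
  if (!is.null(path_class)) {
    # a firing pathogenic combination with any benign evidence present is
    # a conflict under the strict policy even if no benign rule fires
    if (conflict_policy == "strict" && k$n_benign > 0) return("VUS")
    return(path_class)
  }
  if (!is.null(ben_class)) {
    if (conflict_policy == "strict" && k$n_pathogenic > 0) return("VUS")
    return(ben_class)
  }
  "VUS"
}

#' Combine ACMG evidence by signed points
#'
#' Each code contributes its strength weight (pathogenic positive, benign
#' negative); BA1 is disqualifying and short-circuits to class B.  The
#' total is mapped onto the five tiers by the configured thresholds
#' (defaults: P >= 10, LP 6..9, VUS 0..5, LB -6..-1, B <= -7).
#'
#' @inheritParams combine_richards
#' @param config a [combiner_config()].
#' @return a list with `points` (integer total) and `class`.
#' @examples
#' combine_points("PVS1PM2")    # 10 points -> P
#' combine_points("PM2PM3PP5")  # 5 points -> VUS
#' @export
combine_points <- function(criteria, config = combiner_config()) {
  if (is.character(criteria) && length(criteria) == 1 &&
      !inherits(criteria, "criteria_set")) {
    criteria <- parse_criteria_string(criteria)
  }
  k <- criteria_counts(criteria)
  w <- config$point_weights
  total <- k$pvs * w[["very_strong"]] + k$ps * w[["strong"]] +
    k$pm * w[["moderate"]] + k$pp * w[["supporting"]] +
    k$bs * w[["benign_strong"]] + k$bp * w[["benign_supporting"]]
  total <- as.integer(total)
  if (k$ba >= 1) {
    return(list(points = total, class = "B"))
  }
  th <- config$point_thresholds
  cls <- if (total >= th[["P"]]) "P"
         else if (total >= th[["LP"]]) "LP"
         else if (total > th[["LB"]]) "VUS"
         else if (total > th[["B"]]) "LB"
         else "B"
  list(points = total, class = cls)
}

#' Classify a criteria set under a combiner configuration
#'
#' Thin dispatcher over [combine_richards()] / [combine_points()].
#'
#' @inheritParams combine_points
#' @return one of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @export
classify_criteria <- function(criteria, config = combiner_config()) {
  if (config$mode == "points") {
    combine_points(criteria, config)$class
  } else {
    combine_richards(criteria, config$conflict_policy)
  }
}

#' Reconcile engine classifications with reported ones
#'
#' Classifies every record's criteria string under the configured mode and
#' compares with the classification the report carries.  Concordance is a
#' measured quantity, never an assertion: reports routinely contain rows
#' (e.g. `PM2PP4` printed as LP) that no face-value rule combination
#' explains, and those must surface as discordant.
#'
#' @param records a variant-record data.frame (see [read_calls_tsv()]);
#'   must carry `criteria`; rows lacking `reported_class` are listed as
#'   uninformative and not counted either way.
#' @param config a [combiner_config()].
#' @return an object of class `reconciliation_report`: a list with
#'   `table` (per-record data.frame with `engine_class`, `reported_class`,
#'   `concordant`, `detail`), `n_concordant`, `n_discordant`,
#'   `n_uninformative` and `discordant` (the discordant subset).
#' @export
reconcile_with_reported <- function(records, config = combiner_config()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  engine <- character(n)
  detail <- character(n)
  for (i in seq_len(n)) {
    cs <- parse_criteria_string(records$criteria[i])
    if (config$mode == "points") {
      r <- combine_points(cs, config)
      engine[i] <- r$class
      detail[i] <- paste0("points=", r$points)
    } else {
      engine[i] <- combine_richards(cs, config$conflict_policy)
      detail[i] <- paste0("richards/", config$conflict_policy)
    }
  }
  reported <- if ("reported_class" %in% names(records)) {
    as.character(records$reported_class)
  } else {
    rep(NA_character_, n)
  }
  informative <- !is_blank(reported)
  concordant <- informative & engine == reported

  tab <- data.frame(
    patient_id = if ("patient_id" %in% names(records)) records$patient_id
                 else rep(NA_character_, n),
    gene = if ("gene" %in% names(records)) records$gene
           else rep(NA_character_, n),
    cdna = if ("cdna" %in% names(records)) records$cdna
           else rep(NA_character_, n),
    criteria = records$criteria,
    engine_class = engine,
    reported_class = reported,
    concordant = ifelse(informative, concordant, NA),
    detail = detail,
    stringsAsFactors = FALSE)

  structure(list(
    table = tab,
    n_concordant = sum(concordant),
    n_discordant = sum(informative & !concordant),
    n_uninformative = sum(!informative),
    discordant = tab[informative & !concordant, , drop = FALSE]),
    class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat("<reconciliation_report>\n")
  cat("  concordant:   ", x$n_concordant, "\n")
  cat("  discordant:   ", x$n_discordant, "\n")
  cat("  uninformative:", x$n_uninformative, "\n")
  if (x$n_discordant > 0) {
    cat("  discordant rows:\n")
    d <- x$discordant
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %s %s %s: %s -> engine %s vs reported %s\n",
                  d$patient_id[i], d$gene[i], d$cdna[i], d$criteria[i],
                  d$engine_class[i], d$reported_class[i]))
    }
  }
  invisible(x)
}

#' Write a reconciliation report as TSV
#'
#' @param report a `reconciliation_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reconciliation_tsv <- function(report, path) {
  stopifnot(inherits(report, "reconciliation_report"))
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
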