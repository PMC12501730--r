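# Per-patient case solving and cohort statistics: diagnostic yield,
# pathogenicity and consequence-type distributions, per-gene counts,
# recurrence, novelty reconciliation, and reconstruction of integer
# counts from printed subgroup percentages.

#' Solve cases from reported variant records
#'
#' A patient is molecularly solved when they carry, among P/LP records:
#' (a) a homozygous or hemizygous record; (b) at least two heterozygous
#' records in one gene whose inheritance modes include AR (compound
#' heterozygote, phase assumed in trans since panel tables carry no
#' phasing); or (c) a heterozygous record in a gene whose modes include
#' AD.  Rules are tried in that order and the first that applies is
#' recorded.  Patients whose P/LP records are only single heterozygous
#' hits in AR-only genes are returned separately as unsolved carriers.
#'
#' @param records variant-record data.frame with `patient_id`, `gene`,
#'   `zygosity`, `inheritance` and a classification; by default the
#'   `reported_class` column decides P/LP membership, falling back to the
#'   ACMG engine on `criteria` where it is absent.
#' @param engine_config a [combiner_config()] for the fallback.
#' @return a list with `solved` (data.frame: `patient_id`, `rule`,
#'   `genes`, `n_records`, `phase_assumed`) and `carriers` (data.frame of
#'   unsolved carrier patients with their record counts).
#' @examples
#' recs <- load_fixture("table2")
#' solve_cases(recs)$solved[1:3, ]
#' @export
solve_cases <- function(records, engine_config = combiner_config()) {
  stopifnot(is.data.frame(records))
  req <- c("patient_id", "gene", "zygosity", "inheritance")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    ird_stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  cls <- if ("reported_class" %in% names(records)) {
    as.character(records$reported_class)
  } else {
    rep(NA_character_, nrow(records))
  }
  needs_engine <- is_blank(cls)
  if (any(needs_engine)) {
    if (!"criteria" %in% names(records)) {
      ird_stop("records without reported_class need a criteria column")
    }
    cls[needs_engine] <- vapply(records$criteria[needs_engine], function(s) {
      classify_criteria(parse_criteria_string(if (is.na(s)) "" else s),
                        engine_config)
    }, character(1), USE.NAMES = FALSE)
  }
  plp <- records[cls %in% c("P", "LP"), , drop = FALSE]
  plp$zygosity <- normalize_zygosity(plp$zygosity)
  modes <- parse_inheritance(plp$inheritance)

  solved <- list()
  carriers <- list()
  for (pid in unique(plp$patient_id)) {
    idx <- which(plp$patient_id == pid)
    zyg <- plp$zygosity[idx]
    gen <- plp$gene[idx]
    mod <- modes[idx]

    hom <- idx[zyg %in% c("homozygous", "hemizygous")]
    if (length(hom)) {
      rule <- if (plp$zygosity[hom[1]] == "hemizygous") "hemizygous"
              else "homozygous"
      solved[[pid]] <- data.frame(
        patient_id = pid, rule = rule,
        genes = paste(unique(plp$gene[hom]), collapse = ","),
        n_records = length(hom), phase_assumed = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    # compound heterozygote: >=2 het records in one AR-capable gene
    het_ar <- idx[zyg == "heterozygous" &
                  vapply(mod, function(m) "AR" %in% m, logical(1))]
    comp_gene <- names(which(table(plp$gene[het_ar]) >= 2))
    if (length(comp_gene)) {
      solved[[pid]] <- data.frame(
        patient_id = pid, rule = "compound_het_AR",
        genes = paste(comp_gene, collapse = ","),
        n_records = sum(plp$gene[het_ar] %in% comp_gene),
        phase_assumed = TRUE, stringsAsFactors = FALSE)
      next
    }
    het_ad <- idx[zyg == "heterozygous" &
                  vapply(mod, function(m) "AD" %in% m, logical(1))]
    if (length(het_ad)) {
      solved[[pid]] <- data.frame(
        patient_id = pid, rule = "heterozygous_AD",
        genes = paste(unique(plp$gene[het_ad]), collapse = ","),
        n_records = length(het_ad), phase_assumed = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    carriers[[pid]] <- data.frame(
      patient_id = pid,
      genes = paste(unique(gen), collapse = ","),
      n_records = length(idx), stringsAsFactors = FALSE)
  }
  empty_solved <- data.frame(patient_id = character(0), rule = character(0),
                             genes = character(0), n_records = integer(0),
                             phase_assumed = logical(0))
  empty_carriers <- data.frame(patient_id = character(0),
                               genes = character(0), n_records = integer(0))
  list(
    solved = if (length(solved)) do.call(rbind, c(solved, list(
      make.row.names = FALSE))) else empty_solved,
    carriers = if (length(carriers)) do.call(rbind, c(carriers, list(
      make.row.names = FALSE))) else empty_carriers)
}

#' Diagnostic yield
#'
#' @param solved the `solved` data.frame from [solve_cases()] (or any
#'   data.frame with one row per solved patient).
#' @param n_cohort total number of patients tested.
#' @return list with `n_solved`, `pct_raw` (exact percentage) and
#'   `pct_rounded` (nearest integer, half-up).
#' @examples
#' diagnostic_yield(solve_cases(load_fixture("table2"))$solved, 94)
#' @export
diagnostic_yield <- function(solved, n_cohort) {
  n_solved <- if (is.data.frame(solved)) nrow(solved) else as.integer(solved)
  if (!is.numeric(n_cohort) || n_cohort <= 0) {
    ird_stop("n_cohort must be a positive integer")
  }
  if (n_cohort < n_solved) {
    ird_stop("n_cohort smaller than the number of solved patients")
  }
  pct <- 100 * n_solved / n_cohort
  list(n_solved = n_solved, pct_raw = pct,
       pct_rounded = as.integer(round_half_up(pct)))
}

# Internal: counts + half-up two-decimal percentages over a denominator.
count_pct <- function(values, levels, denom = length(values)) {
  n <- vapply(levels, function(l) sum(values == l), integer(1))
  data.frame(level = levels, n = n,
             pct = if (denom > 0) round_half_up(100 * n / denom, 2)
                   else numeric(length(n)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pathogenicity distribution of reported variants
#'
#' @param records variant-record data.frame with `reported_class`.
#' @return data.frame with columns `class`, `n`, `pct` (two decimals,
#'   half-up, denominator = all records with a reported class).
#' @export
pathogenicity_distribution <- function(records) {
  cls <- as.character(records$reported_class)
  cls <- cls[!is_blank(cls)]
  out <- count_pct(cls, intersect(c("P", "LP", "VUS", "LB", "B"),
                                  unique(cls)), length(cls))
  names(out)[1] <- "class"
  out
}

#' Consequence-type distribution with divergence flagging
#'
#' Classifies every record via [classify_consequence()] and tabulates the
#' result.  When an `expected` table is supplied (named integer vector of
#' externally printed counts), classes whose computed count differs are
#' flagged in the output rather than silently reconciled; the fixture's
#' published tally bins one synonymous row under missense and one intronic
#' deletion under splice-site, and those divergences must stay visible.
#'
#' @param records variant-record data.frame with `cdna` and `protein`.
#' @param splice_window passed to [classify_consequence()].
#' @param expected optional named vector of expected counts per class.
#' @return data.frame with `consequence`, `n`, `pct`, and (when
#'   `expected` is given) `expected_n` and `flagged`.
#' @examples
#' variant_type_distribution(load_fixture("table2"))
#' @export
variant_type_distribution <- function(records, splice_window = 20,
                                      expected = NULL) {
  cons <- compute_consequences(records, splice_window)
  out <- count_pct(cons, consequence_types(), length(cons))
  names(out)[1] <- "consequence"
  if (!is.null(expected)) {
    out$expected_n <- ifelse(out$consequence %in% names(expected),
                             as.integer(expected[out$consequence]),
                             NA_integer_)
    out$flagged <- !is.na(out$expected_n) & out$expected_n != out$n
  }
  out
}

#' Per-gene variant and patient counts
#'
#' @param records variant-record data.frame.
#' @return data.frame with `gene`, `n_variants` (table rows) and
#'   `n_patients` (distinct patients), sorted by descending `n_variants`
#'   with alphabetical tie-break; the number of distinct genes is carried
#'   in attribute `n_genes`.
#' @export
gene_distribution <- function(records) {
  genes <- sort(unique(records$gene))
  out <- data.frame(
    gene = genes,
    n_variants = vapply(genes, function(g) sum(records$gene == g),
                        integer(1)),
    n_patients = vapply(genes, function(g) {
      length(unique(records$patient_id[records$gene == g]))
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n_variants, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genes") <- length(genes)
  out
}

#' Recurrence of individual variants across patients
#'
#' Keys variants by (gene, normalized cDNA change) and counts distinct
#' patients, so duplicated rows for one patient never inflate the count.
#'
#' @param records variant-record data.frame.
#' @return data.frame with `gene`, `cdna` (normalized), `n_patients`,
#'   sorted by descending `n_patients` then gene/cdna.
#' @export
recurrence <- function(records) {
  key_gene <- records$gene
  key_cdna <- normalize_hgvs(records$cdna)
  key <- paste(key_gene, key_cdna, sep = "\r")
  uk <- unique(key)
  out <- data.frame(
    gene = sub("\r.*$", "", uk),
    cdna = sub("^.*\r", "", uk),
    n_patients = vapply(uk, function(k) {
      length(unique(records$patient_id[key == k]))
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n_patients, out$gene, out$cdna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile a novel-variant list against the cohort records
#'
#' Matches every row of the novel list onto the cohort table by
#' (patient_id, gene, normalized cDNA change) and sets the `novel` flag
#' on the matched records.  Every novel-list row must match exactly one
#' record: unmatched or multiply-matched rows are an error naming them,
#' never a silent drop.
#'
#' @param records variant-record data.frame.
#' @param novel_list data.frame with `patient_id`, `gene`, `cdna`.
#' @return `records` with a logical `novel` column set.
#' @examples
#' recs <- flag_novel(load_fixture("table2"), load_fixture("table3"))
#' sum(recs$novel)
#' @export
flag_novel <- function(records, novel_list) {
  stopifnot(is.data.frame(records), is.data.frame(novel_list))
  rec_key <- paste(records$patient_id, records$gene,
                   normalize_hgvs(records$cdna), sep = "\r")
  records$novel <- FALSE
  if (nrow(novel_list) == 0) return(records)
  nov_key <- paste(novel_list$patient_id, novel_list$gene,
                   normalize_hgvs(novel_list$cdna), sep = "\r")
  problems <- character(0)
  for (i in seq_along(nov_key)) {
    hits <- which(rec_key == nov_key[i])
    if (length(hits) == 1) {
      records$novel[hits] <- TRUE
    } else {
      problems <- c(problems, sprintf(
        "%s %s %s (%s)", novel_list$patient_id[i], novel_list$gene[i],
        novel_list$cdna[i],
        if (length(hits) == 0) "unmatched" else "multiply matched"))
    }
  }
  if (length(problems)) {
    ird_stop("novel-list rows failed to reconcile: ",
             paste(problems, collapse = "; "))
  }
  records
}

#' Reconstruct an integer count from subgroup percentages
#'
#' Published demographic tables often print only subgroup sizes and
#' percentages; the underlying count is recovered as the sum of
#' `round(n * pct / 100)` over subgroups, rounding half-up per subgroup.
#'
#' @param n integer vector of subgroup sizes.
#' @param pct numeric vector of percentages in `[0, 100]`, same length.
#' @return the reconstructed integer total.
#' @examples
#' # consanguinity across eight clinical subgroups
#' reconstruct_counts_from_percentages(
#'   c(28, 10, 4, 7, 8, 4, 9, 24),
#'   c(82.14, 90, 100, 85.71, 62.50, 75, 100, 41.67))
#' @export
reconstruct_counts_from_percentages <- function(n, pct) {
  stopifnot(length(n) == length(pct))
  if (any(is.na(n)) || any(is.na(pct)) || any(pct < 0) || any(pct > 100)) {
    ird_stop("percentages must lie in [0, 100] and sizes must be known")
  }
  as.integer(sum(round_half_up(n * pct / 100)))
}

#' Summarize a cohort
#'
#' Composes case solving, yield, pathogenicity and consequence-type
#' distributions, gene distribution, recurrence and (optionally) novelty
#' into one summary object.
#'
#' @param records variant-record data.frame.
#' @param n_cohort total patients tested.
#' @param novel_list optional novel-variant list for [flag_novel()].
#' @param splice_window passed to the consequence classifier.
#' @param expected_types optional expected counts for
#'   [variant_type_distribution()] flagging.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records, n_cohort, novel_list = NULL,
                             splice_window = 20, expected_types = NULL) {
  if (!is.null(novel_list)) records <- flag_novel(records, novel_list)
  cases <- solve_cases(records)
  structure(list(
    n_cohort = n_cohort,
    n_records = nrow(records),
    cases = cases,
    yield = if (n_cohort > 0) diagnostic_yield(cases$solved, n_cohort)
            else list(n_solved = 0L, pct_raw = 0, pct_rounded = 0L),
    pathogenicity = pathogenicity_distribution(records),
    types = variant_type_distribution(records, splice_window,
                                      expected_types),
    genes = gene_distribution(records),
    recurrence = recurrence(records),
    n_novel = if ("novel" %in% names(records)) {
      sum(records$novel %in% TRUE)
    } else NA_integer_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  %d variants in %d patients of %d tested; yield %d/%d = %s%% (%d%%)\n",
              x$n_records, nrow(x$cases$solved) + nrow(x$cases$carriers),
              x$n_cohort, x$yield$n_solved, x$n_cohort,
              formatC(x$yield$pct_raw, digits = 2, format = "f"),
              x$yield$pct_rounded))
  cat("  pathogenicity:\n")
  p <- x$pathogenicity
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-4s %3d (%6.2f%%)\n", p$class[i], p$n[i], p$pct[i]))
  }
  cat("  consequence types (nonzero):\n")
  t <- x$types[x$types$n > 0, ]
  for (i in seq_len(nrow(t))) {
    cat(sprintf("    %-14s %3d (%6.2f%%)%s\n", t$consequence[i], t$n[i],
                t$pct[i],
                if (!is.null(t$flagged) && isTRUE(t$flagged[i]))
                  "  [diverges from supplied expected count]" else ""))
  }
  if (nrow(x$genes) > 0) {
    top <- x$genes[1, ]
    cat(sprintf("  genes: %d distinct; top %s with %d variants in %d patients\n",
                attr(x$genes, "n_genes"), top$gene, top$n_variants,
                top$n_patients))
  }
  if (!is.na(x$n_novel)) cat("  novel variants:", x$n_novel, "\n")
  invisible(x)
}

#' Render a cohort summary as a TSV section file
#'
#' Writes the summary's tables (yield, pathogenicity, types, genes,
#' recurrence) as one TSV with a `section` column, deterministic column
#' order and two-decimal percentages; round-trips through
#' [utils::read.delim()].
#'
#' @param summary a `cohort_summary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  rows <- list(
    data.frame(section = "yield", key = "n_solved",
               value = as.character(summary$yield$n_solved)),
    data.frame(section = "yield", key = "n_cohort",
               value = as.character(summary$n_cohort)),
    data.frame(section = "yield", key = "pct_raw",
               value = formatC(summary$yield$pct_raw, digits = 2,
                               format = "f")),
    data.frame(section = "yield", key = "pct_rounded",
               value = as.character(summary$yield$pct_rounded)))
  p <- summary$pathogenicity
  for (i in seq_len(nrow(p))) {
    rows[[length(rows) + 1]] <- data.frame(
      section = "pathogenicity", key = p$class[i],
      value = sprintf("%d|%.2f", p$n[i], p$pct[i]))
  }
  t <- summary$types
  for (i in seq_len(nrow(t))) {
    rows[[length(rows) + 1]] <- data.frame(
      section = "types", key = t$consequence[i],
      value = sprintf("%d|%.2f", t$n[i], t$pct[i]))
  }
  g <- summary$genes
  for (i in seq_len(nrow(g))) {
    rows[[length(rows) + 1]] <- data.frame(
      section = "genes", key = g$gene[i],
      value = sprintf("%d|%d", g$n_variants[i], g$n_patients[i]))
  }
  r <- summary$recurrence
  for (i in seq_len(nrow(r))) {
    rows[[length(rows) + 1]] <- data.frame(
      section = "recurrence", key = paste(r$gene[i], r$cdna[i]),
      value = as.character(r$n_patients[i]))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
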