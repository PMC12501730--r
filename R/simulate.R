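# Seeded synthetic-cohort generator with planted ground truth.
#
# Every record is constructed with a known fate: either it survives the
# whole triage cascade, or it violates exactly one named filter and
# passes all the others.  Planted solved patients receive genotypes that
# satisfy one of the case-solving rules, with criteria sets drawn only
# from fixture strings whose face-value rule-table class is P or LP, so
# cascade + case solving must recover the ground truth exactly — not
# statistically.

#' Simulation configuration
#'
#' Defaults emulate the packaged cohort: 94 patients, a 74% solved rate,
#' a 73.4% consanguinity rate, criteria sets drawn from the empirical
#' distribution of the 97 fixture strings and genes (with inheritance
#' modes) from the 45 fixture genes.
#'
#' @param n_patients cohort size.
#' @param solved_rate probability a patient is planted solved.
#' @param background_mean mean number of background (non-causal) calls
#'   per patient; each background call is planted to fail exactly one
#'   filter or to survive as a VUS.
#' @param stage_failure_mix named proportions over
#'   \{vaf, frequency, clinvar, consequence\} for background fates; the
#'   remainder (must be >= 0) survives the cascade.
#' @param criteria_pool character vector of criteria strings sampled for
#'   causal variants (filtered to face-value P/LP internally).
#' @param gene_pool data.frame with `gene` and `inheritance` columns.
#' @param consanguinity_rate probability a patient's parents are related
#'   (patient metadata only).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 94, solved_rate = 0.74,
                              background_mean = 8,
                              stage_failure_mix = c(vaf = 0.2,
                                                    frequency = 0.3,
                                                    clinvar = 0.2,
                                                    consequence = 0.2),
                              criteria_pool = NULL, gene_pool = NULL,
                              consanguinity_rate = 0.734) {
  stopifnot(n_patients >= 1, solved_rate >= 0, solved_rate <= 1,
            background_mean >= 0,
            consanguinity_rate >= 0, consanguinity_rate <= 1)
  stopifnot(setequal(names(stage_failure_mix),
                     c("vaf", "frequency", "clinvar", "consequence")),
            all(stage_failure_mix >= 0), sum(stage_failure_mix) <= 1)
  if (is.null(criteria_pool) || is.null(gene_pool)) {
    tab2 <- load_fixture("table2")
    if (is.null(criteria_pool)) criteria_pool <- tab2$criteria
    if (is.null(gene_pool)) {
      gene_pool <- data.frame(gene = tab2$gene,
                              inheritance = tab2$inheritance,
                              stringsAsFactors = FALSE)
    }
  }
  # one row per gene, modes unioned across entries (a gene listed with
  # both "AR" and "AD, AR" is AD- and AR-capable)
  if (nrow(gene_pool) > 0) {
    merged <- vapply(split(gene_pool$inheritance, gene_pool$gene),
                     function(v) {
                       m <- unique(unlist(parse_inheritance(v)))
                       paste(sort(m), collapse = ", ")
                     }, character(1))
    gene_pool <- data.frame(gene = names(merged), inheritance = unname(merged),
                            stringsAsFactors = FALSE)
  }
  # causal criteria must classify P/LP at face value so recovery cannot
  # depend on the engine mode
  plp <- vapply(unique(criteria_pool), function(s) {
    combine_richards(parse_criteria_string(s)) %in% c("P", "LP")
  }, logical(1))
  causal_pool <- unique(criteria_pool)[plp]
  if (solved_rate > 0 && (length(causal_pool) == 0 || nrow(gene_pool) == 0)) {
    ird_stop("solved_rate > 0 requires a non-empty P/LP criteria pool ",
             "and gene pool")
  }
  structure(list(n_patients = as.integer(n_patients),
                 solved_rate = solved_rate,
                 background_mean = background_mean,
                 stage_failure_mix = stage_failure_mix,
                 criteria_pool = criteria_pool,
                 causal_pool = causal_pool,
                 gene_pool = gene_pool,
                 consanguinity_rate = consanguinity_rate),
            class = "simulation_config")
}

# Internal synthetic-variant builders.  Positions and bases are random;
# descriptions are valid HGVS-lite by construction.
BASES <- c("A", "C", "G", "T")

synth_missense <- function() {
  pos <- sample(100:9000, 1)
  ref <- sample(BASES, 1); alt <- sample(setdiff(BASES, ref), 1)
  aa <- sample(AA3, 2, replace = FALSE)
  list(cdna = sprintf("c.%d%s>%s", pos, ref, alt),
       protein = sprintf("p.%s%d%s", aa[1], ceiling(pos / 3), aa[2]))
}

synth_nonsense <- function() {
  pos <- sample(100:9000, 1)
  ref <- sample(BASES, 1); alt <- sample(setdiff(BASES, ref), 1)
  list(cdna = sprintf("c.%d%s>%s", pos, ref, alt),
       protein = sprintf("p.%s%d*", sample(AA3, 1), ceiling(pos / 3)))
}

synth_frameshift <- function() {
  pos <- sample(100:9000, 1)
  aa <- sample(AA3, 2, replace = FALSE)
  list(cdna = sprintf("c.%ddel%s", pos, sample(BASES, 1)),
       protein = sprintf("p.%s%d%sfs*%d", aa[1], ceiling(pos / 3), aa[2],
                         sample(2:60, 1)))
}

synth_splice <- function(max_offset = 2) {
  pos <- sample(100:9000, 1)
  off <- sample(c(-max_offset:-1, 1:max_offset), 1)
  ref <- sample(BASES, 1); alt <- sample(setdiff(BASES, ref), 1)
  list(cdna = sprintf("c.%d%+d%s>%s", pos, off, ref, alt), protein = "p.?")
}

synth_deep_intronic <- function(min_offset = 21) {
  pos <- sample(100:9000, 1)
  off <- sample(min_offset:(min_offset + 80), 1) * sample(c(-1, 1), 1)
  ref <- sample(BASES, 1); alt <- sample(setdiff(BASES, ref), 1)
  list(cdna = sprintf("c.%d%+d%s>%s", pos, off, ref, alt), protein = "p.?")
}

synth_synonymous <- function() {
  pos <- sample(100:9000, 1)
  ref <- sample(BASES, 1); alt <- sample(setdiff(BASES, ref), 1)
  aa <- sample(AA3, 1)
  list(cdna = sprintf("c.%d%s>%s", pos, ref, alt),
       protein = sprintf("p.%s%d%s", aa, ceiling(pos / 3), aa))
}

synth_causal_variant <- function() {
  builder <- sample(list(synth_missense, synth_nonsense, synth_frameshift,
                         synth_splice), 1)[[1]]
  builder()
}

# Internal: annotations that pass every filter.
clean_annotations <- function(vaf_range = c(0.35, 0.65),
                              config = cascade_config()) {
  list(variant_fraction = round(stats::runif(1, vaf_range[1],
                                             vaf_range[2]), 3),
       freq_gnomad = if (stats::runif(1) < 0.5) NA_real_ else
         round(stats::runif(1, 0, config$maf_threshold / 2), 6),
       freq_1000g = NA_real_, freq_esp = NA_real_,
       clinvar = sample(c("none", "pathogenic", "likely_pathogenic",
                          "vus", "conflicting"), 1),
       splice_pred_mt = "affects", splice_pred_hsf = "unavailable")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Deterministic for a fixed seed.  Produces an annotated-call table, a
#' trio table (genotypes consistent with each planted causal variant),
#' patient metadata, and the ground truth: each record's planted fate
#' (`survivor` or `fails_<stage>`) and each patient's planted solved
#' status and rule.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param cascade a [cascade_config()] whose thresholds the planted
#'   annotations respect (failing frequencies are sampled in
#'   `[2, 10] * maf_threshold`, surviving ones in `[0, maf_threshold/2]`
#'   or absent, so no fate sits on a boundary).
#' @return a list with `calls`, `trios`, `patients` and `truth`
#'   (data.frame keyed by `call_id` with `planted_fate`).
#' @examples
#' cohort <- generate_cohort(simulation_config(n_patients = 10), seed = 1)
#' table(cohort$truth$planted_fate)
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1,
                            cascade = cascade_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  calls <- list(); truth <- list(); trios <- list(); patients <- list()
  fates <- c(names(config$stage_failure_mix), "survivor")
  fate_prob <- c(unname(config$stage_failure_mix),
                 1 - sum(config$stage_failure_mix))

  # split genes by solvable rule capability
  modes <- parse_inheritance(config$gene_pool$inheritance)
  ar_genes <- config$gene_pool$gene[vapply(modes, function(m) "AR" %in% m,
                                           logical(1))]
  ad_genes <- config$gene_pool$gene[vapply(modes, function(m) "AD" %in% m,
                                           logical(1))]
  xlr_genes <- config$gene_pool$gene[vapply(modes, function(m) "XLR" %in% m,
                                            logical(1))]
  mode_of <- function(g) {
    config$gene_pool$inheritance[match(g, config$gene_pool$gene)]
  }

  call_no <- 0
  new_id <- function() {
    call_no <<- call_no + 1
    sprintf("sim%05d", call_no)
  }

  add_call <- function(pid, gene, variant, zygosity, criteria, ann, fate) {
    id <- new_id()
    calls[[id]] <<- data.frame(
      call_id = id, patient_id = pid, gene = gene,
      transcript = NA_character_, cdna = variant$cdna,
      protein = variant$protein, zygosity = zygosity,
      criteria = criteria, reported_class = NA_character_,
      inheritance = mode_of(gene),
      variant_fraction = ann$variant_fraction,
      freq_gnomad = ann$freq_gnomad, freq_1000g = ann$freq_1000g,
      freq_esp = ann$freq_esp, clinvar = ann$clinvar,
      splice_pred_mt = ann$splice_pred_mt,
      splice_pred_hsf = ann$splice_pred_hsf,
      stringsAsFactors = FALSE)
    truth[[id]] <<- data.frame(call_id = id, patient_id = pid,
                               planted_fate = fate,
                               stringsAsFactors = FALSE)
    id
  }

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("S%03d", p)
    sex <- sample(c("male", "female"), 1)
    solved <- stats::runif(1) < config$solved_rate
    rule <- NA_character_

    if (solved) {
      choices <- c(
        if (length(ar_genes)) c("homozygous", "compound_het_AR"),
        if (length(ad_genes)) "heterozygous_AD",
        if (length(xlr_genes) && sex == "male") "hemizygous")
      rule <- sample(choices, 1,
                     prob = c(0.6, 0.2, 0.15, 0.05)[seq_along(choices)])
      crit <- function() sample(config$causal_pool, 1)
      if (rule == "homozygous") {
        g <- sample(ar_genes, 1)
        v <- synth_causal_variant()
        ann <- clean_annotations(c(0.85, 1.0), cascade)
        add_call(pid, g, v, "homozygous", crit(), ann, "survivor")
        trios[[pid]] <- data.frame(patient_id = pid, gene = g,
                                   cdna = v$cdna, mother_gt = "het",
                                   father_gt = "het", sex = sex,
                                   stringsAsFactors = FALSE)
      } else if (rule == "compound_het_AR") {
        g <- sample(ar_genes, 1)
        v1 <- synth_causal_variant(); v2 <- synth_causal_variant()
        add_call(pid, g, v1, "heterozygous", crit(),
                 clean_annotations(config = cascade), "survivor")
        add_call(pid, g, v2, "heterozygous", crit(),
                 clean_annotations(config = cascade), "survivor")
        trios[[pid]] <- data.frame(patient_id = pid, gene = g,
                                   cdna = v1$cdna, mother_gt = "het",
                                   father_gt = "hom_ref", sex = sex,
                                   stringsAsFactors = FALSE)
      } else if (rule == "heterozygous_AD") {
        g <- sample(ad_genes, 1)
        v <- synth_causal_variant()
        add_call(pid, g, v, "heterozygous", crit(),
                 clean_annotations(config = cascade), "survivor")
        trios[[pid]] <- data.frame(patient_id = pid, gene = g,
                                   cdna = v$cdna, mother_gt = "hom_ref",
                                   father_gt = "het", sex = sex,
                                   stringsAsFactors = FALSE)
      } else { # hemizygous XLR male
        g <- sample(xlr_genes, 1)
        v <- synth_causal_variant()
        ann <- clean_annotations(c(0.85, 1.0), cascade)
        add_call(pid, g, v, "hemizygous", crit(), ann, "survivor")
        trios[[pid]] <- data.frame(patient_id = pid, gene = g,
                                   cdna = v$cdna, mother_gt = "het",
                                   father_gt = "hemi_ref", sex = sex,
                                   stringsAsFactors = FALSE)
      }
    }

    n_bg <- stats::rpois(1, config$background_mean)
    if (n_bg > 0) {
      bg_fates <- sample(fates, n_bg, replace = TRUE, prob = fate_prob)
      for (f in bg_fates) {
        g <- sample(config$gene_pool$gene, 1)
        zyg <- sample(c("heterozygous", "homozygous"), 1,
                      prob = c(0.85, 0.15))
        ann <- clean_annotations(config = cascade)
        v <- synth_causal_variant()
        if (f == "vaf") {
          ann$variant_fraction <- round(stats::runif(1, 0.01, 0.10), 3)
        } else if (f == "frequency") {
          ann$freq_gnomad <- round(stats::runif(1, 2 * cascade$maf_threshold,
                                                10 * cascade$maf_threshold),
                                   6)
        } else if (f == "clinvar") {
          ann$clinvar <- sample(c("benign", "likely_benign"), 1)
        } else if (f == "consequence") {
          if (stats::runif(1) < 0.5) {
            v <- synth_deep_intronic(cascade$splice_window + 1)
          } else {
            v <- synth_synonymous()
            ann$splice_pred_mt <- "no_effect"
            ann$splice_pred_hsf <- "no_effect"
          }
        }
        fate_name <- if (f == "survivor") "survivor" else paste0("fails_", f)
        # background survivors carry no evidence -> VUS, never reportable
        add_call(pid, g, v, zyg, "", ann, fate_name)
      }
    }

    patients[[pid]] <- data.frame(
      patient_id = pid, sex = sex,
      consanguineous = stats::runif(1) < config$consanguinity_rate,
      planted_solved = solved, planted_rule = rule,
      stringsAsFactors = FALSE)
  }

  empty_trio <- data.frame(patient_id = character(0), gene = character(0),
                           cdna = character(0), mother_gt = character(0),
                           father_gt = character(0), sex = character(0))
  list(
    calls = do.call(rbind, c(unname(calls), list(make.row.names = FALSE))),
    trios = if (length(trios)) {
      do.call(rbind, c(unname(trios), list(make.row.names = FALSE)))
    } else empty_trio,
    patients = do.call(rbind, c(unname(patients),
                                list(make.row.names = FALSE))),
    truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))))
}

#' Generate a schema-valid variant table from empirical distributions
#'
#' Samples zygosity, criteria strings, genes and consequence shapes from
#' the packaged cohort table's empirical distributions and synthesizes
#' matching HGVS descriptions; every row parses cleanly through the
#' HGVS-lite and criteria grammars.
#'
#' @param seed integer seed.
#' @param n_rows number of rows (>= 1).
#' @return a variant-record data.frame.
#' @export
generate_table2_like <- function(seed = 1, n_rows = 97) {
  if (!is.numeric(n_rows) || n_rows < 1) {
    ird_stop("n_rows must be at least 1")
  }
  tab2 <- load_fixture("table2")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  cons_emp <- compute_consequences(tab2)
  builders <- list(
    missense = synth_missense, nonsense = synth_nonsense,
    frameshift = synth_frameshift, splice_site = synth_splice,
    synonymous = synth_synonymous,
    delins = function() {
      pos <- sample(100:9000, 1)
      list(cdna = sprintf("c.%d_%ddelins%s", pos, pos + sample(1:8, 1),
                          paste(sample(BASES, 2, TRUE), collapse = "")),
           protein = "p.?")
    },
    deletion = function() {
      pos <- sample(100:9000, 1)
      list(cdna = sprintf("c.%d_%ddel", pos, pos + sample(1:8, 1)),
           protein = "p.?")
    },
    duplication = function() {
      pos <- sample(100:9000, 1)
      list(cdna = sprintf("c.%d_%ddup", pos, pos + sample(1:8, 1)),
           protein = "p.?")
    })
  shapes <- ifelse(cons_emp %in% names(builders), cons_emp, "missense")

  rows <- lapply(seq_len(n_rows), function(i) {
    # sample a fixture row so zygosity/criteria/gene/mode keep their
    # empirical joint distribution, then synthesize fresh HGVS text
    j <- sample(nrow(tab2), 1)
    v <- builders[[sample(shapes, 1)]]()
    data.frame(patient_id = sprintf("S%03d", sample(94, 1)),
               gene = tab2$gene[j], transcript = NA_character_,
               cdna = v$cdna, protein = v$protein,
               zygosity = tab2$zygosity[j],
               criteria = tab2$criteria[j],
               reported_class = tab2$reported_class[j],
               inheritance = tab2$inheritance[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
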