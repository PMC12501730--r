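# Independent oracles, coded by a different mechanism than the package
# implementation so the two can disagree.

# --- ACMG rule-table oracle -------------------------------------------------
# The combining table expressed as data: minimal requirement vectors over
# (very_strong, strong, moderate, supporting).  A combination fires when
# the observed counts dominate some requirement row elementwise.

oracle_p_rules <- rbind(
  c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1), c(1, 0, 0, 2),
  c(0, 2, 0, 0), c(0, 1, 3, 0), c(0, 1, 2, 2), c(0, 1, 1, 4))
oracle_lp_rules <- rbind(
  c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2),
  c(0, 0, 3, 0), c(0, 0, 2, 2), c(0, 0, 1, 4))

oracle_dominates <- function(counts, rules) {
  any(apply(rules, 1, function(r) all(counts >= r)))
}

# counts for a token vector, computed from the token spelling alone
oracle_counts <- function(tokens) {
  c(sum(grepl("^PVS", tokens)), sum(grepl("^PS", tokens)),
    sum(grepl("^PM", tokens)), sum(grepl("^PP", tokens)))
}

oracle_richards <- function(tokens, policy = "pathogenic_dominant") {
  pc <- oracle_counts(tokens)
  n_ba <- sum(tokens == "BA1")
  n_bs <- sum(grepl("^BS", tokens))
  n_bp <- sum(grepl("^BP", tokens))
  n_path <- sum(grepl("^P", tokens))
  n_ben <- length(tokens) - n_path

  path <- if (oracle_dominates(pc, oracle_p_rules)) "P"
          else if (oracle_dominates(pc, oracle_lp_rules)) "LP"
          else NA
  ben <- if (n_ba >= 1 || n_bs >= 2) "B"
         else if ((n_bs >= 1 && n_bp >= 1) || n_bp >= 2) "LB"
         else NA

  if (!is.na(path) && !is.na(ben)) {
    return(if (policy == "strict") "VUS" else path)
  }
  if (!is.na(path)) {
    if (policy == "strict" && n_ben > 0) return("VUS")
    return(path)
  }
  if (!is.na(ben)) {
    if (policy == "strict" && n_path > 0) return("VUS")
    return(ben)
  }
  "VUS"
}

# --- Mendelian trio oracle --------------------------------------------------
# Allele-enumeration: a parental genotype contributes a set of possible
# transmitted alleles; a configuration is Mendelian-consistent when some
# choice of transmitted alleles reconstructs the proband genotype.

oracle_alleles <- function(gt) {
  switch(gt,
    hom_ref = "r", het = c("r", "a"), hom_alt = "a",
    hemi_ref = "r", hemi_alt = "a", unavailable = c("r", "a", "?"))
}

oracle_trio <- function(zygosity, mode, mother_gt, father_gt) {
  m <- oracle_alleles(mother_gt)
  f <- oracle_alleles(father_gt)
  m_avail <- mother_gt != "unavailable"
  f_avail <- father_gt != "unavailable"

  if (zygosity == "homozygous" && mode == "AR") {
    # proband aa needs an 'a' from each parent
    bad <- (m_avail && !"a" %in% m) || (f_avail && !"a" %in% f)
    if (bad) return("inconsistent")
    if (!m_avail || !f_avail) return("uninformative")
    return("consistent")
  }
  if (zygosity == "heterozygous" && mode == "AD") {
    inheritable <- (m_avail && "a" %in% m) || (f_avail && "a" %in% f)
    if (inheritable) return("consistent")
    if (m_avail && f_avail) return("possible_de_novo")
    return("uninformative")
  }
  if (zygosity == "hemizygous" && mode == "XLR") {
    if (!m_avail) return("uninformative")
    if ("a" %in% m) return("consistent")
    return("possible_de_novo")
  }
  "uninformative"
}

# --- shared builders --------------------------------------------------------

make_call <- function(patient_id = "PT1", gene = "ABCA4",
                      cdna = "c.100A>G", protein = "p.Lys34Glu",
                      zygosity = "heterozygous", criteria = "PVS1PM2",
                      inheritance = "AR", variant_fraction = 0.5,
                      freq_gnomad = NA_real_, freq_1000g = NA_real_,
                      freq_esp = NA_real_, clinvar = "none",
                      splice_pred_mt = "unavailable",
                      splice_pred_hsf = "unavailable", ...) {
  data.frame(patient_id = patient_id, gene = gene, cdna = cdna,
             protein = protein, zygosity = zygosity, criteria = criteria,
             inheritance = inheritance,
             variant_fraction = variant_fraction,
             freq_gnomad = freq_gnomad, freq_1000g = freq_1000g,
             freq_esp = freq_esp, clinvar = clinvar,
             splice_pred_mt = splice_pred_mt,
             splice_pred_hsf = splice_pred_hsf,
             stringsAsFactors = FALSE, ...)
}

all_tokens <- evidence_codes()$token
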