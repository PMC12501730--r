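# Readers and writers for the tab-separated variant-table schema and a
# minimal VCF ingestion path.

CALLS_SCHEMA <- c("patient_id", "gene", "transcript", "cdna", "protein",
                  "zygosity", "criteria", "reported_class", "inheritance",
                  "novel", "dann")

#' Read a variant table (TSV)
#'
#' Reads the documented tab-separated schema: one header row, columns
#' `patient_id, gene, transcript, cdna, protein, zygosity, criteria,
#' reported_class, inheritance, novel, dann` (plus any annotated-call
#' columns such as `variant_fraction`, `freq_gnomad`, ...).  `#` lines
#' are comments.  Missing mandatory columns are an error naming them;
#' unknown extra columns are preserved with a warning.  Zygosity is
#' matched case-insensitively against
#' homozygous/heterozygous/hemizygous; `dann` values that are not
#' numbers (e.g. `N/A`) become NA — the score is annotation only.
#'
#' @param path TSV file path (UTF-8).
#' @param mandatory columns that must be present.
#' @return a data.frame, one row per patient-variant pair.
#' @export
read_calls_tsv <- function(path,
                           mandatory = c("patient_id", "gene", "cdna",
                                         "zygosity")) {
  if (!file.exists(path)) ird_stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    ird_stop("variant table missing mandatory column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  known <- c(CALLS_SCHEMA, "variant_fraction", "freq_gnomad", "freq_1000g",
             "freq_esp", "clinvar", "splice_pred_mt", "splice_pred_hsf",
             "consequence", "call_id")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("unknown column(s) preserved: ", paste(unknown, collapse = ", "))
  }
  df$zygosity <- normalize_zygosity(df$zygosity)
  if ("dann" %in% names(df)) {
    df$dann <- suppressWarnings(as.numeric(df$dann))
  }
  if ("novel" %in% names(df)) {
    df$novel <- ifelse(is_blank(df$novel), NA,
                       tolower(df$novel) %in% c("true", "t", "1", "yes"))
  }
  for (col in intersect(c("variant_fraction", "freq_gnomad", "freq_1000g",
                          "freq_esp"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}

#' Write a variant table (TSV)
#'
#' UTF-8, LF line endings, tab-separated; `write_calls_tsv()` then
#' [read_calls_tsv()] is the identity on schema columns.
#'
#' @param records data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- records
  if ("novel" %in% names(out)) {
    out$novel <- ifelse(is.na(out$novel), "",
                        ifelse(out$novel, "TRUE", "FALSE"))
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotated calls from a minimal VCF
#'
#' Ingests a VCF 4.x whose annotations live in the INFO keys `GNOMAD_AF`,
#' `KG_AF`, `ESP_AF`, `CLNSIG`, `CSQTYPE` (consequence), `GENE`, `CDNA`,
#' `PROTEIN`, `CRITERIA`, `SPLICE_MT`, `SPLICE_HSF` and the FORMAT field
#' `VAF` of the single sample.  Absent keys yield absent fields;
#' multi-allelic sites are split into one call per alternate allele
#' (per-allele `Number=A` INFO values are split positionally).
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param patient_id patient identifier to stamp on the calls (defaults
#'   to the sample name in the VCF, or "sample1").
#' @return an annotated-call data.frame suitable for [run_cascade()].
#' @export
read_vcf_minimal <- function(path, patient_id = NULL) {
  if (!file.exists(path)) ird_stop("file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) ird_stop("malformed VCF '", path, "': ",
                                 conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(patient_id = character(0), gene = character(0),
                      cdna = character(0), protein = character(0),
                      zygosity = character(0), criteria = character(0),
                      variant_fraction = numeric(0),
                      freq_gnomad = numeric(0), freq_1000g = numeric(0),
                      freq_esp = numeric(0), clinvar = character(0),
                      splice_pred_mt = character(0),
                      splice_pred_hsf = character(0)))
  }
  info_get <- function(key) {
    v <- tryCatch(vcfR::extract.info(vcf, element = key),
                  error = function(e) rep(NA_character_, nrow(fix)))
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  sample_names <- colnames(vcf@gt)[-1]
  if (is.null(patient_id)) {
    patient_id <- if (length(sample_names)) sample_names[1] else "sample1"
  }
  vaf <- if (length(sample_names)) {
    v <- tryCatch(vcfR::extract.gt(vcf, element = "VAF", as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(v)) rep(NA_real_, nrow(fix)) else as.numeric(v[, 1])
  } else {
    rep(NA_real_, nrow(fix))
  }
  gt <- if (length(sample_names)) {
    g <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                  error = function(e) NULL)
    if (is.null(g)) rep(NA_character_, nrow(fix)) else as.character(g[, 1])
  } else {
    rep(NA_character_, nrow(fix))
  }

  gnomad <- info_get("GNOMAD_AF"); kg <- info_get("KG_AF")
  esp <- info_get("ESP_AF"); clnsig <- info_get("CLNSIG")
  csq <- info_get("CSQTYPE"); gene <- info_get("GENE")
  cdna <- info_get("CDNA"); protein <- info_get("PROTEIN")
  criteria <- info_get("CRITERIA")
  smt <- info_get("SPLICE_MT"); shsf <- info_get("SPLICE_HSF")

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    pick <- function(x, j) {
      if (is.na(x[i])) return(NA_character_)
      parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
      if (length(parts) == n_alt) parts[j] else parts[1]
    }
    for (j in seq_len(n_alt)) {
      zyg <- if (is.na(gt[i])) "heterozygous" else {
        a <- strsplit(gt[i], "[/|]")[[1]]
        if (length(a) == 1) "hemizygous"
        else if (all(a == a[1]) && a[1] != "0") "homozygous"
        else "heterozygous"
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patient_id,
        gene = pick(gene, j),
        cdna = pick(cdna, j),
        protein = pick(protein, j),
        zygosity = zyg,
        criteria = pick(criteria, j),
        variant_fraction = vaf[i],
        freq_gnomad = suppressWarnings(as.numeric(pick(gnomad, j))),
        freq_1000g = suppressWarnings(as.numeric(pick(kg, j))),
        freq_esp = suppressWarnings(as.numeric(pick(esp, j))),
        clinvar = pick(clnsig, j),
        splice_pred_mt = pick(smt, j),
        splice_pred_hsf = pick(shsf, j),
        consequence = pick(csq, j),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a cascade configuration from YAML
#'
#' Accepts a YAML mapping with any subset of the [cascade_config()] keys;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `cascade_config`.
#' @export
read_cascade_config <- function(path) {
  if (!file.exists(path)) ird_stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  allowed <- c("vaf_min", "vaf_max", "maf_threshold", "splice_window",
               "synonymous_rescue", "missing_frequency_passes")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) {
    ird_stop("unknown cascade configuration key(s): ",
             paste(bad, collapse = ", "))
  }
  do.call(cascade_config, y)
}
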