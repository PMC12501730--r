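# Packaged cohort fixtures: the demographic table, the 97-row reported
# variant table and the 28-row novel-variant list of a published
# 94-patient inherited retinal dystrophy panel cohort, transcribed into
# plain TSV.  Integrity (row counts + checksums) is verified on load so
# transcription drift cannot pass silently.

FIXTURE_FILES <- c(
  table1 = "ird_table1_demographics.tsv",
  table2 = "ird_table2_variants.tsv",
  table3 = "ird_table3_novel.tsv")

FIXTURE_ROWS <- c(table1 = 9L, table2 = 97L, table3 = 28L)

# md5 of the fixture content after normalizing line endings to LF;
# recorded when the transcription was frozen.
FIXTURE_MD5 <- c(
  table1 = "35256ea2d1e80820629aad21b06e7ff5",
  table2 = "4848987c484d10c3a7f9735784ad78ad",
  table3 = "a6f28793e0b0cdd34523933bf5330c57")

# Internal: checksum of a text file with line endings canonicalized.
text_md5 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tmp <- tempfile()
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Path to a packaged fixture file
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return the installed file path.
#' @export
fixture_path <- function(name) {
  if (!name %in% names(FIXTURE_FILES)) {
    ird_stop("unknown fixture '", name,
             "'; expected table1, table2 or table3")
  }
  path <- system.file("extdata", FIXTURE_FILES[[name]],
                      package = "irdtriage", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (package loaded but not installed)
    path <- file.path("inst", "extdata", FIXTURE_FILES[[name]])
  }
  if (!file.exists(path)) ird_stop("fixture file missing: ", name)
  path
}

#' Load a packaged cohort fixture
#'
#' `"table1"` is the demographic/clinical subgroup summary (9 rows: eight
#' clinical subtypes plus the total line; subgroup sizes sum to the
#' 94-patient cohort), `"table2"` the 97 reported patient-variant pairs
#' and `"table3"` the 28 novel variants.  Each table is schema-validated
#' and integrity-checked (row count and checksum) on load.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @param check_integrity verify row counts and checksums (default TRUE).
#' @return a data.frame.
#' @examples
#' nrow(load_fixture("table2"))  # 97
#' @export
load_fixture <- function(name, check_integrity = TRUE) {
  path <- fixture_path(name)
  if (check_integrity) {
    md5 <- text_md5(path)
    if (!identical(md5, FIXTURE_MD5[[name]])) {
      ird_stop("fixture '", name, "' failed its checksum (", md5,
               " != ", FIXTURE_MD5[[name]],
               "); the packaged transcription has drifted")
    }
  }
  df <- switch(name,
    table1 = utils::read.delim(path, sep = "\t", header = TRUE,
                               comment.char = "#", quote = "",
                               fileEncoding = "UTF-8",
                               stringsAsFactors = FALSE),
    table2 = read_calls_tsv(path),
    table3 = {
      d <- utils::read.delim(path, sep = "\t", header = TRUE,
                             comment.char = "#", quote = "",
                             colClasses = "character",
                             fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE)
      d$zygosity <- normalize_zygosity(d$zygosity)
      d
    })
  if (check_integrity) {
    if (nrow(df) != FIXTURE_ROWS[[name]]) {
      ird_stop("fixture '", name, "' has ", nrow(df), " rows; expected ",
               FIXTURE_ROWS[[name]])
    }
    if (name == "table1") {
      subgroup <- df[df$group != "Total", ]
      if (sum(subgroup$n) != 94L) {
        ird_stop("fixture 'table1' subgroup sizes do not sum to 94")
      }
    }
    if (name == "table2") {
      for (s in df$criteria) parse_criteria_string(s)
    }
  }
  df
}
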