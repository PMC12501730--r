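#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used throughout the
#' cohort summaries (2.5 -> 3, not 2 as with [base::round()]'s
#' round-half-to-even).  A tiny epsilon absorbs binary representation
#' error so that values printed as .5 at `digits` decimals round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.675), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Normalize HGVS typography
#'
#' Published tables frequently typeset the intronic-offset minus sign as an
#' en dash, em dash or unicode hyphen, and occasionally carry stray
#' (including non-breaking) spaces inside a description.  This maps all
#' dash look-alikes to the ASCII hyphen and strips whitespace so that the
#' parsers see canonical text.
#'
#' @param x character vector of HGVS descriptions.
#' @return character vector, normalized.
#' @examples
#' normalize_hgvs("c.12067–2A>G")  # en dash -> "c.12067-2A>G"
#' @export
normalize_hgvs <- function(x) {
  x <- gsub("[‐‑‒–—―−]", "-", x)
  x <- gsub("[ \\s]+", "", x, perl = TRUE)
  x
}

# Internal: stop with a consistent condition class so callers/tests can
# distinguish validation rejections from programming errors.
ird_stop <- function(..., class = "irdtriage_error") {
  stop(errorCondition(paste0(...), class = c(class, "irdtriage_error")))
}

# Internal: TRUE for NA or "" fields coming off a TSV.
is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

# Internal: canonical zygosity vocabulary, case-insensitive on input.
normalize_zygosity <- function(x) {
  z <- tolower(trimws(x))
  ok <- z %in% c("homozygous", "heterozygous", "hemizygous")
  if (!all(ok)) {
    ird_stop("invalid zygosity value(s): ",
             paste(unique(x[!ok]), collapse = ", "))
  }
  z
}

# Internal: "AD, AR" -> c("AD","AR"); validates the closed vocabulary.
parse_inheritance <- function(x) {
  lapply(x, function(s) {
    if (is_blank(s)) return(character(0))
    modes <- toupper(trimws(strsplit(s, ",")[[1]]))
    bad <- setdiff(modes, c("AD", "AR", "XLR"))
    if (length(bad)) {
      ird_stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "))
    }
    modes
  })
}
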