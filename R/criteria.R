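# ACMG/AMP evidence-code vocabulary and the criteria-string grammar.
#
# Panel reports print the applied evidence codes as one concatenated
# string ("PVS1PM2PS4PP5"); this module parses and formats those strings
# against the closed 28-token vocabulary.

#' The ACMG/AMP evidence-code table
#'
#' The 28 valid evidence tokens with their category (pathogenic or
#' benign), strength (stand-alone, very strong, strong, moderate,
#' supporting) and within-group index.  The token uniquely determines
#' every other column.
#'
#' @return a data.frame with columns `token`, `category`, `strength`,
#'   `index`, in canonical order (pathogenic before benign, descending
#'   strength, ascending index).
#' @export
evidence_codes <- function() {
  codes <- rbind(
    data.frame(token = "PVS1", category = "pathogenic",
               strength = "very_strong", index = 1L),
    data.frame(token = paste0("PS", 1:4), category = "pathogenic",
               strength = "strong", index = 1:4),
    data.frame(token = paste0("PM", 1:6), category = "pathogenic",
               strength = "moderate", index = 1:6),
    data.frame(token = paste0("PP", 1:5), category = "pathogenic",
               strength = "supporting", index = 1:5),
    data.frame(token = "BA1", category = "benign",
               strength = "stand_alone", index = 1L),
    data.frame(token = paste0("BS", 1:4), category = "benign",
               strength = "strong", index = 1:4),
    data.frame(token = paste0("BP", 1:7), category = "benign",
               strength = "supporting", index = 1:7))
  codes
}

# cached lookup
.evidence_table <- evidence_codes()

#' Parse a concatenated ACMG criteria string
#'
#' Consumes the string greedily, token by token, against the 28-token
#' vocabulary; any unconsumed residue is an error naming the offending
#' text.  Duplicated tokens collapse to one occurrence with a warning.
#' The empty string is a valid empty set.
#'
#' @param text a single criteria string, e.g. `"PVS1PM2PS4PP5"`.
#' @return a `criteria_set`: a character vector of unique tokens in
#'   canonical order.
#' @examples
#' parse_criteria_string("PVS1PM2PS4PP5")
#' parse_criteria_string("")
#' @export
parse_criteria_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text)) text <- ""
  s <- gsub("\\s+", "", text)
  tokens <- character(0)
  token_pat <- "^(PVS1|PS[1-4]|PM[1-6]|PP[1-5]|BA1|BS[1-4]|BP[1-7])"
  while (nzchar(s)) {
    m <- regmatches(s, regexpr(token_pat, s))
    if (length(m) == 0) {
      ird_stop("invalid ACMG criteria token at '", s, "'")
    }
    tokens <- c(tokens, m)
    s <- substring(s, nchar(m) + 1)
  }
  if (anyDuplicated(tokens)) {
    warning("duplicated ACMG token(s) collapsed: ",
            paste(unique(tokens[duplicated(tokens)]), collapse = ", "))
    tokens <- unique(tokens)
  }
  criteria_set(tokens)
}

#' Construct a criteria set from tokens
#'
#' @param tokens character vector of evidence tokens.
#' @return a `criteria_set` in canonical order.
#' @export
criteria_set <- function(tokens = character(0)) {
  tokens <- unique(as.character(tokens))
  bad <- setdiff(tokens, .evidence_table$token)
  if (length(bad)) {
    ird_stop("unknown ACMG token(s): ", paste(bad, collapse = ", "))
  }
  ord <- match(tokens, .evidence_table$token)
  structure(tokens[order(ord)], class = "criteria_set")
}

#' Format a criteria set as its canonical string
#'
#' The inverse of [parse_criteria_string()]: pathogenic codes before
#' benign, descending strength, ascending index, no separators, so
#' `parse_criteria_string(format_criteria(x))` is the identity.
#'
#' @param criteria a `criteria_set` (or character vector of tokens).
#' @return a single string.
#' @examples
#' format_criteria(criteria_set(c("PM2", "PVS1")))  # "PVS1PM2"
#' @export
format_criteria <- function(criteria) {
  if (!inherits(criteria, "criteria_set")) criteria <- criteria_set(criteria)
  paste(unclass(criteria), collapse = "")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("<criteria_set>", if (length(x)) format_criteria(x) else "(empty)", "\n")
  invisible(x)
}

# Internal: counts of codes per (category, strength) for the combiner.
criteria_counts <- function(criteria) {
  if (!inherits(criteria, "criteria_set")) criteria <- criteria_set(criteria)
  tab <- .evidence_table[match(unclass(criteria), .evidence_table$token), ]
  list(
    pvs = sum(tab$strength == "very_strong"),
    ps  = sum(tab$category == "pathogenic" & tab$strength == "strong"),
    pm  = sum(tab$strength == "moderate"),
    pp  = sum(tab$category == "pathogenic" & tab$strength == "supporting"),
    ba  = sum(tab$strength == "stand_alone"),
    bs  = sum(tab$category == "benign" & tab$strength == "strong"),
    bp  = sum(tab$category == "benign" & tab$strength == "supporting"),
    n_pathogenic = sum(tab$category == "pathogenic"),
    n_benign = sum(tab$category == "benign"))
}
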