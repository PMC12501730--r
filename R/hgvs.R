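# HGVS-lite parsing: coding-DNA ("c.") and protein ("p.") change
# descriptions as they appear in diagnostic panel reports, plus the
# consequence-type classification used for triage and cohort statistics.
#
# Deliberately a subset of full HGVS: substitutions, deletions,
# duplications, insertions and delins over exonic anchors with optional
# intronic offsets.  No inversions, genomic/mitochondrial coordinates or
# allele lists, and no reference-sequence validation.

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' The closed consequence-type vocabulary
#'
#' Every classified variant carries exactly one of these values.
#'
#' @return character vector of the valid consequence types.
#' @export
consequence_types <- function() {
  c("missense", "nonsense", "frameshift", "splice_site", "delins",
    "deletion", "duplication", "inframe_indel", "synonymous",
    "intronic_other", "unknown")
}

# Internal: parse one "123", "123-45" or "123+45" coding position into
# (anchor, offset).
parse_cpos <- function(tok, context) {
  m <- regmatches(tok, regexec("^(\\d+)([+-]\\d+)?$", tok))[[1]]
  if (length(m) == 0) {
    ird_stop("unparseable coding position '", tok, "' in '", context, "'")
  }
  list(anchor = as.integer(m[2]),
       offset = if (nzchar(m[3])) as.integer(m[3]) else 0L)
}

#' Parse a coding-DNA change description
#'
#' Accepts the "c." descriptions found in panel reports: substitutions
#' (`c.3244G>T`), deletions with or without stated bases (`c.269del`,
#' `c.871delT`), duplications (`c.9_10dupGG`), insertions (`c.9_10insAC`)
#' and deletion-insertions (`c.802-8_810delinsGC`).  Unicode dashes and
#' stray spaces are normalized before parsing, so table-typeset strings
#' such as `c.12067–2A>G` (en dash) parse cleanly.
#'
#' @param text a single HGVS coding-DNA description beginning with `c.`.
#' @return an object of class `cdna_change`: a list with `raw` (the input),
#'   `kind` (one of substitution/deletion/duplication/delins/insertion),
#'   `start_anchor`/`start_offset` and `end_anchor`/`end_offset` (1-based
#'   coding position plus signed intronic offset, 0 = exonic), and
#'   `ref`/`alt` nucleotide strings (may be empty).
#' @examples
#' parse_cdna("c.3244G>T")
#' parse_cdna("c.802-8_810delinsGC")
#' @seealso [parse_protein()], [classify_consequence()]
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- text
  s <- normalize_hgvs(text)
  if (!startsWith(s, "c.")) {
    ird_stop("unsupported prefix in '", raw, "': expected 'c.'")
  }
  body <- substring(s, 3)

  m <- regmatches(body, regexec(
    "^(\\d+[+-]?\\d*)(?:_(\\d+[+-]?\\d*))?(.*)$", body))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) {
    ird_stop("unparseable position syntax in '", raw, "'")
  }
  start <- parse_cpos(m[2], raw)
  end <- if (nzchar(m[3])) parse_cpos(m[3], raw) else start
  edit <- m[4]

  if (start$anchor > end$anchor ||
      (start$anchor == end$anchor && start$offset > end$offset)) {
    ird_stop("start position follows end position in '", raw, "'")
  }

  check_bases <- function(b, what) {
    if (nzchar(b) && grepl("[^ACGT]", b)) {
      ird_stop("non-ACGT ", what, " bases '", b, "' in '", raw, "'")
    }
    b
  }

  if (grepl("^[ACGT]>[ACGT]$", edit)) {
    kind <- "substitution"
    ref <- substring(edit, 1, 1)
    alt <- substring(edit, 3, 3)
    if (!identical(start, end)) {
      ird_stop("substitution must be a single position in '", raw, "'")
    }
  } else if (grepl("^delins", edit)) {
    kind <- "delins"
    ref <- ""
    alt <- check_bases(substring(edit, 7), "inserted")
    if (!nzchar(alt)) ird_stop("delins without inserted bases in '", raw, "'")
  } else if (grepl("^del", edit)) {
    kind <- "deletion"
    ref <- check_bases(substring(edit, 4), "deleted")
    alt <- ""
  } else if (grepl("^dup", edit)) {
    kind <- "duplication"
    ref <- check_bases(substring(edit, 4), "duplicated")
    alt <- ""
  } else if (grepl("^ins", edit)) {
    kind <- "insertion"
    ref <- ""
    alt <- check_bases(substring(edit, 4), "inserted")
    if (!nzchar(alt)) ird_stop("insertion without bases in '", raw, "'")
  } else {
    ird_stop("unrecognized edit '", edit, "' in '", raw, "'")
  }

  structure(
    list(raw = raw, kind = kind,
         start_anchor = start$anchor, start_offset = start$offset,
         end_anchor = end$anchor, end_offset = end$offset,
         ref = ref, alt = alt),
    class = "cdna_change")
}

#' Format a parsed coding-DNA change back to HGVS text
#'
#' Inverse of [parse_cdna()] up to dash/whitespace normalization:
#' `format_cdna(parse_cdna(x)) == normalize_hgvs(x)`.
#'
#' @param x a `cdna_change` object.
#' @return a single HGVS string.
#' @export
format_cdna <- function(x) {
  stopifnot(inherits(x, "cdna_change"))
  pos1 <- paste0(x$start_anchor,
                 if (x$start_offset != 0) sprintf("%+d", x$start_offset))
  pos2 <- paste0(x$end_anchor,
                 if (x$end_offset != 0) sprintf("%+d", x$end_offset))
  span <- if (identical(pos1, pos2)) pos1 else paste0(pos1, "_", pos2)
  edit <- switch(x$kind,
    substitution = paste0(x$ref, ">", x$alt),
    deletion     = paste0("del", x$ref),
    duplication  = paste0("dup", x$ref),
    delins       = paste0("delins", x$alt),
    insertion    = paste0("ins", x$alt))
  paste0("c.", span, edit)
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change>", format_cdna(x), "(", x$kind, ")\n")
  invisible(x)
}

#' Parse a protein change description
#'
#' Accepts the "p." descriptions found in panel reports, optionally wrapped
#' in parentheses, with stray internal spaces tolerated (`p.Arg 4192Gly`).
#' `*` and `Ter` are treated as the same stop symbol, so `fs*41` and
#' `fsTer41` are the same frameshift syntax.
#'
#' @param text a single protein change description.
#' @return an object of class `protein_change`: a list with `raw`, `kind`
#'   (substitution/nonsense/frameshift/synonymous/unknown), `position`
#'   (residue number or NA), `ref`/`alt` (3-letter residue code, `"*"` for
#'   a stop, or NA) and `fs_stop_distance` (codons to the new stop in a
#'   frameshift, or NA).
#' @examples
#' parse_protein("(p.Glu4Glyfs*41)")
#' parse_protein("p.?")
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- text
  s <- normalize_hgvs(text)
  s <- gsub("^\\(|\\)$", "", s)
  if (!startsWith(s, "p.")) {
    ird_stop("missing 'p.' prefix in '", raw, "'")
  }
  body <- substring(s, 3)

  out <- list(raw = raw, kind = "unknown", position = NA_integer_,
              ref = NA_character_, alt = NA_character_,
              fs_stop_distance = NA_integer_)

  aa <- paste(AA3, collapse = "|")
  stop_pat <- "\\*|Ter"

  if (body == "?") {
    # kind stays "unknown"
  } else if (grepl(paste0("^(", aa, ")(\\d+)(", aa, "|", stop_pat,
                          ")?fs((", stop_pat, ")(\\d+))?$"), body)) {
    m <- regmatches(body, regexec(paste0(
      "^(", aa, ")(\\d+)(", aa, "|", stop_pat,
      ")?fs(?:(?:", stop_pat, ")(\\d+))?$"), body, perl = TRUE))[[1]]
    out$kind <- "frameshift"
    out$ref <- m[2]
    out$position <- as.integer(m[3])
    out$alt <- if (nzchar(m[4])) sub("^Ter$", "*", m[4]) else NA_character_
    out$fs_stop_distance <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  } else if (grepl(paste0("^(", aa, ")(\\d+)(", stop_pat, ")$"), body)) {
    m <- regmatches(body, regexec(paste0(
      "^(", aa, ")(\\d+)(", stop_pat, ")$"), body))[[1]]
    out$kind <- "nonsense"
    out$ref <- m[2]
    out$position <- as.integer(m[3])
    out$alt <- "*"
  } else if (grepl(paste0("^(", aa, ")(\\d+)(", aa, ")$"), body)) {
    m <- regmatches(body, regexec(paste0(
      "^(", aa, ")(\\d+)(", aa, ")$"), body))[[1]]
    out$ref <- m[2]
    out$position <- as.integer(m[3])
    out$alt <- m[4]
    out$kind <- if (identical(out$ref, out$alt)) "synonymous" else "substitution"
  } else {
    ird_stop("unrecognizable protein change syntax in '", raw, "'")
  }
  structure(out, class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change>", x$raw, "(", x$kind, ")\n")
  invisible(x)
}

#' Classify the consequence type of a variant
#'
#' Protein-level evidence takes precedence over the DNA edit kind: a
#' frameshift, stop-gain, residue substitution or synonymous protein
#' change decides the class outright (so a DNA delins producing `p.Ile582*`
#' counts as nonsense).  Only when the protein consequence is unknown
#' (`p.?`) does the DNA description decide: intronic substitutions within
#' `splice_window` of the nearest exon end are splice-site; deeper intronic
#' substitutions are `intronic_other`; non-substitution edits keep their
#' DNA edit kind (an intronic deletion stays `deletion`, never
#' `splice_site`); insertions are reported as `inframe_indel`; an exonic
#' substitution with unknown protein effect is `unknown`.
#'
#' @param cdna a `cdna_change` (or a string passed to [parse_cdna()]).
#' @param protein a `protein_change` (or a string passed to
#'   [parse_protein()]); `NULL`/`NA`/empty counts as unknown.
#' @param splice_window half-width, in bases, of the exon-intron junction
#'   window inside which an intronic substitution is called splice-site
#'   (default 20, the panel's junction coverage).
#' @return a single consequence type (see [consequence_types()]).
#' @examples
#' classify_consequence("c.12067-2A>G", "p.?")            # splice_site
#' classify_consequence("c.1744_1751delinsT", "p.Ile582*") # nonsense
#' @export
classify_consequence <- function(cdna, protein, splice_window = 20) {
  if (is.character(cdna)) cdna <- parse_cdna(cdna)
  stopifnot(inherits(cdna, "cdna_change"))
  if (is.null(protein) || (is.atomic(protein) && length(protein) == 1 &&
                           (is.na(protein) || !nzchar(trimws(protein))))) {
    protein <- parse_protein("p.?")
  } else if (is.character(protein)) {
    protein <- parse_protein(protein)
  }
  stopifnot(inherits(protein, "protein_change"))

  decided <- switch(protein$kind,
    frameshift = "frameshift",
    nonsense = "nonsense",
    substitution = "missense",
    synonymous = "synonymous",
    NULL)
  if (!is.null(decided)) return(decided)

  # protein consequence unknown: fall back to the DNA description
  if (cdna$kind == "substitution") {
    off <- cdna$start_offset
    if (off != 0 && abs(off) <= splice_window) return("splice_site")
    if (off != 0) return("intronic_other")
    return("unknown")
  }
  switch(cdna$kind,
    delins = "delins",
    deletion = "deletion",
    duplication = "duplication",
    insertion = "inframe_indel")
}
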