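# Trio segregation consistency: does the genotype configuration observed
# in the proband's parents match Mendelian transmission of the variant
# under its inheritance mode?  Purely genotypic — consanguinity and
# sibling genotypes are annotation, never evidence.

TRIO_GT <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt",
             "unavailable")

# Internal: does this parental genotype carry at least one alternate
# allele?
carries_alt <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")

#' Check trio genotype consistency for one variant
#'
#' Verdicts by inheritance mode of the record:
#' \itemize{
#'   \item AR homozygous proband: consistent iff every available parent
#'     carries at least one alternate allele; inconsistent if an
#'     available parent is hom_ref.
#'   \item AD heterozygous proband: consistent if an available parent
#'     carries the variant; possible_de_novo if both parents are
#'     available and hom_ref.
#'   \item XLR hemizygous male proband: consistent if the mother is
#'     het/hom_alt; possible_de_novo if she is hom_ref; the father's
#'     genotype never decides.
#' }
#' Any relative required by the applicable rule being unavailable makes
#' the verdict uninformative, as does a zygosity/mode configuration with
#' no rule (e.g. a single heterozygous record in an AR-only gene, whose
#' phase a trio cannot resolve without the partner allele).
#'
#' @param zygosity the proband record's zygosity
#'   (homozygous/heterozygous/hemizygous).
#' @param inheritance_modes character vector drawn from AD, AR, XLR.
#' @param mother_gt,father_gt parental genotypes over
#'   \{hom_ref, het, hom_alt, hemi_ref, hemi_alt, unavailable\}.
#' @param proband_sex `"male"`, `"female"` or `"unknown"`.
#' @return a list with `verdict` (consistent / inconsistent /
#'   possible_de_novo / uninformative) and `explanation`.
#' @examples
#' check_trio_consistency("homozygous", "AR", "het", "het")
#' check_trio_consistency("heterozygous", "AD", "hom_ref", "hom_ref")
#' @export
check_trio_consistency <- function(zygosity, inheritance_modes,
                                   mother_gt = "unavailable",
                                   father_gt = "unavailable",
                                   proband_sex = "unknown") {
  zygosity <- normalize_zygosity(zygosity)
  if (is.character(inheritance_modes) && length(inheritance_modes) == 1 &&
      grepl(",", inheritance_modes)) {
    inheritance_modes <- parse_inheritance(inheritance_modes)[[1]]
  }
  inheritance_modes <- toupper(inheritance_modes)
  stopifnot(mother_gt %in% TRIO_GT, father_gt %in% TRIO_GT,
            proband_sex %in% c("male", "female", "unknown"))
  if (mother_gt %in% c("hemi_ref", "hemi_alt")) {
    ird_stop("a mother cannot carry a hemizygous genotype")
  }
  if (zygosity == "hemizygous" && proband_sex == "female") {
    ird_stop("hemizygous proband genotype incompatible with female sex")
  }

  verdict <- function(v, why) list(verdict = v, explanation = why)

  if (zygosity == "hemizygous" && "XLR" %in% inheritance_modes) {
    if (mother_gt == "unavailable") {
      return(verdict("uninformative", "maternal genotype unavailable"))
    }
    if (carries_alt(mother_gt)) {
      return(verdict("consistent", "X-linked variant present in mother"))
    }
    return(verdict("possible_de_novo",
                   "mother hom_ref; de novo or germline mosaic"))
  }
  if (zygosity == "homozygous" && "AR" %in% inheritance_modes) {
    gts <- c(mother = mother_gt, father = father_gt)
    avail <- gts != "unavailable"
    if (any(avail & !carries_alt(gts))) {
      return(verdict("inconsistent", paste(
        paste(names(gts)[avail & !carries_alt(gts)], collapse = " and "),
        "carries no alternate allele")))
    }
    if (!all(avail)) {
      return(verdict("uninformative",
                     "at least one parental genotype unavailable"))
    }
    return(verdict("consistent", "both parents carry the variant"))
  }
  if (zygosity == "heterozygous" && "AD" %in% inheritance_modes) {
    gts <- c(mother_gt, father_gt)
    avail <- gts != "unavailable"
    if (any(carries_alt(gts))) {
      return(verdict("consistent", "variant present in a parent"))
    }
    if (all(avail)) {
      return(verdict("possible_de_novo", "both parents hom_ref"))
    }
    return(verdict("uninformative",
                   "no carrier parent found and a genotype is unavailable"))
  }
  verdict("uninformative",
          "no segregation rule for this zygosity/mode configuration")
}

#' Batch segregation over a cohort
#'
#' Applies [check_trio_consistency()] to every record using a trio table
#' keyed by `patient_id`.  A trio row may optionally carry `gene` and
#' `cdna` columns naming the variant that was genotyped in the family;
#' when present, the trio is only applied to the matching record and all
#' other records of that patient are uninformative.  Records without a
#' trio are uninformative.
#'
#' @param records variant-record data.frame.
#' @param trios data.frame with `patient_id`, `mother_gt`, `father_gt`,
#'   optionally `sex`, `gene`, `cdna`.
#' @return `records` with `segregation` and `segregation_note` columns.
#' @export
batch_segregate <- function(records, trios) {
  stopifnot(is.data.frame(records), is.data.frame(trios))
  n <- nrow(records)
  records$segregation <- rep("uninformative", n)
  records$segregation_note <- rep("no trio genotyped for this patient", n)
  if (nrow(trios) == 0 || n == 0) return(records)
  variant_keyed <- all(c("gene", "cdna") %in% names(trios))
  for (i in seq_len(n)) {
    hit <- trios$patient_id == records$patient_id[i]
    if (variant_keyed) {
      hit <- hit & !is_blank(trios$gene) &
        trios$gene == records$gene[i] &
        normalize_hgvs(trios$cdna) == normalize_hgvs(records$cdna[i])
    }
    j <- which(hit)
    if (length(j) == 0) next
    j <- j[1]
    res <- check_trio_consistency(
      records$zygosity[i], records$inheritance[i],
      trios$mother_gt[j], trios$father_gt[j],
      if ("sex" %in% names(trios) && !is_blank(trios$sex[j]))
        trios$sex[j] else "unknown")
    records$segregation[i] <- res$verdict
    records$segregation_note[i] <- res$explanation
  }
  records
}
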