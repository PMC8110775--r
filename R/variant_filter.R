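# Somatic variant filtering cascade and hierarchical confidence tiers.
#
# The pipeline removes low-quality and non-somatic calls, keeps only
# protein-altering variants, drops common polymorphisms, and assigns each
# survivor a confidence tier (1 best) from a hierarchy of annotation rules.
# The historical "manual inspection" step is replaced by the deterministic
# tier output plus a complete audit log of removals.

# consequences counted as an obvious protein-coding change
PROTEIN_ALTERING <- c("missense", "nonsense", "stop_gain", "stop-gain",
                      "stop_loss", "stop-loss", "frameshift",
                      "inframe_indel", "in-frame_indel", "splicing",
                      "splice_site", "splice-site")

# loss-of-function consequences for the tumor-suppressor tier
LOF_CONSEQUENCES <- c("splicing", "splice_site", "splice-site",
                      "stop_gain", "stop-gain", "nonsense",
                      "stop_loss", "stop-loss", "frameshift")

#' Build an annotation resource for variant classification
#'
#' Bundles the lookups that drive the filtering cascade and the confidence
#' hierarchy: a catalog of confirmed somatic mutations (COSMIC-style), a
#' tumor-suppressor gene list, population allele frequencies, and a boolean
#' damaging prediction. All lookups are total over any variant universe:
#' a variant absent from `popfreq` has frequency 0 and one absent from
#' `damaging` is not damaging.
#'
#' @param cosmic data.frame with columns `gene`, `protein_pos`,
#'   `protein_change` (e.g. "R132H"); one row per confirmed somatic record.
#' @param tsg_genes character vector of tumor-suppressor gene symbols.
#' @param popfreq data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `frequency` (maximum frequency across population databases).
#' @param damaging data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `damaging` (logical in-silico prediction).
#' @return object of class `annotation_resource`.
#' @export
annotation_resource <- function(cosmic = data.frame(gene = character(),
                                                    protein_pos = integer(),
                                                    protein_change = character()),
                                tsg_genes = character(),
                                popfreq = NULL, damaging = NULL) {
  stopifnot(all(c("gene", "protein_pos", "protein_change") %in% names(cosmic)))
  pf <- new.env(parent = emptyenv())
  if (!is.null(popfreq) && nrow(popfreq)) {
    k <- variant_key(popfreq$chrom, popfreq$pos, popfreq$ref, popfreq$alt)
    for (i in seq_along(k)) assign(k[i], popfreq$frequency[i], envir = pf)
  }
  dm <- new.env(parent = emptyenv())
  if (!is.null(damaging) && nrow(damaging)) {
    k <- variant_key(damaging$chrom, damaging$pos, damaging$ref, damaging$alt)
    for (i in seq_along(k)) assign(k[i], isTRUE(damaging$damaging[i]), envir = dm)
  }
  structure(list(cosmic = cosmic, tsg_genes = unique(tsg_genes),
                 .popfreq = pf, .damaging = dm),
            class = "annotation_resource")
}

#' Load annotation resources from a directory of TSV files
#'
#' Expects `cosmic.tsv`, `tsg.txt` (one symbol per line), `popfreq.tsv`
#' and `damaging.tsv`; any missing file yields an empty lookup.
#'
#' @param dir directory path.
#' @return an [annotation_resource()].
#' @export
read_annotation_resources <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_tsv_table(p) else NULL
  }
  cosmic <- rd("cosmic.tsv")
  if (is.null(cosmic))
    cosmic <- data.frame(gene = character(), protein_pos = integer(),
                         protein_change = character())
  tsg_path <- file.path(dir, "tsg.txt")
  tsg <- if (file.exists(tsg_path)) readLines(tsg_path, warn = FALSE) else character()
  dmg <- rd("damaging.tsv")
  if (!is.null(dmg)) dmg$damaging <- as.logical(dmg$damaging)
  annotation_resource(cosmic = cosmic, tsg_genes = tsg[nzchar(tsg)],
                      popfreq = rd("popfreq.tsv"), damaging = dmg)
}

popfreq_lookup <- function(resource, keys) {
  vapply(keys, function(k) {
    v <- get0(k, envir = resource$.popfreq, ifnotfound = 0)
    if (isTRUE(v) || isFALSE(v)) 0 else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

damaging_lookup <- function(resource, keys) {
  vapply(keys, function(k)
    isTRUE(get0(k, envir = resource$.damaging, ifnotfound = FALSE)),
    logical(1), USE.NAMES = FALSE)
}

#' Apply the variant quality/somatic/polymorphism filtering cascade
#'
#' A call survives iff all of the following hold:
#' \itemize{
#'   \item tumor coverage >= 15 reads,
#'   \item tumor VAF >= 5\%,
#'   \item normal VAF < 1\% for SNVs and exactly 0 for indels,
#'   \item the consequence is an obvious protein-coding change,
#'   \item population frequency < 0.14\% (a frequency of exactly 0.14\%
#'     triggers removal).
#' }
#' Thresholds are stated as removal conditions; their complements are kept,
#' so depth exactly 15 and VAF exactly 5\% both survive.
#'
#' @param calls data.frame of variant calls with columns `patient_id`,
#'   `timepoint`, `gene`, `chrom`, `pos`, `ref`, `alt`, `variant_class`
#'   ("SNV"/"indel"), `consequence`, `tumor_depth`, `tumor_vaf`,
#'   `normal_vaf` (and optionally `protein_pos`, `protein_change`).
#' @param resource an [annotation_resource()].
#' @param min_depth,min_vaf,max_normal_snv,max_popfreq filter thresholds;
#'   defaults follow the published cascade.
#' @return list with `kept` (surviving rows), `verdicts` (one row per input
#'   call: logical pass per rule family and a `failed_rules` string).
#' @export
apply_variant_filters <- function(calls, resource,
                                  min_depth = 15, min_vaf = 0.05,
                                  max_normal_snv = 0.01,
                                  max_popfreq = 0.0014) {
  if (nrow(calls) == 0L)
    return(list(kept = calls,
                verdicts = data.frame(failed_rules = character())))
  if (any(calls$tumor_vaf < 0 | calls$tumor_vaf > 1, na.rm = TRUE) ||
      any(calls$normal_vaf < 0 | calls$normal_vaf > 1, na.rm = TRUE))
    stop_input("VAF outside [0,1]")
  is_indel <- calls$variant_class == "indel"
  ok_depth <- calls$tumor_depth >= min_depth
  ok_vaf <- calls$tumor_vaf >= min_vaf
  ok_normal <- ifelse(is_indel, calls$normal_vaf == 0,
                      calls$normal_vaf < max_normal_snv)
  ok_coding <- tolower(calls$consequence) %in% PROTEIN_ALTERING
  freq <- popfreq_lookup(resource,
                         variant_key(calls$chrom, calls$pos,
                                     calls$ref, calls$alt))
  ok_popfreq <- freq < max_popfreq
  fails <- cbind(coverage = !ok_depth, vaf = !ok_vaf, normal = !ok_normal,
                 coding = !ok_coding, popfreq = !ok_popfreq)
  failed_rules <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ","))
  verdicts <- data.frame(ok_depth = ok_depth, ok_vaf = ok_vaf,
                         ok_normal = ok_normal, ok_coding = ok_coding,
                         ok_popfreq = ok_popfreq,
                         failed_rules = failed_rules,
                         stringsAsFactors = FALSE)
  keep <- ok_depth & ok_vaf & ok_normal & ok_coding & ok_popfreq
  list(kept = calls[keep, , drop = FALSE], verdicts = verdicts)
}

#' Assign hierarchical confidence tiers to filtered variants
#'
#' Each surviving variant is assigned the first applicable rank:
#' \enumerate{
#'   \item exact match to a confirmed somatic record (same gene, protein
#'     position and amino-acid change);
#'   \item loss-of-function consequence (splicing, stop-gain, stop-loss,
#'     frameshift) in a tumor-suppressor gene;
#'   \item same gene and protein position as a confirmed somatic record;
#'   \item within three amino acids of a confirmed somatic record in the
#'     same gene AND predicted damaging in silico.
#' }
#' Variants matching none of the rules are `NA` ("unclassified"). Variants
#' without a protein position skip the position-based rules (1, 3, 4).
#'
#' @param calls data.frame of filtered calls (see [apply_variant_filters()]).
#' @param resource an [annotation_resource()].
#' @param max_aa_distance near-position window for tier 4 (default 3).
#' @return integer vector of tiers (1-4 or NA), one per row of `calls`.
#' @export
classify_confidence <- function(calls, resource, max_aa_distance = 3) {
  n <- nrow(calls)
  if (n == 0L) return(integer(0))
  cos <- resource$cosmic
  cos_exact <- paste(cos$gene, cos$protein_change, sep = "|")
  cos_pos <- paste(cos$gene, cos$protein_pos, sep = "|")
  has_pos <- !is.na(calls$protein_pos %||% rep(NA, n))
  pchange <- calls$protein_change %||% rep(NA_character_, n)
  keys <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  dmg <- damaging_lookup(resource, keys)
  lof <- tolower(calls$consequence) %in% LOF_CONSEQUENCES
  tier <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    g <- calls$gene[i]
    if (has_pos[i] && !is.na(pchange[i]) &&
        paste(g, pchange[i], sep = "|") %in% cos_exact) {
      tier[i] <- 1L
    } else if (lof[i] && g %in% resource$tsg_genes) {
      tier[i] <- 2L
    } else if (has_pos[i] &&
               paste(g, calls$protein_pos[i], sep = "|") %in% cos_pos) {
      tier[i] <- 3L
    } else if (has_pos[i] && dmg[i]) {
      near <- cos$gene == g &
        abs(cos$protein_pos - calls$protein_pos[i]) <= max_aa_distance
      if (any(near)) tier[i] <- 4L
    }
  }
  tier
}

#' Run the full variant pipeline: deduplicate, filter, classify
#'
#' Duplicated rows (same patient, timepoint and variant allele) are
#' collapsed to one before filtering. The output driver table contains
#' only variants that survive all filters and receive a tier in 1-4;
#' the audit log records every removal with the rule(s) that caused it.
#'
#' @param calls data.frame of variant calls.
#' @param resource an [annotation_resource()].
#' @param ... passed to [apply_variant_filters()].
#' @return list with `drivers` (surviving calls + `tier` column),
#'   `audit` (character log lines), and `class_counts` (drivers by
#'   variant_class).
#' @export
run_variant_pipeline <- function(calls, resource, ...) {
  audit <- character()
  if (nrow(calls)) {
    key <- paste(calls$patient_id, calls$timepoint,
                 variant_key(calls$chrom, calls$pos, calls$ref, calls$alt),
                 sep = "|")
    dup <- duplicated(key)
    if (any(dup))
      audit <- c(audit, sprintf("deduplicated %d repeated call row(s)",
                                sum(dup)))
    calls <- calls[!dup, , drop = FALSE]
  }
  flt <- apply_variant_filters(calls, resource, ...)
  removed <- flt$verdicts$failed_rules
  if (length(removed)) {
    idx <- which(nzchar(removed))
    audit <- c(audit, sprintf("removed %s:%s %s %s (%s)",
                              calls$patient_id[idx], calls$timepoint[idx],
                              calls$gene[idx],
                              variant_key(calls$chrom, calls$pos,
                                          calls$ref, calls$alt)[idx],
                              removed[idx]))
  }
  kept <- flt$kept
  tier <- classify_confidence(kept, resource)
  uncls <- is.na(tier)
  if (any(uncls))
    audit <- c(audit, sprintf("unclassified (no tier): %s %s",
                              kept$gene[uncls],
                              variant_key(kept$chrom, kept$pos, kept$ref,
                                          kept$alt)[uncls]))
  drivers <- kept[!uncls, , drop = FALSE]
  drivers$tier <- tier[!uncls]
  class_counts <- table(factor(drivers$variant_class,
                               levels = c("SNV", "indel")))
  list(drivers = drivers, audit = audit,
       class_counts = as.integer(class_counts))
}
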