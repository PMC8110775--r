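# Longitudinal VAF analytics: cancer cell fractions, relative mutation
# timing, IDH-mutation clearance, relapse acquisition/selection events,
# pathway grouping, and single-cell clone-independence testing.

#' Estimate cancer cell fraction from variant allele frequency
#'
#' Under the diploid, copy-neutral, heterozygous model half the alleles in
#' a mutant cell carry the variant, so CCF = 2 x VAF, clipped at 1. This
#' ignores copy-number events and loss of heterozygosity; it is the
#' generator's ground-truth model and the pipeline's working assumption.
#'
#' @param vaf numeric vector of tumor VAFs in \[0,1\].
#' @return CCF vector in \[0,1\].
#' @export
compute_ccf <- function(vaf) {
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE))
    stop_input("VAF outside [0,1]")
  pmin(1, 2 * vaf)
}

#' Infer relative timing of co-occurring mutations vs the IDH mutation
#'
#' For one patient's baseline driver table, each non-IDH gene's mean CCF is
#' compared with the IDH1/2 CCF: `later` if below IDH - tau (subclonal,
#' acquired after the IDH event), `earlier` if above IDH + tau, otherwise
#' `co-occurring`.
#'
#' @param drivers baseline driver table for one patient (columns `gene`,
#'   `tumor_vaf`).
#' @param tau CCF tolerance for the tie band (default 0.1).
#' @return data.frame with `gene`, `mean_ccf`, `idh_ccf`, `timing`.
#' @export
infer_relative_timing <- function(drivers, tau = 0.1) {
  idh <- drivers$gene %in% c("IDH1", "IDH2")
  if (!any(idh))
    stop_input("no IDH1/2 mutation found; the cohort is IDH-mutant by design")
  ccf <- compute_ccf(drivers$tumor_vaf)
  idh_ccf <- mean(ccf[idh])
  other <- drivers[!idh, , drop = FALSE]
  if (nrow(other) == 0L)
    return(data.frame(gene = character(), mean_ccf = numeric(),
                      idh_ccf = numeric(), timing = character()))
  mean_ccf <- tapply(ccf[!idh], other$gene, mean)
  timing <- ifelse(mean_ccf < idh_ccf - tau, "later",
                   ifelse(mean_ccf > idh_ccf + tau, "earlier",
                          "co-occurring"))
  data.frame(gene = names(mean_ccf), mean_ccf = as.numeric(mean_ccf),
             idh_ccf = idh_ccf, timing = as.character(timing),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call IDH-mutation clearance from a longitudinal VAF series
#'
#' A patient is called `cleared/substantially-reduced` when the best
#' (minimum) on-treatment IDH VAF represents a decrease of at least 75%
#' from baseline, i.e. best_post <= 0.25 x baseline; otherwise
#' `persistent`. The boundary is inclusive: exactly 75% decrease clears.
#'
#' @param baseline_vaf baseline IDH VAF (> 0).
#' @param post_vafs numeric vector of on-treatment IDH VAFs (any order;
#'   the minimum is used).
#' @param patient_id optional identifier carried through.
#' @param min_decrease clearance threshold as a fraction (default 0.75).
#' @return one-row data.frame: `patient_id`, `baseline_vaf`,
#'   `best_post_vaf`, `relative_decrease`, `status`.
#' @export
classify_idh_clearance <- function(baseline_vaf, post_vafs,
                                   patient_id = NA_character_,
                                   min_decrease = 0.75) {
  if (is.na(baseline_vaf) || baseline_vaf <= 0)
    stop_input("baseline IDH VAF must be present and > 0")
  if (length(post_vafs) == 0L || all(is.na(post_vafs)))
    stop_input("at least one on-treatment VAF is required")
  best <- min(post_vafs, na.rm = TRUE)
  decrease <- (baseline_vaf - best) / baseline_vaf
  status <- if (decrease >= min_decrease) "cleared/substantially-reduced"
            else "persistent"
  data.frame(patient_id = patient_id, baseline_vaf = baseline_vaf,
             best_post_vaf = best, relative_decrease = decrease,
             status = status, stringsAsFactors = FALSE)
}

#' Default gene-to-pathway map for relapse summaries
#'
#' Total mapping with explicit "other"; shipped as an editable TSV in
#' `inst/extdata/pathway_map.tsv`.
#'
#' @return named character vector (gene -> pathway) loaded from the
#'   packaged TSV.
#' @export
default_pathway_map <- function() {
  path <- system.file("extdata", "pathway_map.tsv", package = "idhres")
  tab <- read_tsv_table(path)
  stats::setNames(tab$pathway, tab$gene)
}

map_pathway <- function(genes, pathway_map) {
  p <- unname(pathway_map[genes])
  p[is.na(p)] <- "other"
  p
}

#' Detect emergent and selected mutations at relapse
#'
#' Compares one patient's post-filter driver tables at baseline and
#' relapse. A relapse variant is `emergent` if its allele was not
#' detectable at baseline (absent after the 5% VAF detection floor of the
#' pipeline), and `selected` if present at both timepoints with relapse
#' VAF at least `fold` times the baseline VAF.
#'
#' @param baseline_drivers,relapse_drivers driver tables (post pipeline)
#'   for one patient at the two timepoints.
#' @param fold selection fold-change threshold (default 2).
#' @param pathway_map named vector gene -> pathway; defaults to the
#'   packaged map.
#' @return data.frame of events: `patient_id`, `gene`, `event_type`,
#'   `baseline_vaf`, `relapse_vaf`, `pathway`.
#' @export
detect_relapse_events <- function(baseline_drivers, relapse_drivers,
                                  fold = 2,
                                  pathway_map = default_pathway_map()) {
  empty <- data.frame(patient_id = character(), gene = character(),
                      event_type = character(), baseline_vaf = numeric(),
                      relapse_vaf = numeric(), pathway = character(),
                      stringsAsFactors = FALSE)
  if (nrow(relapse_drivers) == 0L) return(empty)
  bkey <- if (nrow(baseline_drivers))
    variant_key(baseline_drivers$chrom, baseline_drivers$pos,
                baseline_drivers$ref, baseline_drivers$alt) else character()
  rkey <- variant_key(relapse_drivers$chrom, relapse_drivers$pos,
                      relapse_drivers$ref, relapse_drivers$alt)
  events <- empty
  for (i in seq_len(nrow(relapse_drivers))) {
    j <- match(rkey[i], bkey)
    if (is.na(j)) {
      events <- rbind(events, data.frame(
        patient_id = relapse_drivers$patient_id[i],
        gene = relapse_drivers$gene[i], event_type = "emergent",
        baseline_vaf = 0, relapse_vaf = relapse_drivers$tumor_vaf[i],
        pathway = map_pathway(relapse_drivers$gene[i], pathway_map),
        stringsAsFactors = FALSE))
    } else if (relapse_drivers$tumor_vaf[i] >=
               fold * baseline_drivers$tumor_vaf[j]) {
      events <- rbind(events, data.frame(
        patient_id = relapse_drivers$patient_id[i],
        gene = relapse_drivers$gene[i], event_type = "selected",
        baseline_vaf = baseline_drivers$tumor_vaf[j],
        relapse_vaf = relapse_drivers$tumor_vaf[i],
        pathway = map_pathway(relapse_drivers$gene[i], pathway_map),
        stringsAsFactors = FALSE))
    }
  }
  events
}

#' Summarize relapse-associated events as per-pathway patient fractions
#'
#' Fraction of relapsed patients with at least one emergent/selected event
#' in each pathway; each patient counts once per pathway regardless of how
#' many events they have.
#'
#' @param events event table from [detect_relapse_events()] across
#'   patients.
#' @param relapsed_patients character vector of all patients with tested
#'   baseline/relapse pairs (the denominator).
#' @return data.frame `pathway`, `n_patients`, `fraction`.
#' @export
summarize_relapse_pathways <- function(events, relapsed_patients) {
  denom <- length(unique(relapsed_patients))
  if (denom == 0L) stop_input("no relapsed patients in denominator")
  pathways <- sort(unique(c(events$pathway, character())))
  n <- vapply(pathways, function(p)
    length(unique(events$patient_id[events$pathway == p])), integer(1))
  data.frame(pathway = pathways, n_patients = as.integer(n),
             fraction = as.numeric(n) / denom,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test clone independence of variant pairs in single-cell genotypes
#'
#' For each pair of variants in a cells x variants genotype matrix
#' (0 = wildtype, 1 = mutant, NA = missing; missing cells are excluded
#' pairwise), builds the 2x2 co-classification table, computes a Fisher
#' exact p-value, and calls the pair `mutually-exclusive` when the
#' observed double-mutant count falls below its independence expectation
#' with p < alpha, `co-occurring` when above with p < alpha, and
#' `ambiguous` otherwise. Pairs with fewer than `min_cells` informative
#' cells are `ambiguous` with a warning.
#'
#' @param sc_matrix numeric matrix, cells x variants, entries in
#'   \{0, 1, NA\}.
#' @param alpha significance level (default 0.05).
#' @param min_cells minimum informative cells per pair (default 50).
#' @return data.frame per pair: `variant1`, `variant2`, `n_cells`,
#'   `n11` (double mutant), `expected11`, `p`, `verdict`.
#' @export
test_clone_independence <- function(sc_matrix, alpha = 0.05,
                                    min_cells = 50) {
  vn <- colnames(sc_matrix) %||% paste0("v", seq_len(ncol(sc_matrix)))
  bad <- !(sc_matrix %in% c(0, 1, NA))
  if (any(bad)) stop_input("genotypes must be 0, 1 or NA")
  pairs <- utils::combn(seq_len(ncol(sc_matrix)), 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    keep <- !is.na(sc_matrix[, i]) & !is.na(sc_matrix[, j])
    gi <- sc_matrix[keep, i]; gj <- sc_matrix[keep, j]
    n <- sum(keep)
    n11 <- sum(gi == 1 & gj == 1)
    n10 <- sum(gi == 1 & gj == 0)
    n01 <- sum(gi == 0 & gj == 1)
    n00 <- sum(gi == 0 & gj == 0)
    exp11 <- sum(gi == 1) * sum(gj == 1) / max(n, 1L)
    if (n < min_cells) {
      warning(sprintf("pair %s/%s: only %d informative cells; ambiguous",
                      vn[i], vn[j], n))
      verdict <- "ambiguous"; p <- NA_real_
    } else {
      p <- fisher_exact_2x2(matrix(c(n11, n10, n01, n00), 2, 2))$p
      verdict <- if (p < alpha && n11 < exp11) "mutually-exclusive"
                 else if (p < alpha && n11 > exp11) "co-occurring"
                 else "ambiguous"
    }
    out[[k]] <- data.frame(variant1 = vn[i], variant2 = vn[j],
                           n_cells = n, n11 = n11, expected11 = exp11,
                           p = p, verdict = verdict,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
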