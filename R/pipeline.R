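# End-to-end analysis over a cohort bundle: variant pipeline, clonal
# dynamics, methylation clustering, stemness scoring, association
# statistics and evolution-pattern calls, mirroring the full study
# workflow on any cohort with the expected table structure.

#' Run the full analysis on a cohort bundle
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] (or any
#'   list with the same `clinical` / `variants` / `beta` / `expression`
#'   / `trajectories` / `resource` components).
#' @param n_resamples consensus-clustering resamples (default 200; use
#'   1000 for production-quality consensus matrices).
#' @param seed seed for the stochastic stages (consensus resampling).
#' @return list: `drivers` (classified variant table), `clearance`,
#'   `relapse_events`, `pathway_summary`, `clustering` (consensus
#'   result), `cluster_assignments`, `lsc17` (per-sample scores),
#'   `lsc17_by_response`, `cluster_vs_response` (Fisher row), `roc`
#'   (LSC17 vs nonresponse), `patterns` (per relapsed patient).
#' @export
run_cohort_analysis <- function(cohort, n_resamples = 200, seed = 1) {
  clin <- cohort$clinical
  # 1. variants: filter + classify across all timepoints at once
  vp <- run_variant_pipeline(cohort$variants, cohort$resource)
  drivers <- vp$drivers
  # 2. IDH clearance per patient from baseline + on-treatment VAFs
  clearance <- do.call(rbind, lapply(clin$patient_id, function(id) {
    d <- drivers[drivers$patient_id == id &
                   drivers$gene %in% c("IDH1", "IDH2"), ]
    bl <- d$tumor_vaf[d$timepoint == "baseline"]
    post <- d$tumor_vaf[d$timepoint != "baseline"]
    if (!length(bl)) return(NULL)
    # clearance means the allele may vanish post-filter: absent = 0
    if (!length(post)) post <- 0
    classify_idh_clearance(max(bl), post, patient_id = id)
  }))
  # 3. relapse events + pathway summary over tested baseline/relapse pairs
  rel_ids <- clin$patient_id[clin$relapsed]
  events <- do.call(rbind, lapply(rel_ids, function(id) {
    detect_relapse_events(
      drivers[drivers$patient_id == id & drivers$timepoint == "baseline", ],
      drivers[drivers$patient_id == id & drivers$timepoint == "relapse", ])
  }))
  if (is.null(events))
    events <- data.frame(patient_id = character(), gene = character(),
                         event_type = character(), baseline_vaf = numeric(),
                         relapse_vaf = numeric(), pathway = character())
  pathway_summary <- if (length(rel_ids))
    summarize_relapse_pathways(events, rel_ids) else NULL
  # 4. methylation clustering at baseline
  filtered <- filter_probes(cohort$beta$baseline)
  topcpg <- select_top_variable_promoter_cpgs(filtered)
  clustering <- consensus_kmeans_cluster(topcpg, k_range = 2,
                                         n_resamples = n_resamples,
                                         seed = seed)
  cl <- clustering$assignments
  # 5. stemness
  scores <- lsc17_score(cohort$expression$baseline)
  responder <- clin$response[match(names(scores), clin$patient_id)] ==
    "responder"
  lsc17_by_response <- c(responder = mean(scores[responder]),
                         nonresponder = mean(scores[!responder]))
  roc <- auroc(scores, as.integer(!responder), direction = ">")
  # 6. cluster vs response enrichment
  cl_by_patient <- cl[clin$patient_id]
  cluster_vs_response <- fisher_enrichment(
    as.integer(cl_by_patient == 2L), as.integer(!responder))
  # 7. evolution patterns for relapsed patients
  patterns <- lapply(rel_ids, function(id) {
    emergent <- events$gene[events$patient_id == id &
                              events$event_type == "emergent"]
    classify_evolution_pattern(cohort$trajectories[[id]],
                               relapse_genes = emergent,
                               idh_gene = clin$idh_gene[
                                 clin$patient_id == id])
  })
  names(patterns) <- rel_ids
  list(drivers = drivers, audit = vp$audit, clearance = clearance,
       relapse_events = events, pathway_summary = pathway_summary,
       clustering = clustering, cluster_assignments = cl_by_patient,
       lsc17 = scores, lsc17_by_response = lsc17_by_response,
       cluster_vs_response = cluster_vs_response, roc = roc,
       patterns = patterns)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --n N --out DIR` writes a synthetic
#' cohort; `variants --calls F --resources DIR --out F` runs the variant
#' pipeline on a TSV; `run-all --seed S --out DIR` simulates a cohort,
#' runs the full analysis and writes summary tables. Installed as the
#' `idhres` script under `inst/cli`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
idhres_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: idhres <simulate|variants|run-all> [options]",
    "  simulate --seed S --n N --out DIR",
    "  variants --calls calls.tsv --resources DIR --out drivers.tsv",
    "  run-all  --seed S --out DIR", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "idhres_out")
  if (cmd == "simulate") {
    n <- as.integer(opt("--n", "60"))
    write_cohort(generate_cohort(cohort_config(n_patients = n,
                                               seed = seed)), out)
    message("cohort written to ", out)
  } else if (cmd == "variants") {
    calls <- read_tsv_table(opt("--calls"))
    res <- read_annotation_resources(opt("--resources"))
    vp <- run_variant_pipeline(calls, res)
    write_tsv_table(vp$drivers, out)
    writeLines(vp$audit, paste0(out, ".audit.log"))
    message(nrow(vp$drivers), " drivers written to ", out)
  } else if (cmd == "run-all") {
    cohort <- generate_cohort(cohort_config(seed = seed))
    an <- run_cohort_analysis(cohort, seed = seed)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(an$drivers, file.path(out, "drivers.tsv"))
    write_tsv_table(an$clearance, file.path(out, "clearance.tsv"))
    write_tsv_table(an$relapse_events, file.path(out, "relapse_events.tsv"))
    write_tsv_table(an$pathway_summary, file.path(out, "pathway_summary.tsv"))
    write_tsv_table(data.frame(patient_id = names(an$cluster_assignments),
                               cluster = an$cluster_assignments,
                               lsc17 = an$lsc17[names(an$cluster_assignments)]),
                    file.path(out, "samples.tsv"))
    message("analysis written to ", out)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
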