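# Seeded synthetic multi-omics cohort generator.
#
# Emulates the statistical structure of a ~60-patient IDH1/2-mutant AML
# cohort treated with mutant-IDH inhibitors: a responder/nonresponder
# split, two latent promoter-methylation clusters (cluster 1 relatively
# hypomethylated and DNMT3A-enriched, cluster 2 hypermethylated with
# elevated LSC-signature expression and worse response), co-occurring
# driver mutations with clonal/subclonal structure, longitudinal VAF
# trajectories with relapse acquisitions, treatment-induced demethylation,
# and plasma 2HG suppression dynamics. Every planted fact is recorded in
# a ground-truth object so downstream analyses can be tested for
# parameter recovery.

# fixed gene catalog: symbol, chromosome, tumor-suppressor flag,
# baseline mutation probability (cluster-independent part), clonality
# class, and a COSMIC-style hotspot for tier-1 classification
gene_catalog <- function() {
  g <- function(gene, chrom, tsg, prob, clonality, hotspot_pos) {
    data.frame(gene = gene, chrom = chrom, tsg = tsg, prob = prob,
               clonality = clonality, hotspot_pos = hotspot_pos,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("DNMT3A", "chr2",  TRUE,  NA,    "early", 882),
    g("SRSF2",  "chr17", FALSE, 0.44,  "early", 95),
    g("ASXL1",  "chr20", TRUE,  0.37,  "early", 642),
    g("RUNX1",  "chr21", TRUE,  0.31,  "early", 201),
    g("U2AF1",  "chr21", FALSE, 0.07,  "early", 34),
    g("TET2",   "chr4",  TRUE,  0.12,  "early", 1218),
    g("NRAS",   "chr1",  FALSE, 0.10,  "late",  61),
    g("KRAS",   "chr12", FALSE, 0.05,  "late",  61),
    g("NF1",    "chr17", TRUE,  0.05,  "late",  1423),
    g("PTPN11", "chr12", FALSE, 0.05,  "late",  72),
    g("CBL",    "chr11", FALSE, 0.05,  "late",  371),
    g("FLT3",   "chr13", FALSE, 0.05,  "late",  835),
    g("CEBPA",  "chr19", FALSE, 0.08,  "co",    312),
    g("GATA2",  "chr3",  FALSE, 0.05,  "co",    398),
    g("STAG2",  "chrX",  TRUE,  0.08,  "co",    1060),
    g("SMC1A",  "chrX",  FALSE, 0.03,  "co",    470),
    g("RAD21",  "chr8",  TRUE,  0.03,  "co",    530),
    g("BCOR",   "chrX",  TRUE,  0.05,  "co",    1459),
    g("EZH2",   "chr7",  TRUE,  0.04,  "co",    641),
    g("TP53",   "chr17", TRUE,  0.05,  "co",    273),
    g("WT1",    "chr11", TRUE,  0.04,  "co",    378)
  )
}

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
        "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration of the synthetic cohort generator
#'
#' Defaults state the emulated world: 60 patients, half responders, 30\%
#' in the hypermethylated cluster 2, a +0.15 beta shift on 5\% of probes
#' discriminating the clusters, a +1 log2 shift of LSC-signature genes
#' in cluster 2, sequencing depth around 300x, and a 5\% VAF detection
#' floor matching the variant pipeline. All randomness is fixed by
#' `seed`.
#'
#' @param n_patients cohort size.
#' @param responder_fraction fraction achieving overall response.
#' @param cluster2_fraction fraction in the hypermethylated cluster 2.
#' @param n_probes methylation probes on the simulated array.
#' @param promoter_fraction fraction of probes flagged as promoter CpGs.
#' @param n_genes genes on the simulated expression matrix (includes the
#'   17 stemness-signature genes and the planted LSC set).
#' @param delta_beta_cluster mean beta shift of cluster 2 on
#'   discriminating probes.
#' @param discriminating_probe_fraction fraction of probes
#'   discriminating the clusters (all promoter-flagged).
#' @param lsc_effect additive log2 shift of LSC-signature genes in
#'   cluster-2 samples.
#' @param vaf_noise_sd extra Gaussian VAF measurement noise on top of
#'   binomial read sampling.
#' @param seed integer seed fixing every downstream draw.
#' @param relapse_fraction fraction of responders who relapse.
#' @param clearance_fraction fraction of responders whose IDH VAF drops
#'   >= 75\% at response.
#' @param cluster2_nonresponse_weight sampling weight (< 1) of cluster-2
#'   patients when drawing responders; lower = stronger enrichment of
#'   cluster 2 among nonresponders.
#' @param demeth_fraction,demeth_effect fraction of probes demethylated
#'   on therapy and the beta reduction applied to them.
#' @param beta_noise_sd per-sample Gaussian noise on beta values.
#' @param expr_noise_sd per-sample Gaussian noise on log2 expression.
#' @param mean_depth,depth_size negative-binomial sequencing depth model
#'   (mean and size), matching a ~300x targeted panel.
#' @param detection_floor VAF below which a variant is considered
#'   undetectable (mirrors the pipeline filter).
#' @param n_lsc_genes size of the planted LSC gene set.
#' @param pattern_probs probabilities of evolution patterns 1/2/3 among
#'   relapsing responders.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60, responder_fraction = 0.5,
                          cluster2_fraction = 0.3, n_probes = 10000,
                          promoter_fraction = 0.4, n_genes = 1000,
                          delta_beta_cluster = 0.15,
                          discriminating_probe_fraction = 0.05,
                          lsc_effect = 1.0, vaf_noise_sd = 0.01,
                          seed = 1,
                          relapse_fraction = 2 / 3,
                          clearance_fraction = 0.29,
                          cluster2_nonresponse_weight = 0.35,
                          demeth_fraction = 0.3, demeth_effect = 0.15,
                          beta_noise_sd = 0.02, expr_noise_sd = 0.5,
                          mean_depth = 300, depth_size = 8,
                          detection_floor = 0.05,
                          n_lsc_genes = 50,
                          pattern_probs = c(0.4, 0.4, 0.2)) {
  cfg <- as.list(environment())
  for (nm in c("responder_fraction", "cluster2_fraction",
               "promoter_fraction", "discriminating_probe_fraction",
               "relapse_fraction", "clearance_fraction",
               "demeth_fraction", "detection_floor"))
    assert_proportion(cfg[[nm]], nm)
  for (nm in c("n_patients", "n_probes", "n_genes", "seed"))
    assert_count(cfg[[nm]], nm)
  if (discriminating_probe_fraction > promoter_fraction)
    stop_input("discriminating probes must fit inside the promoter set")
  class(cfg) <- "cohort_config"
  cfg
}

sub_seed <- function(config, k) {
  as.integer((as.numeric(config$seed) * 97 + k) %% 2147483647)
}

patient_ids <- function(n) sprintf("P%03d", seq_len(n))

# latent per-patient truth: clusters, response, relapse, clearance,
# evolution patterns, planted drivers and relapse acquisitions
generate_truth <- function(config) {
  set.seed(sub_seed(config, 1L))
  n <- config$n_patients
  ids <- patient_ids(n)
  n_c2 <- round(n * config$cluster2_fraction)
  cluster <- rep(1L, n)
  cluster[sample.int(n, n_c2)] <- 2L
  # responders drawn with reduced weight for cluster 2 -> cluster 2 is
  # enriched among nonresponders while the overall count stays exact
  n_resp <- round(n * config$responder_fraction)
  w <- ifelse(cluster == 2L, config$cluster2_nonresponse_weight, 1)
  responder <- rep(FALSE, n)
  responder[sample.int(n, n_resp, prob = w)] <- TRUE
  idh_gene <- ifelse(stats::runif(n) < 0.63, "IDH2", "IDH1")
  idh_change <- ifelse(idh_gene == "IDH1",
                       sample(c("R132H", "R132C"), n, replace = TRUE),
                       sample(c("R140Q", "R172K"), n, replace = TRUE))
  idh_ccf <- stats::runif(n, 0.6, 0.85)
  resp_idx <- which(responder)
  cleared <- rep(FALSE, n)
  if (length(resp_idx))
    cleared[sample(resp_idx, round(length(resp_idx) *
                                     config$clearance_fraction))] <- TRUE
  relapsed <- rep(FALSE, n)
  if (length(resp_idx))
    relapsed[sample(resp_idx, round(length(resp_idx) *
                                      config$relapse_fraction))] <- TRUE
  rel_idx <- which(relapsed)
  pattern <- rep(NA_integer_, n)
  if (length(rel_idx)) {
    pattern[rel_idx] <- sample(1:3, length(rel_idx), replace = TRUE,
                               prob = config$pattern_probs)
    # with enough relapses, make sure every pattern is represented
    if (length(rel_idx) >= 3L)
      for (pt in 1:3)
        if (!pt %in% pattern[rel_idx])
          pattern[rel_idx[pt]] <- pt
  }
  # planted co-occurring drivers
  cat <- gene_catalog()
  drivers <- list()
  for (i in seq_len(n)) {
    hit <- character()
    for (j in seq_len(nrow(cat))) {
      p <- if (cat$gene[j] == "DNMT3A") {
        if (cluster[i] == 1L) 0.55 else 0.20
      } else cat$prob[j]
      if (stats::runif(1) < p) hit <- c(hit, cat$gene[j])
    }
    for (g in hit) {
      row <- cat[cat$gene == g, ]
      ccf <- switch(row$clonality,
                    early = 1.0,
                    late = stats::runif(1, 0.2, 0.4),  # VAF >= 0.1: above floor
                    co = min(1, idh_ccf[i] + stats::runif(1, -0.05, 0.05)))
      # tumor suppressors carry loss-of-function alleles half the time
      lof <- row$tsg && stats::runif(1) < 0.5
      drivers[[length(drivers) + 1L]] <- data.frame(
        patient_id = ids[i], gene = g, ccf = ccf,
        consequence = if (lof) "frameshift" else "missense",
        variant_class = if (lof) "indel" else "SNV",
        protein_pos = if (lof) sample.int(500, 1) else row$hotspot_pos,
        stringsAsFactors = FALSE)
    }
    drivers[[length(drivers) + 1L]] <- data.frame(
      patient_id = ids[i], gene = idh_gene[i], ccf = idh_ccf[i],
      consequence = "missense", variant_class = "SNV",
      protein_pos = as.integer(sub("^[A-Z]", "",
                                   sub("[A-Z]$", "", idh_change[i]))),
      stringsAsFactors = FALSE)
  }
  drivers <- do.call(rbind, drivers)
  drivers$protein_change <- ifelse(
    drivers$consequence == "missense",
    paste0(sample(AA, nrow(drivers), replace = TRUE), drivers$protein_pos,
           sample(AA, nrow(drivers), replace = TRUE)),
    paste0("fs", drivers$protein_pos))
  # the IDH mutation keeps its canonical hotspot change
  is_idh <- drivers$gene %in% c("IDH1", "IDH2")
  drivers$protein_change[is_idh] <-
    idh_change[match(drivers$patient_id[is_idh], ids)]
  # unique genomic coordinates per (gene, protein_change)
  key <- paste(drivers$gene, drivers$protein_change)
  uk <- unique(key)
  coord <- data.frame(key = uk,
                      chrom = cat$chrom[match(sub(" .*", "", uk), cat$gene)],
                      pos = sample(1e6:2e8, length(uk)),
                      stringsAsFactors = FALSE)
  coord$chrom[is.na(coord$chrom)] <-
    ifelse(sub(" .*", "", uk[is.na(coord$chrom)]) == "IDH1", "chr2", "chr15")
  m <- match(key, coord$key)
  drivers$chrom <- coord$chrom[m]
  drivers$pos <- coord$pos[m]
  drivers$ref <- sample(c("A", "C", "G", "T"), nrow(drivers), replace = TRUE)
  drivers$alt <- ifelse(drivers$variant_class == "indel", "-",
                        substr(chartr("ACGT", "GTAC", drivers$ref), 1, 1))
  # relapse acquisitions: pattern-linked trigger plus extra pathway events
  acquisitions <- list()
  for (i in rel_idx) {
    trig <- switch(pattern[i],
                   sample(c("KRAS", "NRAS"), 1),       # pattern 1: RAS clone
                   "TET2",                              # pattern 2
                   if (idh_gene[i] == "IDH2") "IDH1" else "IDH2")  # 3: switch
    extra <- character()
    if (stats::runif(1) < 0.28) extra <- c(extra, sample(c("ASXL1", "BCOR",
                                                           "EZH2"), 1))
    if (stats::runif(1) < 0.28) extra <- c(extra, sample(c("RUNX1", "CEBPA",
                                                           "GATA2"), 1))
    baseline_genes <- drivers$gene[drivers$patient_id == ids[i]]
    for (g in unique(c(trig, extra))) {
      if (g %in% baseline_genes) next  # emergent events only
      acquisitions[[length(acquisitions) + 1L]] <- data.frame(
        patient_id = ids[i], gene = g,
        ccf = stats::runif(1, 0.25, 0.7), stringsAsFactors = FALSE)
    }
  }
  acquisitions <- if (length(acquisitions)) do.call(rbind, acquisitions)
    else data.frame(patient_id = character(), gene = character(),
                    ccf = numeric())
  if (nrow(acquisitions)) {
    acquisitions$consequence <- "missense"
    acquisitions$variant_class <- "SNV"
    acquisitions$protein_pos <-
      cat$hotspot_pos[match(acquisitions$gene, cat$gene)]
    sw <- acquisitions$gene %in% c("IDH1", "IDH2")
    acquisitions$protein_pos[sw] <-
      ifelse(acquisitions$gene[sw] == "IDH1", 132L, 140L)
    acquisitions$protein_change <- paste0(
      sample(AA, nrow(acquisitions), replace = TRUE),
      acquisitions$protein_pos,
      sample(AA, nrow(acquisitions), replace = TRUE))
    acquisitions$protein_change[sw] <-
      ifelse(acquisitions$gene[sw] == "IDH1", "R132C", "R140Q")
    acquisitions$chrom <- cat$chrom[match(acquisitions$gene, cat$gene)]
    acquisitions$chrom[is.na(acquisitions$chrom)] <-
      ifelse(acquisitions$gene[is.na(acquisitions$chrom)] == "IDH1",
             "chr2", "chr15")
    acquisitions$pos <- sample(1e6:2e8, nrow(acquisitions))
    acquisitions$ref <- sample(c("A", "C", "G", "T"), nrow(acquisitions),
                               replace = TRUE)
    acquisitions$alt <- substr(chartr("ACGT", "GTAC", acquisitions$ref), 1, 1)
  }
  # planted probe structure
  n_prom <- round(config$n_probes * config$promoter_fraction)
  probe_id <- sprintf("cg%06d", seq_len(config$n_probes))
  promoter <- seq_len(config$n_probes) <= n_prom
  n_disc <- round(config$n_probes * config$discriminating_probe_fraction)
  disc <- sample(which(promoter), n_disc)
  demeth <- sample.int(config$n_probes,
                       round(config$n_probes * config$demeth_fraction))
  snp_flag <- stats::runif(config$n_probes) < 0.02
  chrom_probe <- sample(paste0("chr", c(1:22, "X", "Y")),
                        config$n_probes, replace = TRUE,
                        prob = c(rep(1, 22), 0.03, 0.01))
  # planted LSC gene set and expression universe
  n_bg <- config$n_genes - 17L - config$n_lsc_genes
  if (n_bg < 0) stop_input("n_genes too small for the planted signatures")
  lsc_set <- sprintf("LSC%03d", seq_len(config$n_lsc_genes))
  genes <- c(names(lsc17_signature()), lsc_set,
             sprintf("BG%04d", seq_len(n_bg)))
  list(
    patients = data.frame(patient_id = ids, cluster = cluster,
                          responder = responder, relapsed = relapsed,
                          idh_cleared = cleared, pattern = pattern,
                          idh_gene = idh_gene, idh_change = idh_change,
                          idh_ccf = idh_ccf, stringsAsFactors = FALSE),
    drivers = drivers, acquisitions = acquisitions,
    probes = data.frame(probe_id = probe_id, promoter = promoter,
                        snp = snp_flag, chrom = chrom_probe,
                        stringsAsFactors = FALSE),
    discriminating_probes = probe_id[disc],
    demeth_probes = probe_id[demeth],
    genes = genes, lsc_genes = lsc_set)
}

measure_vaf <- function(ccf, depth, noise_sd) {
  vaf <- stats::rbinom(length(ccf), depth, pmin(1, ccf) / 2) / depth
  pmin(1, pmax(0, vaf + stats::rnorm(length(ccf), 0, noise_sd)))
}

#' Generate longitudinal variant-call tables from planted truth
#'
#' Depth is negative-binomial around the configured panel depth; VAFs
#' are binomial draws of depth reads at CCF/2 (diploid heterozygous,
#' copy-neutral) plus optional Gaussian measurement noise. Baseline
#' drivers persist at response and relapse; the IDH VAF drops >= 75\% at
#' response in planted clearance patients; relapse samples add the
#' planted emergent mutations and 3x-selected subclonal RAS clones.
#' Each patient-timepoint also carries junk calls (synonymous,
#' sub-floor VAF, low coverage, common polymorphism) that exercise the
#' filtering cascade.
#'
#' @param config a [cohort_config()].
#' @param truth internal truth object from [generate_cohort()].
#' @return data.frame of variant calls across timepoints.
#' @export
generate_variant_tables <- function(config, truth) {
  set.seed(sub_seed(config, 2L))
  pts <- truth$patients
  drv <- truth$drivers
  rows <- list()
  emit <- function(d, patient, tp, ccf) {
    depth <- pmax(30L, stats::rnbinom(nrow(d), mu = config$mean_depth,
                                      size = config$depth_size))
    data.frame(patient_id = patient, timepoint = tp, gene = d$gene,
               chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
               variant_class = d$variant_class, consequence = d$consequence,
               protein_pos = d$protein_pos,
               protein_change = d$protein_change,
               tumor_depth = depth,
               tumor_vaf = measure_vaf(ccf, depth, config$vaf_noise_sd),
               normal_vaf = 0, stringsAsFactors = FALSE)
  }
  junk <- function(patient, tp) {
    depth <- pmax(30L, stats::rnbinom(3L, mu = config$mean_depth,
                                      size = config$depth_size))
    data.frame(patient_id = patient, timepoint = tp,
               gene = c("JUNK1", "JUNK2", "JUNK3"),
               chrom = "chr9", pos = sample(1e6:2e8, 3L),
               ref = "A", alt = "G", variant_class = "SNV",
               consequence = c("synonymous", "missense", "missense"),
               protein_pos = sample.int(500, 3L),
               protein_change = paste0("X", 1:3, "Y"),
               tumor_depth = c(depth[1L], depth[2L], 12L),
               tumor_vaf = c(stats::runif(1, 0.1, 0.4),
                             stats::runif(1, 0.005, 0.03),
                             stats::runif(1, 0.1, 0.4)),
               normal_vaf = 0, stringsAsFactors = FALSE)
  }
  common_snp <- function(patient, tp) {
    depth <- pmax(30L, stats::rnbinom(1L, mu = config$mean_depth,
                                      size = config$depth_size))
    data.frame(patient_id = patient, timepoint = tp, gene = "SNPGENE",
               chrom = "chr9", pos = 500000L, ref = "C", alt = "T",
               variant_class = "SNV", consequence = "missense",
               protein_pos = 10L, protein_change = "A10V",
               tumor_depth = depth, tumor_vaf = stats::runif(1, 0.3, 0.6),
               normal_vaf = stats::runif(1, 0.3, 0.6),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pts))) {
    id <- pts$patient_id[i]
    d <- drv[drv$patient_id == id, , drop = FALSE]
    is_idh <- d$gene %in% c("IDH1", "IDH2")
    tps <- c("baseline", "response", if (pts$relapsed[i]) "relapse")
    for (tp in tps) {
      ccf <- d$ccf
      if (tp != "baseline" && pts$idh_cleared[i])
        ccf[is_idh] <- ccf[is_idh] * stats::runif(1, 0.02, 0.2)
      if (tp == "relapse") {
        late <- d$ccf < 0.45 & !is_idh
        ccf[late] <- pmin(1, d$ccf[late] * 3)  # selected subclones
      }
      rows[[length(rows) + 1L]] <- emit(d, id, tp, ccf)
      if (tp == "relapse") {
        acq <- truth$acquisitions[truth$acquisitions$patient_id == id, ,
                                  drop = FALSE]
        if (nrow(acq))
          rows[[length(rows) + 1L]] <- emit(acq, id, tp, acq$ccf)
      }
      rows[[length(rows) + 1L]] <- junk(id, tp)
      rows[[length(rows) + 1L]] <- common_snp(id, tp)
    }
  }
  do.call(rbind, rows)
}

#' Build the mock annotation resource matching the planted cohort
#'
#' The COSMIC-style catalog contains the canonical hotspot records of
#' every cataloged gene (and the IDH hotspots), so planted missense
#' drivers classify as tier 1; frameshift alleles in tumor suppressors
#' are absent from the catalog and classify as tier 2. The common
#' polymorphism planted by [generate_variant_tables()] carries a 1\%
#' population frequency.
#'
#' @param config a [cohort_config()].
#' @param truth truth object.
#' @return an [annotation_resource()].
#' @export
generate_annotation_resource <- function(config, truth) {
  drv <- rbind(truth$drivers[, c("gene", "protein_pos", "protein_change")],
               if (nrow(truth$acquisitions))
                 truth$acquisitions[, c("gene", "protein_pos",
                                        "protein_change")])
  cosmic <- unique(drv[!grepl("^fs", drv$protein_change), , drop = FALSE])
  cat <- gene_catalog()
  annotation_resource(
    cosmic = cosmic,
    tsg_genes = cat$gene[cat$tsg],
    popfreq = data.frame(chrom = "chr9", pos = 500000L, ref = "C",
                         alt = "T", frequency = 0.01,
                         stringsAsFactors = FALSE),
    damaging = NULL)
}

#' Generate per-timepoint methylation beta matrices
#'
#' Background probes have fixed per-probe means (Beta-distributed across
#' probes) with Gaussian per-sample noise; discriminating promoter
#' probes are shifted +`delta_beta_cluster` in cluster-2 samples; the
#' fixed demethylation probe set loses `demeth_effect` beta in every
#' on-treatment sample, and stays suppressed at relapse except in
#' planted pattern-2/3 patients, whose relapse samples rebound to
#' baseline levels. All betas are clipped to \[0,1\].
#'
#' @param config a [cohort_config()].
#' @param truth truth object.
#' @return named list of beta matrices (`baseline`, `post`, `relapse`)
#'   built with [beta_matrix()]; the relapse matrix covers relapsing
#'   patients only.
#' @export
generate_methylation <- function(config, truth) {
  set.seed(sub_seed(config, 3L))
  pts <- truth$patients
  n <- nrow(pts)
  np <- config$n_probes
  probe_means <- stats::rbeta(np, 3, 3) * 0.6 + 0.2  # keep room to shift
  disc <- truth$probes$probe_id %in% truth$discriminating_probes
  demeth <- truth$probes$probe_id %in% truth$demeth_probes
  draw <- function(sample_idx, demeth_on) {
    m <- matrix(probe_means, np, length(sample_idx))
    c2 <- pts$cluster[sample_idx] == 2L
    m[disc, c2] <- m[disc, c2] + config$delta_beta_cluster
    if (length(demeth_on))
      m[demeth, demeth_on] <- m[demeth, demeth_on] - config$demeth_effect
    m <- m + stats::rnorm(length(m), 0, config$beta_noise_sd)
    m <- pmin(pmax(m, 0), 1)  # matrix first so dims survive
    colnames(m) <- pts$patient_id[sample_idx]
    beta_matrix(m, truth$probes)
  }
  all_idx <- seq_len(n)
  baseline <- draw(all_idx, integer(0))
  post <- draw(all_idx, seq_along(all_idx))  # everyone demethylates
  rel_idx <- which(pts$relapsed)
  relapse <- NULL
  if (length(rel_idx)) {
    # pattern 1 stays demethylated; patterns 2 and 3 rebound
    keep_supp <- which(pts$pattern[rel_idx] == 1L)
    relapse <- draw(rel_idx, keep_supp)
  }
  list(baseline = baseline, post = post, relapse = relapse)
}

#' Generate per-timepoint log2 expression matrices
#'
#' Background genes are i.i.d. Gaussian around fixed per-gene means; the
#' 17 stemness-signature genes and the planted LSC gene set are shifted
#' by `lsc_effect` in cluster-2 samples at every timepoint (stemness is
#' not reversed by therapy).
#'
#' @param config a [cohort_config()].
#' @param truth truth object.
#' @return named list of genes x samples matrices (`baseline`, `post`).
#' @export
generate_expression <- function(config, truth) {
  set.seed(sub_seed(config, 4L))
  pts <- truth$patients
  genes <- truth$genes
  ng <- length(genes)
  gene_means <- stats::rnorm(ng, 5, 1)
  shifted <- genes %in% c(names(lsc17_signature()), truth$lsc_genes)
  draw <- function() {
    m <- matrix(gene_means, ng, nrow(pts))
    c2 <- pts$cluster == 2L
    m[shifted, c2] <- m[shifted, c2] + config$lsc_effect
    m <- m + stats::rnorm(length(m), 0, config$expr_noise_sd)
    dimnames(m) <- list(genes, pts$patient_id)
    m
  }
  list(baseline = draw(), post = draw())
}

#' Generate longitudinal clinical trajectories (2HG, blasts, IDH VAF)
#'
#' Plasma 2HG starts around 1000 ng/ml (lognormal spread), is suppressed
#' to a few percent of baseline on treatment in responders and most
#' nonresponders, and at relapse stays suppressed in patterns 1/2 but
#' rebounds to near baseline in pattern-3 (IDH homolog switch) patients.
#' Mean beta per timepoint is taken from the generated methylation
#' matrices.
#'
#' @param config a [cohort_config()].
#' @param truth truth object.
#' @param beta optional output of [generate_methylation()]; regenerated
#'   (deterministically) when omitted.
#' @return named list of [patient_trajectory()] objects.
#' @export
generate_trajectories <- function(config, truth, beta = NULL) {
  if (is.null(beta)) beta <- generate_methylation(config, truth)
  set.seed(sub_seed(config, 5L))
  pts <- truth$patients
  mean_beta <- list(baseline = colMeans(beta$baseline),
                    post = colMeans(beta$post),
                    relapse = if (!is.null(beta$relapse))
                      colMeans(beta$relapse))
  out <- list()
  for (i in seq_len(nrow(pts))) {
    id <- pts$patient_id[i]
    hg2_bl <- exp(stats::rnorm(1, log(1000), 0.3))
    suppressed <- pts$responder[i] || stats::runif(1) < 0.8
    hg2_resp <- hg2_bl * (if (suppressed) stats::runif(1, 0.02, 0.1)
                          else stats::runif(1, 0.7, 1.1))
    blast_bl <- stats::runif(1, 20, 80)
    blast_resp <- if (pts$responder[i]) stats::runif(1, 1, 10)
                  else blast_bl * stats::runif(1, 0.8, 1.2)
    idh_bl <- pts$idh_ccf[i] / 2
    idh_resp <- if (pts$idh_cleared[i]) idh_bl * stats::runif(1, 0.02, 0.2)
                else idh_bl * stats::runif(1, 0.9, 1.1)
    tp <- c("baseline", "response")
    mb <- c(mean_beta$baseline[id], mean_beta$post[id])
    hg2 <- c(hg2_bl, hg2_resp)
    blast <- c(blast_bl, blast_resp)
    idh_vaf <- c(idh_bl, idh_resp)
    if (pts$relapsed[i]) {
      tp <- c(tp, "relapse")
      mb <- c(mb, mean_beta$relapse[id])
      hg2 <- c(hg2, if (pts$pattern[i] == 3L)
        hg2_bl * stats::runif(1, 0.8, 1.1)
        else hg2_resp * stats::runif(1, 0.8, 1.5))
      blast <- c(blast, stats::runif(1, 30, 80))
      idh_vaf <- c(idh_vaf, if (pts$pattern[i] == 3L) idh_resp
                   else idh_bl * stats::runif(1, 0.8, 1.1))
    }
    resp_label <- ifelse(pts$responder[i], "responder", "nonresponder")
    out[[id]] <- patient_trajectory(id, tp, mean_beta = unname(mb),
                                    hg2 = hg2, idh_vaf = idh_vaf,
                                    blast = blast, response = resp_label)
  }
  out
}

#' Generate the full synthetic multi-omics cohort
#'
#' Single entry point producing mutually consistent clinical, variant,
#' methylation, expression and trajectory data plus the ground truth and
#' the mock annotation resource. Byte-identical under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort`: `clinical` (patient table
#'   without latent truth columns), `variants`, `beta` (per-timepoint
#'   beta matrices), `expression`, `trajectories`, `resource`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop_input("`config` must be a cohort_config()")
  truth <- generate_truth(config)
  variants <- generate_variant_tables(config, truth)
  beta <- generate_methylation(config, truth)
  expression <- generate_expression(config, truth)
  trajectories <- generate_trajectories(config, truth, beta)
  clinical <- truth$patients[, c("patient_id", "idh_gene", "relapsed")]
  clinical$treatment <- ifelse(clinical$idh_gene == "IDH1",
                               "ivosidenib", "enasidenib")
  clinical$response <- ifelse(truth$patients$responder,
                              "responder", "nonresponder")
  structure(list(clinical = clinical, variants = variants, beta = beta,
                 expression = expression, trajectories = trajectories,
                 resource = generate_annotation_resource(config, truth),
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Simulate a single-cell genotype matrix with a planted clone structure
#'
#' @param n_cells number of cells.
#' @param p1,p2 mutant-cell prevalences of the two variants.
#' @param mode `"independent"` (genotypes drawn independently),
#'   `"exclusive"` (mutant cells never share both variants) or
#'   `"nested"` (variant-2 mutants are a subset of variant-1 mutants).
#' @param missing_rate fraction of genotypes set to NA.
#' @param seed integer seed.
#' @return cells x 2 matrix of \{0,1,NA\} with column names `v1`, `v2`.
#' @export
simulate_sc_matrix <- function(n_cells, p1 = 0.3, p2 = 0.2,
                               mode = c("independent", "exclusive",
                                        "nested"),
                               missing_rate = 0, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  g1 <- stats::rbinom(n_cells, 1, p1)
  g2 <- switch(mode,
    independent = stats::rbinom(n_cells, 1, p2),
    exclusive = ifelse(g1 == 1, 0,
                       stats::rbinom(n_cells, 1,
                                     min(1, p2 / max(1e-9, 1 - p1)))),
    nested = ifelse(g1 == 1,
                    stats::rbinom(n_cells, 1, min(1, p2 / max(1e-9, p1))),
                    0))
  m <- cbind(v1 = g1, v2 = g2)
  if (missing_rate > 0) {
    drop <- stats::runif(length(m)) < missing_rate
    m[drop] <- NA
  }
  m
}

#' Write a generated cohort to a directory of portable text files
#'
#' Emits the same TSV formats the analysis functions read, plus a truth
#' JSON sidecar for tests: `clinical.tsv`, `variants.tsv`, per-timepoint
#' `beta_<tp>.tsv` and `expr_<tp>.tsv`, `probes.tsv`, `trajectories.tsv`,
#' resource TSVs and `truth.json`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv_table(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv_table(cohort$truth$probes, file.path(dir, "probes.tsv"))
  for (tp in names(cohort$beta)) {
    m <- cohort$beta[[tp]]
    if (is.null(m)) next
    df <- data.frame(probe_id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
    write_tsv_table(df, file.path(dir, paste0("beta_", tp, ".tsv")))
  }
  for (tp in names(cohort$expression)) {
    m <- cohort$expression[[tp]]
    df <- data.frame(gene = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    write_tsv_table(df, file.path(dir, paste0("expr_", tp, ".tsv")))
  }
  traj <- do.call(rbind, lapply(cohort$trajectories, as.data.frame))
  write_tsv_table(traj, file.path(dir, "trajectories.tsv"))
  res <- cohort$resource
  write_tsv_table(res$cosmic, file.path(dir, "cosmic.tsv"))
  writeLines(res$tsg_genes, file.path(dir, "tsg.txt"))
  write_tsv_table(data.frame(chrom = "chr9", pos = 500000L, ref = "C",
                             alt = "T", frequency = 0.01),
                  file.path(dir, "popfreq.tsv"))
  truth_small <- cohort$truth
  truth_small$probes <- NULL  # large and reconstructible from probes.tsv
  jsonlite::write_json(truth_small, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
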