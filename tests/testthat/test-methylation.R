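# probe filtering, top-variance selection, consensus clustering, DMP
# testing and longitudinal delta-beta analyses

fixture_beta <- function(n_probes = 200, n_samples = 20, seed = 1,
                         n_snp = 0, n_chrx = 0, promoter = TRUE) {
  set.seed(seed)
  info <- data.frame(probe_id = sprintf("cg%05d", 1:n_probes),
                     promoter = promoter, snp = FALSE, chrom = "chr1",
                     stringsAsFactors = FALSE)
  if (n_snp) info$snp[seq_len(n_snp)] <- TRUE
  if (n_chrx) info$chrom[n_snp + seq_len(n_chrx)] <- "chrX"
  m <- matrix(runif(n_probes * n_samples, 0.2, 0.8), n_probes, n_samples,
              dimnames = list(info$probe_id, paste0("S", 1:n_samples)))
  beta_matrix(m, info)
}

test_that("probe filter removes SNP and sex-chromosome probes", {
  m <- fixture_beta(1000, 10, n_snp = 100, n_chrx = 50)
  out <- filter_probes(m)
  expect_equal(nrow(out), 850L)
  expect_equal(ncol(out), 10L)
  # no flagged probes -> identity
  m2 <- fixture_beta(100, 5)
  expect_equal(dim(filter_probes(m2)), dim(m2))
  # all probes flagged -> empty with warning
  m3 <- fixture_beta(10, 5, n_snp = 10)
  expect_warning(out3 <- filter_probes(m3), "all probes")
  expect_equal(nrow(out3), 0L)
})

test_that("top-variance selection counts probes then intersects promoters", {
  m <- fixture_beta(10000, 12, seed = 3)
  sel <- select_top_variable_promoter_cpgs(m, 0.01)
  expect_equal(nrow(sel), 100L)  # all probes promoter-flagged here
  expect_error(select_top_variable_promoter_cpgs(m, 0), "top_fraction")
  expect_error(select_top_variable_promoter_cpgs(m, 1.5), "top_fraction")
  # constant probes never beat variable ones
  info <- data.frame(probe_id = paste0("p", 1:10), promoter = TRUE,
                     snp = FALSE, chrom = "chr1")
  const <- beta_matrix(rbind(matrix(0.5, 9, 6),
                             seq(0, 1, length.out = 6)), info)
  sel2 <- select_top_variable_promoter_cpgs(const, 0.1)
  expect_equal(rownames(sel2), "p10")
})

test_that("planted discriminating probes are selected by variance", {
  cfg <- cohort_config(n_patients = 40, n_probes = 2000, n_genes = 100,
                       seed = 9)
  co <- generate_cohort(cfg)
  filtered <- filter_probes(co$beta$baseline)
  sel <- select_top_variable_promoter_cpgs(
    filtered, cfg$discriminating_probe_fraction)
  planted <- intersect(co$truth$discriminating_probes, rownames(filtered))
  expect_gte(mean(planted %in% rownames(sel)), 0.9)
})

test_that("consensus clustering recovers planted clusters, labels hyper as 2", {
  cfg <- cohort_config(n_patients = 60, n_probes = 2000, n_genes = 100,
                       seed = 21)
  co <- generate_cohort(cfg)
  top <- select_top_variable_promoter_cpgs(filter_probes(co$beta$baseline))
  res <- consensus_kmeans_cluster(top, k_range = 2, n_resamples = 100,
                                  seed = 1)
  truth_cl <- co$truth$patients$cluster
  expect_equal(oracle_ari(res$assignments[co$truth$patients$patient_id],
                          truth_cl), 1.0)
  # the hypermethylated planted group is always reported as cluster 2
  mean_by_cl <- tapply(colMeans(top), res$assignments, mean)
  expect_gt(mean_by_cl["2"], mean_by_cl["1"])
  # consensus matrix is symmetric with unit diagonal, entries in [0,1]
  cm <- res$consensus
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(top)))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_error(consensus_kmeans_cluster(top, k_range = 100), "exceeds")
})

test_that("assignments are invariant under sample-order permutation", {
  cfg <- cohort_config(n_patients = 30, n_probes = 1000, n_genes = 100,
                       seed = 13)
  co <- generate_cohort(cfg)
  top <- select_top_variable_promoter_cpgs(filter_probes(co$beta$baseline))
  set.seed(99)
  perm <- sample(ncol(top))
  permuted <- top[, perm]
  attr(permuted, "probe_info") <- attr(top, "probe_info")
  r1 <- consensus_kmeans_cluster(top, n_resamples = 100, seed = 4)
  r2 <- consensus_kmeans_cluster(permuted, n_resamples = 100, seed = 4)
  expect_equal(r2$assignments[names(r1$assignments)], r1$assignments)
})

test_that("null structure yields no reproducible 2-cluster split", {
  cfg <- cohort_config(n_patients = 40, n_probes = 1000, n_genes = 100,
                       delta_beta_cluster = 0, lsc_effect = 0, seed = 17)
  co <- generate_cohort(cfg)
  top <- select_top_variable_promoter_cpgs(filter_probes(co$beta$baseline))
  res <- consensus_kmeans_cluster(top, k_range = 2, n_resamples = 100,
                                  seed = 1)
  # consensus ambiguity: many pairwise frequencies far from 0 and 1
  off <- res$consensus[upper.tri(res$consensus)]
  expect_gte(mean(off > 0.1 & off < 0.9), 0.2)
  expect_lt(oracle_ari(res$assignments[co$truth$patients$patient_id],
                       co$truth$patients$cluster), 0.3)
})

test_that("realized inter-cluster gap is monotone in delta_beta_cluster", {
  gap_for <- function(delta) {
    cfg <- cohort_config(n_patients = 30, n_probes = 1000, n_genes = 100,
                         delta_beta_cluster = delta, seed = 31)
    co <- generate_cohort(cfg)
    disc <- rownames(co$beta$baseline) %in% co$truth$discriminating_probes
    cl <- co$truth$patients$cluster
    mean(co$beta$baseline[disc, cl == 2]) -
      mean(co$beta$baseline[disc, cl == 1])
  }
  g0 <- gap_for(0.05); g1 <- gap_for(0.15)
  expect_lt(abs(g1 - 0.15), 0.02)   # realized gap matches construction
  expect_gt(g1, g0)
})

test_that("dmp_test matches construction and the BH oracle", {
  set.seed(5)
  n <- 100
  m <- matrix(rnorm(n * 20, 0.5, 0.05), n, 20)
  m[1:10, 11:20] <- m[1:10, 11:20] + 0.2
  m <- pmin(pmax(m, 0), 1)
  rownames(m) <- paste0("p", 1:n)
  res <- dmp_test(m, rep(c("g1", "g2"), each = 10))
  expect_true(all(res$significant[1:10]))
  expect_equal(res$direction[1:10], rep("hyper", 10))
  expect_true(all(res$q >= res$p))
  expect_equal(res$q, oracle_bh(res$p))
  # group-label swap flips delta sign, keeps p
  res_sw <- dmp_test(m, rep(c("g2", "g1"), each = 10))
  expect_equal(res_sw$delta_beta, -res$delta_beta)
  expect_equal(res_sw$p, res$p)
})

test_that("longitudinal deltas, concordance and DMP overlap behave", {
  set.seed(6)
  info <- data.frame(probe_id = paste0("p", 1:50), promoter = TRUE,
                     snp = FALSE, chrom = "chr1")
  bl <- beta_matrix(matrix(runif(50 * 12, 0.4, 0.8), 50, 12,
                           dimnames = list(info$probe_id,
                                           paste0("S", 1:12))), info)
  post <- bl - 0.1
  attr(post, "probe_info") <- info
  pairing <- data.frame(baseline = colnames(bl), post = colnames(bl),
                        group = rep(c("a", "b"), each = 6))
  out <- longitudinal_delta_beta(bl, post, pairing)
  expect_equal(unname(out$delta[, "a"]), rep(0.1, 50))
  expect_equal(out$concordance, 1.0)
  # independent noise deltas -> concordance near 0
  post2 <- pmin(pmax(bl + matrix(rnorm(50 * 12, 0, 0.05), 50, 12), 0), 1)
  attr(post2, "probe_info") <- info
  out2 <- longitudinal_delta_beta(bl, post2, pairing)
  expect_lt(abs(out2$concordance), 0.35)
  # planted shared demethylation set -> overlap equals planted size
  set.seed(7)
  blg <- matrix(runif(50 * 20, 0.3, 0.5), 50, 20,
                dimnames = list(info$probe_id, paste0("T", 1:20)))
  blg[1:15, 11:20] <- blg[1:15, 11:20] + 0.3  # group-b hypermethylation
  blg <- beta_matrix(pmin(blg, 1), info)
  postg <- blg - 0.05
  attr(postg, "probe_info") <- info
  pg <- data.frame(baseline = colnames(blg), post = colnames(blg),
                   group = rep(c("a", "b"), each = 10))
  out3 <- longitudinal_delta_beta(blg, postg, pg)
  expect_equal(unname(out3$dmp_overlap["overlap"]), 15L)
  expect_equal(unname(out3$dmp_overlap["baseline_only"]), 0L)
})
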