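# Promoter methylation analysis: probe filtering, top-variance CpG
# selection, consensus k-means clustering of samples, differential
# methylation (DMP) testing with BH correction, and longitudinal
# delta-beta / concordance analyses.
#
# A beta matrix is a numeric matrix (probes x samples) with values in
# [0,1] plus a probe-annotation data.frame carried as attribute
# "probe_info" with columns: probe_id, promoter (logical), snp (logical),
# chrom. Inputs are assumed normalized (array normalization is upstream
# and out of scope).

#' Construct a beta matrix with probe annotation
#'
#' @param beta numeric matrix probes x samples, values in \[0,1\];
#'   rownames are probe ids.
#' @param probe_info data.frame with columns `probe_id`, `promoter`,
#'   `snp`, `chrom`, aligned with the rows of `beta`.
#' @return the matrix with `probe_info` attached as an attribute.
#' @export
beta_matrix <- function(beta, probe_info) {
  stopifnot(nrow(beta) == nrow(probe_info))
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_input("beta values must lie in [0,1]")
  rownames(beta) <- probe_info$probe_id
  attr(beta, "probe_info") <- probe_info
  beta
}

probe_info <- function(mat) {
  pi <- attr(mat, "probe_info")
  if (is.null(pi)) stop_input("matrix has no probe_info annotation")
  pi
}

subset_probes <- function(mat, keep) {
  out <- mat[keep, , drop = FALSE]
  attr(out, "probe_info") <- probe_info(mat)[keep, , drop = FALSE]
  out
}

#' Remove SNP-related probes and sex-chromosome probes
#'
#' Standard EPIC-array hygiene before clustering: drops probes flagged as
#' SNP-related and probes on chromosomes X and Y. Samples are unchanged.
#'
#' @param mat beta matrix from [beta_matrix()].
#' @return filtered beta matrix (possibly empty, with a warning).
#' @export
filter_probes <- function(mat) {
  pi <- probe_info(mat)
  keep <- !pi$snp & !(pi$chrom %in% c("chrX", "chrY", "X", "Y"))
  if (!any(keep)) warning("all probes removed by SNP/sex-chromosome filter")
  subset_probes(mat, keep)
}

#' Select promoter probes among the most variably methylated CpGs
#'
#' Per-probe variance is computed across all samples of the filtered
#' matrix; the top `top_fraction` most variable probes are taken and then
#' intersected with promoter-flagged probes.
#'
#' @param mat filtered beta matrix.
#' @param top_fraction fraction of probes to keep by variance
#'   (default 0.01, i.e. the top 1\%).
#' @return beta matrix restricted to variable promoter probes.
#' @export
select_top_variable_promoter_cpgs <- function(mat, top_fraction = 0.01) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop_input("`top_fraction` must be in (0,1]")
  v <- apply(mat, 1L, stats::var)
  n_top <- max(1L, floor(nrow(mat) * top_fraction))
  top <- rank(-v, ties.method = "first") <= n_top
  subset_probes(mat, top & probe_info(mat)$promoter)
}

# k-means++ seeding: spread initial centers by squared-distance sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  min_d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(min_d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      i <- sample.int(n, 1L, prob = min_d2)
      centers[j, ] <- x[i, ]
      d2 <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      min_d2 <- pmin(min_d2, d2)
    }
  }
  centers
}

# Euclidean k-means with k-means++ init and lowest-inertia restarts
kmeans_pp <- function(x, k, nstart = 10) {
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- unique(kmeanspp_centers(x, k))
    fit <- suppressWarnings(
      stats::kmeans(x, centers = if (nrow(centers) < k) k else centers,
                    iter.max = 50))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Consensus k-means clustering of samples
#'
#' For each k, k-means (Euclidean, k-means++ seeding, 10 restarts) is run
#' on `n_resamples` random subsets of `subsample_fraction` of the samples;
#' for every pair of co-sampled samples the frequency of co-assignment is
#' accumulated into a consensus matrix. The final partition is a k-means
#' clustering of the consensus-matrix rows. Cluster labels are then
#' ordered by grand-mean beta so that "cluster 2" is always the
#' relatively hypermethylated group, matching the field convention for
#' IDH-mutant AML methylation clusters.
#'
#' @param mat beta matrix (probes x samples); typically the output of
#'   [select_top_variable_promoter_cpgs()].
#' @param k_range integer vector of cluster counts to evaluate
#'   (default 2).
#' @param n_resamples subsampling iterations per k (default 1000; 100 is
#'   adequate in tests).
#' @param subsample_fraction fraction of samples per resample
#'   (default 0.8).
#' @param seed integer seed for the resampling draws.
#' @return list of class `consensus_result`: `k` (selected k, highest
#'   stability), `assignments` (named integer vector), `consensus`
#'   (matrix for the selected k), `stability` (named numeric per k),
#'   `per_k` (per-k assignments and consensus matrices).
#' @export
consensus_kmeans_cluster <- function(mat, k_range = 2, n_resamples = 1000,
                                     subsample_fraction = 0.8, seed = 1) {
  n <- ncol(mat)
  if (n < 2L) stop_input("need >= 2 samples")
  if (any(k_range > n)) stop_input("k exceeds the number of samples")
  x <- t(mat)
  per_k <- list()
  stability <- stats::setNames(numeric(length(k_range)),
                               as.character(k_range))
  set.seed(seed)
  for (k in k_range) {
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    m <- max(2L, floor(subsample_fraction * n))
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, m)
      fit <- kmeans_pp(x[idx, , drop = FALSE], min(k, m))
      same <- outer(fit$cluster, fit$cluster, "==")
      co[idx, idx] <- co[idx, idx] + same
      tog[idx, idx] <- tog[idx, idx] + 1
    }
    cons <- ifelse(tog > 0, co / tog, 0)
    diag(cons) <- 1
    assign_fit <- kmeans_pp(cons, k)
    cl <- assign_fit$cluster
    # relabel so mean beta increases with cluster index (cluster 2 = hyper)
    grand <- colMeans(mat)
    ord <- order(tapply(grand, cl, mean))
    relab <- integer(k); relab[ord] <- seq_len(k)
    cl <- relab[cl]
    names(cl) <- colnames(mat)
    same_cl <- outer(cl, cl, "==")
    off <- upper.tri(cons)
    within_mean <- mean(cons[off & same_cl])
    between_mean <- if (any(off & !same_cl)) mean(cons[off & !same_cl]) else 0
    stability[as.character(k)] <- within_mean - between_mean
    dimnames(cons) <- list(colnames(mat), colnames(mat))
    per_k[[as.character(k)]] <- list(assignments = cl, consensus = cons)
  }
  k_best <- k_range[which.max(stability)]
  structure(list(k = k_best,
                 assignments = per_k[[as.character(k_best)]]$assignments,
                 consensus = per_k[[as.character(k_best)]]$consensus,
                 stability = stability, per_k = per_k),
            class = "consensus_result")
}

#' Differentially methylated probe (DMP) testing
#'
#' Per-probe two-sided Welch t-test of beta values between two sample
#' groups, with Benjamini-Hochberg FDR correction. This deliberately
#' replaces a moderated-t pipeline with the plain Welch statistic: the
#' analysis target (DMP sets at a BH FDR) is preserved in structure.
#'
#' @param mat beta matrix.
#' @param group_labels vector over samples with exactly two levels; the
#'   sorted second level is "group 2" (direction `hyper` means higher
#'   beta in group 2).
#' @param fdr significance threshold on BH q-values (default 0.05).
#' @return data.frame: `probe_id`, `mean1`, `mean2`, `delta_beta`
#'   (group2 - group1), `t`, `p`, `q`, `direction`, `significant`.
#' @export
dmp_test <- function(mat, group_labels, fdr = 0.05) {
  res <- row_welch(mat, group_labels)
  q <- stats::p.adjust(res$p, method = "BH")
  data.frame(probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             mean1 = res$mean1, mean2 = res$mean2, delta_beta = res$delta,
             t = res$t, p = res$p, q = q,
             direction = ifelse(res$delta >= 0, "hyper", "hypo"),
             significant = q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Longitudinal delta-beta and cross-group concordance analysis
#'
#' For paired baseline/post sample sets, computes per-probe mean paired
#' deltas (baseline minus post, so demethylation is positive), the
#' per-sample mean-methylation trend, and -- when a two-level grouping is
#' supplied -- the cross-group concordance of the per-probe deltas
#' (Pearson correlation) and the overlap of between-group DMP sets called
#' at baseline and at post (Venn counts).
#'
#' @param mat_baseline,mat_post beta matrices with identical probes.
#' @param pairing data.frame with columns `baseline`, `post` naming the
#'   paired sample columns (and optionally `group`).
#' @param fdr FDR threshold for the DMP-overlap component.
#' @return list: `delta` (per-probe mean delta per group, or overall),
#'   `sample_trend` (per-pair mean beta at both timepoints),
#'   `concordance` (correlation of per-probe deltas between the two
#'   groups; NA if no grouping), `dmp_overlap` (counts baseline-only /
#'   overlap / post-only of significant between-group probes; NULL if no
#'   grouping).
#' @export
longitudinal_delta_beta <- function(mat_baseline, mat_post, pairing,
                                    fdr = 0.05) {
  stopifnot(nrow(mat_baseline) == nrow(mat_post))
  b <- mat_baseline[, pairing$baseline, drop = FALSE]
  p <- mat_post[, pairing$post, drop = FALSE]
  d <- b - p
  sample_trend <- data.frame(baseline = pairing$baseline,
                             post = pairing$post,
                             mean_baseline = colMeans(b),
                             mean_post = colMeans(p),
                             row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(pairing$group)) {
    return(list(delta = rowMeans(d), sample_trend = sample_trend,
                concordance = NA_real_, dmp_overlap = NULL))
  }
  groups <- sort(unique(as.character(pairing$group)))
  if (length(groups) != 2L)
    stop_input("`pairing$group` must have exactly two levels")
  g1 <- pairing$group == groups[1L]
  delta <- cbind(rowMeans(d[, g1, drop = FALSE]),
                 rowMeans(d[, !g1, drop = FALSE]))
  colnames(delta) <- groups
  # a uniform shift leaves no variance for a correlation: two groups that
  # moved by the same constant are perfectly concordant by definition
  if (stats::sd(delta[, 1L]) < 1e-10 && stats::sd(delta[, 2L]) < 1e-10) {
    concordance <- if (max(abs(delta[, 1L] - delta[, 2L])) < 1e-10) 1
                   else NA_real_
  } else {
    concordance <- stats::cor(delta[, 1L], delta[, 2L])
  }
  lab <- as.character(pairing$group)
  dmp_b <- dmp_test(b, lab, fdr = fdr)
  dmp_p <- dmp_test(p, lab, fdr = fdr)
  sig_b <- dmp_b$probe_id[dmp_b$significant]
  sig_p <- dmp_p$probe_id[dmp_p$significant]
  overlap <- c(baseline_only = length(setdiff(sig_b, sig_p)),
               overlap = length(intersect(sig_b, sig_p)),
               post_only = length(setdiff(sig_p, sig_b)))
  list(delta = delta, sample_trend = sample_trend,
       concordance = concordance, dmp_overlap = overlap)
}
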