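# Expression analytics: LSC17 leukemia-stemness scoring, simplified
# differential expression on log2 values, and a minimal preranked
# running-sum enrichment statistic with a permutation p-value.

#' The 17-gene leukemia stem cell (LSC17) signature
#'
#' Published gene/weight pairs of the LSC17 stemness score. A higher
#' score indicates a more stem-like, chemoresistant expression profile.
#' Gene aliases (KIAA0125 = FAM30A, NGFRAP1 = BEX3, GPR56 = ADGRG1) are
#' resolved through the packaged alias table before scoring.
#'
#' @return named numeric vector of 17 coefficients.
#' @export
lsc17_signature <- function() {
  c(DNMT3B = 0.0874, ZBTB46 = -0.0347, NYNRIN = 0.00865,
    ARHGAP22 = -0.0138, LAPTM4B = 0.00582, MMRN1 = 0.0258,
    DPYSL3 = 0.0284, KIAA0125 = 0.0196, CDK6 = -0.0704,
    CPXM1 = -0.0258, SOCS2 = 0.0271, SMIM24 = -0.0226,
    EMP1 = 0.0146, NGFRAP1 = 0.0465, CD34 = 0.0338,
    AKR1C3 = -0.0402, GPR56 = 0.0501)
}

# editable alias table: current symbol -> signature symbol
lsc17_aliases <- function() {
  path <- system.file("extdata", "gene_aliases.tsv", package = "idhres")
  tab <- read_tsv_table(path)
  stats::setNames(tab$signature_symbol, tab$alias)
}

#' Compute the LSC17 stemness score
#'
#' Weighted sum of 17 normalized log2 expression values. The absolute
#' score scale depends on the upstream normalization, so only relative
#' comparisons within one normalized dataset are meaningful.
#'
#' @param expr named numeric vector (gene -> log2 expression) or a
#'   genes x samples matrix with rownames.
#' @param signature named coefficient vector (default the published 17).
#' @param impute_missing if TRUE, absent signature genes contribute 0;
#'   by default a missing gene is an error naming the gene.
#' @return numeric score (one per sample for matrix input).
#' @export
lsc17_score <- function(expr, signature = lsc17_signature(),
                        impute_missing = FALSE) {
  if (is.matrix(expr)) {
    return(apply(expr, 2L, lsc17_score, signature = signature,
                 impute_missing = impute_missing))
  }
  nm <- names(expr)
  al <- lsc17_aliases()
  hit <- nm %in% names(al)
  nm[hit] <- unname(al[nm[hit]])
  names(expr) <- nm
  missing <- setdiff(names(signature), nm)
  if (length(missing) && !impute_missing)
    stop_input("missing LSC17 signature gene(s): ",
               paste(missing, collapse = ", "))
  vals <- expr[names(signature)]
  vals[is.na(vals)] <- 0
  sum(signature * vals)
}

#' Simplified differential expression between two groups
#'
#' Per-gene two-sided Welch t-test on normalized log2 values with BH
#' correction; log fold-change is mean(group 2) - mean(group 1). A
#' count-model pipeline is deliberately replaced by this simpler test,
#' which preserves the analysis structure (gene sets at a BH FDR).
#'
#' @param mat genes x samples matrix of log2 expression.
#' @param group_labels two-level vector over samples.
#' @param fdr BH threshold (default 0.05).
#' @return data.frame: `gene`, `lfc`, `t`, `p`, `q`, `significant`.
#' @export
differential_expression <- function(mat, group_labels, fdr = 0.05) {
  res <- row_welch(mat, group_labels)
  q <- stats::p.adjust(res$p, method = "BH")
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             lfc = res$delta, t = res$t, p = res$p, q = q,
             significant = q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov-style running-sum enrichment score
running_sum_es <- function(ranked_stats, in_set) {
  w <- abs(ranked_stats)
  nh <- sum(in_set)
  miss_step <- 1 / (length(ranked_stats) - nh)
  wsum <- sum(w[in_set])
  if (wsum == 0) { # all-zero weights: fall back to unweighted steps
    hit_step <- rep(1 / nh, length(ranked_stats))
  } else {
    hit_step <- w / wsum
  }
  steps <- ifelse(in_set, hit_step, -miss_step)
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Minimal preranked gene-set enrichment statistic
#'
#' Genes are ordered by decreasing ranking statistic; a weighted
#' running sum (weight = |statistic|, exponent 1) increments at set
#' members and decrements elsewhere. The enrichment score (ES) is the
#' maximum deviation of the running sum; its sign gives the direction.
#' The p-value comes from random gene-label permutations of the set:
#' p = (1 + #\{|ES_perm| >= |ES|\}) / (n_permutations + 1).
#'
#' @param stats_by_gene named numeric vector, gene -> ranking statistic.
#' @param gene_set character vector, a subset of the ranked universe
#'   with at least 5 members.
#' @param n_permutations permutation count (default 1000).
#' @param seed integer seed for the permutations.
#' @return list of class `enrichment_result`: `es`, `p`, `direction`,
#'   `set_size`.
#' @export
preranked_enrichment <- function(stats_by_gene, gene_set,
                                 n_permutations = 1000, seed = 1) {
  if (length(gene_set) == 0L) stop_input("empty gene set")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% names(stats_by_gene)))
    stop_input("gene_set must be a subset of the ranked universe")
  if (length(gene_set) < 5L)
    stop_input("gene_set needs >= 5 members")
  ord <- order(stats_by_gene, decreasing = TRUE)
  s <- stats_by_gene[ord]
  in_set <- names(s) %in% gene_set
  es <- running_sum_es(s, in_set)
  nh <- sum(in_set)
  set.seed(seed)
  n_extreme <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- logical(length(s))
    perm[sample.int(length(s), nh)] <- TRUE
    if (abs(running_sum_es(s, perm)) >= abs(es)) n_extreme <- n_extreme + 1L
  }
  structure(list(es = es, p = (1 + n_extreme) / (n_permutations + 1),
                 direction = if (es >= 0) "up" else "down",
                 set_size = nh),
            class = "enrichment_result")
}
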