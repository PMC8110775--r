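# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity with the most naive method
# available (explicit loops, exhaustive enumeration, closed forms) and
# share no code with the package internals.

# --- naive per-variant re-evaluation of the filtering + tier rules ----
oracle_variant_verdict <- function(v, cosmic, tsg, popfreq, damaging) {
  # popfreq / damaging are lookup data.frames keyed by chrom:pos:ref:alt
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  freq <- 0
  if (nrow(popfreq)) {
    hit <- paste(popfreq$chrom, popfreq$pos, popfreq$ref,
                 popfreq$alt, sep = ":") == key
    if (any(hit)) freq <- popfreq$frequency[hit][1]
  }
  coding <- tolower(v$consequence) %in%
    c("missense", "nonsense", "stop_gain", "stop-gain", "stop_loss",
      "stop-loss", "frameshift", "inframe_indel", "in-frame_indel",
      "splicing", "splice_site", "splice-site")
  pass <- TRUE
  if (v$tumor_depth < 15) pass <- FALSE
  if (v$tumor_vaf < 0.05) pass <- FALSE
  if (v$variant_class == "indel") {
    if (v$normal_vaf != 0) pass <- FALSE
  } else {
    if (v$normal_vaf >= 0.01) pass <- FALSE
  }
  if (!coding) pass <- FALSE
  if (freq >= 0.0014) pass <- FALSE
  if (!pass) return(list(kept = FALSE, tier = NA_integer_))
  dmg <- FALSE
  if (nrow(damaging)) {
    hit <- paste(damaging$chrom, damaging$pos, damaging$ref,
                 damaging$alt, sep = ":") == key
    if (any(hit)) dmg <- isTRUE(damaging$damaging[hit][1])
  }
  tier <- NA_integer_
  has_pos <- !is.na(v$protein_pos)
  lof <- tolower(v$consequence) %in%
    c("splicing", "splice_site", "splice-site", "stop_gain", "stop-gain",
      "nonsense", "stop_loss", "stop-loss", "frameshift")
  exact <- has_pos && !is.na(v$protein_change) &&
    any(cosmic$gene == v$gene & cosmic$protein_change == v$protein_change)
  samepos <- has_pos &&
    any(cosmic$gene == v$gene & cosmic$protein_pos == v$protein_pos)
  near <- has_pos &&
    any(cosmic$gene == v$gene &
          abs(cosmic$protein_pos - v$protein_pos) <= 3)
  if (exact) tier <- 1L
  else if (lof && v$gene %in% tsg) tier <- 2L
  else if (samepos) tier <- 3L
  else if (near && dmg) tier <- 4L
  list(kept = TRUE, tier = tier)
}

# random annotated variant universe for the oracle sweep
random_variant_universe <- function(n, seed) {
  set.seed(seed)
  genes <- paste0("GENE", 1:8)
  cosmic <- data.frame(gene = sample(genes, 12, replace = TRUE),
                       protein_pos = sample(1:60, 12, replace = TRUE),
                       stringsAsFactors = FALSE)
  cosmic$protein_change <- paste0("A", cosmic$protein_pos, "T")
  tsg <- sample(genes, 3)
  calls <- data.frame(
    patient_id = "PX", timepoint = "baseline",
    gene = sample(genes, n, replace = TRUE),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample(1:2000, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    variant_class = sample(c("SNV", "indel"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
    consequence = sample(c("missense", "synonymous", "frameshift",
                           "splicing", "stop_gain", "noncoding"),
                         n, replace = TRUE),
    protein_pos = ifelse(runif(n) < 0.9,
                         sample(1:60, n, replace = TRUE), NA),
    tumor_depth = sample(c(5:20, 100:400), n, replace = TRUE),
    tumor_vaf = round(runif(n, 0, 0.6), 3),
    normal_vaf = sample(c(0, 0, 0, 0.005, 0.02, 0.4), n, replace = TRUE),
    stringsAsFactors = FALSE)
  calls$protein_change <- ifelse(
    is.na(calls$protein_pos), NA,
    paste0(sample(c("A", "R"), n, replace = TRUE), calls$protein_pos,
           sample(c("T", "G"), n, replace = TRUE)))
  # population-frequency and damaging annotations on random subsets
  idx_pf <- sample(n, n %/% 5)
  popfreq <- data.frame(chrom = calls$chrom[idx_pf], pos = calls$pos[idx_pf],
                        ref = calls$ref[idx_pf], alt = calls$alt[idx_pf],
                        frequency = sample(c(0.0005, 0.0014, 0.01),
                                           length(idx_pf), replace = TRUE),
                        stringsAsFactors = FALSE)
  idx_dm <- sample(n, n %/% 3)
  damaging <- data.frame(chrom = calls$chrom[idx_dm], pos = calls$pos[idx_dm],
                         ref = calls$ref[idx_dm], alt = calls$alt[idx_dm],
                         damaging = sample(c(TRUE, FALSE), length(idx_dm),
                                           replace = TRUE),
                         stringsAsFactors = FALSE)
  list(calls = calls, cosmic = cosmic, tsg = tsg, popfreq = popfreq,
       damaging = damaging)
}

# --- exhaustive two-sided Fisher p by table enumeration ---------------
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  tab_prob <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  p_obs <- tab_prob(a)
  total <- 0
  for (x in lo:hi) {
    px <- tab_prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

# --- O(n^2) pairwise-comparison AUROC ---------------------------------
oracle_auroc <- function(scores, outcome) {
  pos <- scores[outcome == 1]; neg <- scores[outcome == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# --- sorted-rank Benjamini-Hochberg -----------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# --- adjusted Rand index from the contingency table -------------------
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
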