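# Response-association statistics: Fisher exact enrichment with odds
# ratios and Woolf CIs, response-rate comparisons, ROC/AUROC, logistic
# regression by IRLS, starburst methylation x expression integration,
# and a two-group log-rank relapse-free-survival comparison.

# Exact two-sided Fisher p for a 2x2 table by the minimum-likelihood
# convention: sum of hypergeometric probabilities of all tables (with
# the observed margins) whose probability does not exceed the observed
# table's. A small relative tolerance absorbs floating-point ties.
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 margin (successes in population)
  n <- sum(tab[2, ])   # row-2 margin
  k <- sum(tab[, 1])   # column-1 margin (draws)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(1, p), support = support, probs = probs)
}

#' Fisher exact enrichment of a binary feature against a binary outcome
#'
#' Builds the 2x2 table (feature x outcome), reports the sample odds
#' ratio (ad/bc, uncorrected), a Woolf logit 95\% confidence interval
#' (with a Haldane-Anscombe 0.5 correction applied only when some cell
#' is zero, and only for the CI), and the exact two-sided Fisher p-value
#' (minimum-likelihood convention). Pairs with a missing outcome are
#' dropped.
#'
#' @param feature,outcome logical (or 0/1) vectors of equal length.
#' @param conf_level CI coverage (default 0.95).
#' @return one-row data.frame: cell counts `a` (feature+, outcome+),
#'   `b`, `c`, `d`, `odds_ratio`, `ci_lo`, `ci_hi`, `p`.
#' @export
fisher_enrichment <- function(feature, outcome, conf_level = 0.95) {
  if (length(feature) != length(outcome))
    stop_input("feature and outcome must have equal length")
  keep <- !is.na(outcome) & !is.na(feature)
  feature <- feature[keep]; outcome <- outcome[keep]
  if (!all(feature %in% c(0, 1)) || !all(outcome %in% c(0, 1)))
    stop_input("feature and outcome must be binary")
  a <- sum(feature == 1 & outcome == 1)
  b <- sum(feature == 1 & outcome == 0)
  c_ <- sum(feature == 0 & outcome == 1)
  d <- sum(feature == 0 & outcome == 0)
  or <- (a * d) / (b * c_)  # may be 0, Inf or NaN for degenerate tables
  cc <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
  lo <- log((a + cc) * (d + cc) / ((b + cc) * (c_ + cc)))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))$p
  data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or,
             ci_lo = exp(lo - z * se), ci_hi = exp(lo + z * se), p = p)
}

#' Per-group response rates with a between-group Fisher comparison
#'
#' Rates are computed over evaluable patients only (missing responses are
#' excluded from the denominator). With exactly two groups a Fisher
#' exact p for the rate difference is included.
#'
#' @param response logical/0-1 vector (NA = not assessed).
#' @param group grouping vector.
#' @return list: `rates` data.frame (`group`, `n_evaluable`,
#'   `n_response`, `rate`; empty groups get NA rate and a flag),
#'   `p` (two-group Fisher p or NA).
#' @export
response_rates <- function(response, group) {
  if (length(response) != length(group))
    stop_input("response and group must have equal length")
  groups <- unique(as.character(group))
  rows <- lapply(groups, function(g) {
    r <- response[group == g]
    n_eval <- sum(!is.na(r))
    data.frame(group = g, n_evaluable = n_eval,
               n_response = sum(r, na.rm = TRUE),
               rate = if (n_eval) sum(r, na.rm = TRUE) / n_eval else NA_real_,
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rows)
  p <- NA_real_
  if (length(groups) == 2L && all(rates$n_evaluable > 0)) {
    keep <- !is.na(response)
    p <- fisher_enrichment(as.integer(group[keep] == groups[1L]),
                           as.integer(response[keep]))$p
  }
  list(rates = rates, p = p)
}

#' AUROC and ROC curve by the Mann-Whitney construction
#'
#' AUROC is the tie-corrected Mann-Whitney U statistic divided by
#' n1 x n0: the probability that a random positive outscores a random
#' negative, with ties counting one half. The curve enumerates all
#' distinct score thresholds. When `direction = "auto"` the score is
#' flipped if AUROC < 0.5 so the reported AUROC is always >= 0.5 and the
#' orientation used is returned.
#'
#' @param scores numeric predictor.
#' @param outcome binary outcome (1 = positive class).
#' @param direction `">"` (higher score predicts positive), `"<"`, or
#'   `"auto"`.
#' @return list: `auroc`, `direction`, `curve` (data.frame `threshold`,
#'   `tpr`, `fpr`).
#' @export
auroc <- function(scores, outcome, direction = ">") {
  keep <- !is.na(scores) & !is.na(outcome)
  scores <- scores[keep]; outcome <- as.integer(outcome[keep])
  if (!all(outcome %in% c(0L, 1L))) stop_input("outcome must be binary")
  n1 <- sum(outcome == 1L); n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) stop_input("need both classes present")
  auc_for <- function(s) {
    r <- rank(s)  # midranks give the tie-half convention
    (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  used <- direction
  a <- auc_for(scores)
  if (direction == "<" || (direction == "auto" && a < 0.5)) {
    scores <- -scores
    a <- auc_for(scores)
    used <- "<"
  } else if (direction == "auto") used <- ">"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & outcome == 1L) / n1,
                 numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & outcome == 0L) / n0,
                 numeric(1)))
  list(auroc = a, direction = used, curve = curve)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary-outcome logistic model with Wald
#' standard errors, z statistics and p-values. Complete cases only.
#' Perfect or quasi-perfect separation is detected (diverging
#' coefficients / degenerate fitted probabilities) and flagged; no
#' estimates are returned in that case.
#'
#' @param design numeric matrix or data.frame of covariates (an
#'   intercept column is added automatically).
#' @param outcome binary vector.
#' @param tol convergence tolerance on the coefficient change
#'   (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 50).
#' @return list of class `logistic_fit`: `coefficients` data.frame
#'   (`term`, `estimate`, `std_error`, `z`, `p`), `converged`,
#'   `separation`, `n`.
#' @export
fit_logistic <- function(design, outcome, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(design)
  if (ncol(X) && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(outcome)
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(outcome[keep])
  if (!all(y %in% c(0, 1))) stop_input("outcome must be binary")
  X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, .Machine$double.eps)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  mu <- stats::plogis(drop(X %*% beta))
  separation <- !converged && all(mu < 1e-6 | mu > 1 - 1e-6) ||
    max(abs(beta)) > 30
  if (separation) {
    return(structure(list(coefficients = NULL, converged = FALSE,
                          separation = TRUE, n = length(y)),
                     class = "logistic_fit"))
  }
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  cov_beta <- solve(t(X * w) %*% X)
  se <- sqrt(diag(cov_beta))
  zv <- beta / se
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta,
                              std_error = se, z = zv,
                              p = 2 * stats::pnorm(-abs(zv)),
                              row.names = NULL, stringsAsFactors = FALSE),
    converged = converged, separation = FALSE, n = length(y)),
    class = "logistic_fit")
}

#' Starburst integration of differential methylation and expression
#'
#' Joins per-CpG methylation results with the differential-expression
#' result of each CpG's linked gene. A CpG is double-significant when
#' both its methylation q-value and its gene's expression q-value fall
#' below `fdr`; double-significant CpGs are assigned a quadrant by the
#' signs of delta-beta and log fold-change.
#'
#' @param dmp data.frame from [dmp_test()].
#' @param de data.frame from [differential_expression()].
#' @param cpg_gene data.frame with columns `probe_id`, `gene` (each CpG
#'   links to at most one gene).
#' @param fdr threshold applied to both q-values (default 0.05).
#' @return list: `table` (per linked CpG: quadrant or NA), `counts`
#'   (named vector hyper_down, hyper_up, hypo_down, hypo_up),
#'   `n_double_significant`.
#' @export
starburst_integration <- function(dmp, de, cpg_gene, fdr = 0.05) {
  if (anyDuplicated(cpg_gene$probe_id))
    stop_input("every CpG must link to at most one gene")
  m <- merge(cpg_gene, dmp[, c("probe_id", "delta_beta", "q")],
             by = "probe_id")
  names(m)[names(m) == "q"] <- "q_meth"
  m <- merge(m, de[, c("gene", "lfc", "q")], by = "gene")
  names(m)[names(m) == "q"] <- "q_expr"
  double_sig <- m$q_meth < fdr & m$q_expr < fdr
  quadrant <- ifelse(!double_sig, NA_character_,
                     paste0(ifelse(m$delta_beta >= 0, "hyper", "hypo"),
                            "_", ifelse(m$lfc <= 0, "down", "up")))
  m$quadrant <- quadrant
  counts <- vapply(c("hyper_down", "hyper_up", "hypo_down", "hypo_up"),
                   function(qd) sum(quadrant == qd, na.rm = TRUE),
                   integer(1))
  list(table = m, counts = counts,
       n_double_significant = sum(double_sig))
}

#' Two-group log-rank comparison of relapse-free survival
#'
#' Standard log-rank test honoring right-censoring, with per-group
#' median survival from the Kaplan-Meier estimate.
#'
#' @param time time to relapse or censoring.
#' @param event 1 = relapse observed, 0 = censored.
#' @param group two-level grouping vector.
#' @return list: `chisq`, `p`, `medians` (named per group), `n_events`;
#'   if no events occurred, `p` is NA and `flag` explains.
#' @export
logrank_rfs <- function(time, event, group) {
  if (length(unique(group)) != 2L) stop_input("need exactly two groups")
  if (sum(event) == 0L)
    return(list(chisq = NA_real_, p = NA_real_, medians = NULL,
                n_events = 0L, flag = "no events (all censored)"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  med <- summary(fit)$table[, "median"]
  list(chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       medians = med, n_events = sum(event), flag = NULL)
}
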