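# Fisher enrichment, response rates, AUROC, logistic regression,
# starburst integration and log-rank survival

test_that("fisher enrichment handles symmetric and degenerate tables", {
  # table [[2,2],[2,2]]
  f <- rep(c(1, 0), each = 4)
  o <- rep(c(1, 0, 1, 0), each = 2)
  row <- fisher_enrichment(f, o)
  expect_equal(row$odds_ratio, 1.0)
  expect_equal(row$p, 1.0)
  expect_true(row$ci_lo <= 1 && row$ci_hi >= 1)
  # table [[0,10],[10,0]]: OR 0 uncorrected, p from exact enumeration
  f2 <- rep(c(1, 0), each = 10)
  o2 <- rep(c(1, 0), times = 10)[order(rep(c(1, 0), each = 10),
                                       decreasing = TRUE)]
  o2 <- c(rep(0, 10), rep(1, 10))
  row2 <- fisher_enrichment(f2, o2)
  expect_equal(row2$odds_ratio, 0)
  expect_equal(row2$p, oracle_fisher_p(0, 10, 10, 0))
  expect_error(fisher_enrichment(c(1, 2), c(0, 1)), "binary")
  expect_error(fisher_enrichment(1, c(0, 1)), "length")
})

test_that("fisher p matches exhaustive enumeration and fisher.test", {
  for (a in 0:6) for (b in 0:6) for (c_ in 0:6) for (d in 0:6) {
    if (a + b > 8 || c_ + d > 8 || a + c_ > 8 || b + d > 8) next
    if (a + b + c_ + d == 0) next
    p <- idhres:::fisher_exact_2x2(matrix(c(a, b, c_, d), 2, 2,
                                          byrow = TRUE))$p
    expect_equal(p, oracle_fisher_p(a, b, c_, d), tolerance = 1e-10,
                 info = paste(a, b, c_, d))
  }
  # spot-check against the reference implementation's convention
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_equal(idhres:::fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("response rates use evaluable denominators", {
  resp <- c(rep(1, 12), rep(0, 10), rep(1, 18), rep(0, 19), NA)
  grp <- c(rep("ivosidenib", 22), rep("enasidenib", 37), "ivosidenib")
  out <- response_rates(resp, grp)
  ivo <- out$rates[out$rates$group == "ivosidenib", ]
  expect_equal(ivo$n_evaluable, 22L)
  expect_equal(round(100 * ivo$rate, 1), 54.5)
  ena <- out$rates[out$rates$group == "enasidenib", ]
  expect_equal(round(100 * ena$rate, 1), 48.6)
  expect_gt(out$p, 0.05)  # the two arms do not differ
  # identical all-responder groups -> p = 1
  out2 <- response_rates(rep(1, 10), rep(c("a", "b"), 5))
  expect_equal(out2$rates$rate, c(1, 1))
  expect_equal(out2$p, 1.0)
})

test_that("auroc equals the pairwise oracle and handles degeneracy", {
  # perfectly separating scores
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auroc, 1.0)
  # all scores equal
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5))$auroc, 0.5)
  set.seed(42)
  for (i in 1:20) {
    sc <- round(rnorm(20), 1)  # rounding forces ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(sc, y)$auroc, oracle_auroc(sc, y))
  }
  # auto orientation reports the flip
  r <- auroc(c(5, 4, 3, 1, 0), c(1, 1, 1, 0, 0), direction = "auto")
  expect_equal(r$direction, ">")
  r2 <- auroc(-c(5, 4, 3, 1, 0), c(1, 1, 1, 0, 0), direction = "auto")
  expect_equal(r2$direction, "<")
  expect_equal(r2$auroc, 1.0)
  # curve endpoints
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("logistic fit matches glm on a fixture and flags separation", {
  set.seed(43)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(-1 + 0.8 * x))
  fit <- fit_logistic(cbind(x = x), y)
  ref <- stats::glm(y ~ x, family = binomial())
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$std_error,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-5)
  expect_equal(fit$coefficients$z,
               fit$coefficients$estimate / fit$coefficients$std_error)
  # intercept-only on a 50% outcome -> intercept ~ 0
  fit0 <- fit_logistic(matrix(numeric(0), 20, 0), rep(c(0, 1), 10))
  expect_lt(abs(fit0$coefficients$estimate[1]), 1e-6)
  # perfect separation -> flagged, no estimates
  sep <- fit_logistic(cbind(x = c(1:10, 21:30)),
                      rep(c(0, 1), each = 10))
  expect_true(sep$separation)
  expect_null(sep$coefficients)
})

test_that("null logistic p-values are uniform", {
  set.seed(44)
  ps <- vapply(1:200, function(i) {
    x <- rnorm(80)
    y <- rbinom(80, 1, 0.5)
    fit <- fit_logistic(cbind(x = x), y)
    fit$coefficients$p[2]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("starburst quadrants count double-significant CpGs", {
  dmp <- data.frame(probe_id = paste0("cg", 1:15),
                    delta_beta = c(rep(0.2, 12), rep(-0.2, 3)),
                    q = c(rep(0.001, 12), 0.001, 0.5, 0.5))
  de <- data.frame(gene = paste0("g", 1:15),
                   lfc = c(rep(-1, 10), rep(1, 2), -1, -1, -1),
                   q = c(rep(0.001, 13), 0.5, 0.5))
  link <- data.frame(probe_id = paste0("cg", 1:15),
                     gene = paste0("g", 1:15))
  out <- starburst_integration(dmp, de, link)
  expect_equal(unname(out$counts),
               c(10L, 2L, 1L, 0L))  # hyper_down, hyper_up, hypo_down, hypo_up
  expect_equal(out$n_double_significant, 13L)
  expect_equal(sum(out$counts), out$n_double_significant)
  # thresholds at 1.0 -> everything double-significant
  out2 <- starburst_integration(dmp, de, link, fdr = 1.000001)
  expect_equal(out2$n_double_significant, 15L)
  # no significant genes -> zero
  de0 <- de; de0$q <- 0.9
  expect_equal(starburst_integration(dmp, de0, link)$n_double_significant,
               0L)
  expect_error(starburst_integration(dmp, de, rbind(link, link[1, ])),
               "at most one gene")
})

test_that("log-rank comparison honors censoring and flags no-event input", {
  # identical groups -> statistic ~ 0
  t0 <- rep(c(1, 2, 3, 4, 5), 2)
  e0 <- rep(1, 10)
  g0 <- rep(c("a", "b"), each = 5)
  out <- logrank_rfs(t0, e0, g0)
  expect_lt(out$chisq, 1e-10)
  expect_gt(out$p, 0.99)
  # planted hazard difference is detected with power
  set.seed(45)
  detect <- vapply(1:50, function(i) {
    t1 <- rexp(100, 1); t2 <- rexp(100, 3)
    cens <- rexp(200, 0.2)
    tt <- pmin(c(t1, t2), cens)
    ee <- as.integer(c(t1, t2) <= cens)
    logrank_rfs(tt, ee, rep(c("a", "b"), each = 100))$p < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.9)
  # all censored
  out2 <- logrank_rfs(t0, rep(0, 10), g0)
  expect_true(is.na(out2$p))
  expect_match(out2$flag, "no events")
  expect_error(logrank_rfs(t0, e0, rep("a", 10)), "two groups")
})

test_that("end-to-end: stemness and cluster-2 associate with nonresponse", {
  co <- generate_cohort(cohort_config(n_probes = 2000, n_genes = 200,
                                      seed = 10))
  an <- run_cohort_analysis(co, n_resamples = 100, seed = 1)
  expect_gt(an$lsc17_by_response["nonresponder"],
            an$lsc17_by_response["responder"])
  expect_gt(an$cluster_vs_response$odds_ratio, 1)
  expect_gt(an$roc$auroc, 0.5)
  ras <- an$pathway_summary[an$pathway_summary$pathway == "RAS-RTK", ]
  expect_gt(ras$fraction, 0)
})
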