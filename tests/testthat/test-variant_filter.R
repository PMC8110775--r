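# filtering cascade boundary semantics and hierarchical tiers

make_call <- function(gene = "GENE1", variant_class = "SNV",
                      consequence = "missense", tumor_depth = 300,
                      tumor_vaf = 0.3, normal_vaf = 0, protein_pos = 10,
                      protein_change = "A10T", chrom = "chr1", pos = 100,
                      ref = "A", alt = "G") {
  data.frame(patient_id = "P1", timepoint = "baseline", gene = gene,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_class = variant_class, consequence = consequence,
             protein_pos = protein_pos, protein_change = protein_change,
             tumor_depth = tumor_depth, tumor_vaf = tumor_vaf,
             normal_vaf = normal_vaf, stringsAsFactors = FALSE)
}

empty_resource <- annotation_resource()

test_that("filter rules remove exactly the stated conditions", {
  cases <- rbind(
    cbind(make_call(tumor_depth = 14, tumor_vaf = 0.40), keep = FALSE),
    cbind(make_call(tumor_depth = 15), keep = TRUE),       # boundary kept
    cbind(make_call(tumor_vaf = 0.049), keep = FALSE),
    cbind(make_call(tumor_vaf = 0.05), keep = TRUE),       # boundary kept
    cbind(make_call(variant_class = "indel", tumor_vaf = 0.30,
                    normal_vaf = 0.004), keep = FALSE),    # indel: 0 only
    cbind(make_call(normal_vaf = 0.004), keep = TRUE),     # SNV: < 1% ok
    cbind(make_call(normal_vaf = 0.01), keep = FALSE),
    cbind(make_call(consequence = "synonymous"), keep = FALSE),
    cbind(make_call(consequence = "noncoding"), keep = FALSE))
  res <- apply_variant_filters(cases, empty_resource)
  expect_equal(nrow(res$kept), sum(cases$keep))
  expect_equal(res$verdicts$failed_rules[1], "coverage")
  expect_match(res$verdicts$failed_rules[5], "normal")
})

test_that("population-frequency threshold removes at exactly 0.14%", {
  pf <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "G",
                   frequency = c(0.0014, 0.00139))
  res <- annotation_resource(popfreq = pf)
  calls <- rbind(make_call(pos = 100), make_call(pos = 200),
                 make_call(pos = 300))
  out <- apply_variant_filters(calls, res)
  expect_equal(out$kept$pos, c(200, 300))
})

test_that("VAF outside [0,1] is an input error", {
  expect_error(apply_variant_filters(make_call(tumor_vaf = 1.2),
                                     empty_resource), "VAF")
})

test_that("tiers follow the hierarchy, lowest applicable rank wins", {
  cosmic <- data.frame(gene = "TSG1", protein_pos = 10,
                       protein_change = "A10T")
  res <- annotation_resource(cosmic = cosmic, tsg_genes = "TSG1")
  # exact COSMIC match that is also LoF-in-TSG context -> tier 1
  expect_equal(classify_confidence(make_call(gene = "TSG1"), res), 1L)
  # frameshift in TSG, no COSMIC record -> tier 2
  fs <- make_call(gene = "TSG1", consequence = "frameshift",
                  variant_class = "indel", protein_pos = 99,
                  protein_change = "fs99")
  expect_equal(classify_confidence(fs, res), 2L)
  # same position, different change -> tier 3
  expect_equal(classify_confidence(
    make_call(gene = "TSG1", protein_change = "A10G"), res), 3L)
  # 3 residues away + damaging -> tier 4; 4 residues away -> unclassified
  dmg <- data.frame(chrom = "chr1", pos = c(100, 101), ref = "A",
                    alt = "G", damaging = TRUE)
  res_d <- annotation_resource(cosmic = cosmic, tsg_genes = character(),
                               damaging = dmg)
  near <- make_call(gene = "TSG1", protein_pos = 13,
                    protein_change = "A13T")
  far <- make_call(gene = "TSG1", protein_pos = 14,
                   protein_change = "A14T", pos = 101)
  expect_equal(classify_confidence(near, res_d), 4L)
  expect_true(is.na(classify_confidence(far, res_d)))
  # missing protein position skips all position rules
  nopos <- make_call(gene = "TSG1", protein_pos = NA,
                     protein_change = NA)
  expect_true(is.na(classify_confidence(nopos, res)))
})

test_that("adding an exact COSMIC match can only lower the tier number", {
  v <- make_call(gene = "G1", protein_pos = 20, protein_change = "A20T")
  res0 <- annotation_resource(
    cosmic = data.frame(gene = "G1", protein_pos = 20,
                        protein_change = "A20G"))
  res1 <- annotation_resource(
    cosmic = data.frame(gene = "G1", protein_pos = c(20, 20),
                        protein_change = c("A20G", "A20T")))
  expect_equal(classify_confidence(v, res0), 3L)
  expect_equal(classify_confidence(v, res1), 1L)
})

test_that("pipeline deduplicates, filters and reports counts", {
  calls <- rbind(make_call(), make_call(),  # duplicate rows
                 make_call(consequence = "synonymous", pos = 500))
  cosmic <- data.frame(gene = "GENE1", protein_pos = 10,
                       protein_change = "A10T")
  out <- run_variant_pipeline(calls, annotation_resource(cosmic = cosmic))
  expect_equal(nrow(out$drivers), 1L)
  expect_equal(out$drivers$tier, 1L)
  expect_true(any(grepl("dedup", out$audit)))
  expect_equal(out$class_counts, c(1L, 0L))
  # all-synonymous input -> empty output, no error
  syn <- make_call(consequence = "synonymous")
  expect_equal(nrow(run_variant_pipeline(syn, empty_resource)$drivers), 0L)
  # empty input
  expect_equal(nrow(run_variant_pipeline(syn[0, ], empty_resource)$drivers),
               0L)
})

test_that("surviving set is invariant to filter-family order", {
  # rules are independent predicates; verify the conjunction matches
  # applying each family alone in any order on a random fixture
  u <- random_variant_universe(200, seed = 42)
  res <- annotation_resource(cosmic = u$cosmic, tsg_genes = u$tsg,
                             popfreq = u$popfreq, damaging = u$damaging)
  full <- apply_variant_filters(u$calls, res)
  v <- full$verdicts
  manual <- v$ok_depth & v$ok_vaf & v$ok_normal & v$ok_coding & v$ok_popfreq
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    fams <- list(v$ok_depth & v$ok_vaf & v$ok_normal, v$ok_coding,
                 v$ok_popfreq)[perm]
    expect_equal(Reduce(`&`, fams), manual)
  }
  expect_equal(nrow(full$kept), sum(manual))
})

test_that("pipeline agrees with the brute-force oracle on random variants", {
  u <- random_variant_universe(300, seed = 7)
  res <- annotation_resource(cosmic = u$cosmic, tsg_genes = u$tsg,
                             popfreq = u$popfreq, damaging = u$damaging)
  flt <- apply_variant_filters(u$calls, res)
  tiers <- rep(NA_integer_, nrow(u$calls))
  keep <- with(flt$verdicts, ok_depth & ok_vaf & ok_normal & ok_coding &
                 ok_popfreq)
  tiers[keep] <- classify_confidence(u$calls[keep, ], res)
  for (i in seq_len(nrow(u$calls))) {
    o <- oracle_variant_verdict(u$calls[i, ], u$cosmic, u$tsg,
                                u$popfreq, u$damaging)
    expect_equal(keep[i], o$kept, info = paste("row", i))
    expect_equal(tiers[i], o$tier, info = paste("row", i))
  }
})

test_that("resources round-trip through the TSV directory format", {
  dir <- withr::local_tempdir()
  write_tsv_table(data.frame(gene = "G1", protein_pos = 5,
                             protein_change = "A5T"),
                  file.path(dir, "cosmic.tsv"))
  writeLines(c("G1", "G2"), file.path(dir, "tsg.txt"))
  write_tsv_table(data.frame(chrom = "chr1", pos = 9, ref = "A", alt = "T",
                             frequency = 0.5),
                  file.path(dir, "popfreq.tsv"))
  res <- read_annotation_resources(dir)
  expect_equal(res$tsg_genes, c("G1", "G2"))
  expect_equal(classify_confidence(
    make_call(gene = "G1", protein_pos = 5, protein_change = "A5T"), res),
    1L)
  out <- apply_variant_filters(make_call(chrom = "chr1", pos = 9,
                                         ref = "A", alt = "T"), res)
  expect_equal(nrow(out$kept), 0L)
})
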