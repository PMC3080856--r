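# Synthetic-data generator: annotations, truth tables, arrays, qPCR.

test_that("annotations are unique, arm-consistent and reproducible", {
  ann <- generate_annotation(8073, seed = 1)
  expect_equal(nrow(ann), 8073)
  expect_equal(anyDuplicated(ann$gene_id), 0L)
  expect_true(all(ann$division >= 1 & ann$division <= 102))
  # divisions must match each gene's arm range and position its arm length
  ranges <- list(X = 1:20, `2L` = 21:40, `2R` = 41:60, `3L` = 61:80,
                 `3R` = 81:100, `4` = 101:102)
  lens <- default_arm_lengths()
  for (a in names(ranges)) {
    sub <- ann[ann$arm == a, ]
    expect_true(all(sub$division %in% ranges[[a]]))
    expect_true(all(sub$position_mb >= 0 & sub$position_mb < lens[[a]]))
  }
  expect_identical(ann, generate_annotation(8073, seed = 1))
})

test_that("single-gene and invalid-parameter annotation cases", {
  one <- generate_annotation(1, arm_lengths_mb = c(`2L` = 20), seed = 3)
  expect_equal(nrow(one), 1)
  expect_true(one$division >= 21 && one$division <= 40)
  expect_error(generate_annotation(0), "n_genes")
  expect_error(generate_annotation(10, arm_lengths_mb = c(X = -1)), "positive")
  expect_error(generate_annotation(10, arm_lengths_mb = c(Z = 5)), "unknown arm")
})

test_that("arm assignment is proportional to arm length (binomial oracle)", {
  lens <- c(X = 22, `2L` = 23, `2R` = 21, `3L` = 24, `3R` = 28.7, `4` = 1.3)
  ann <- generate_annotation(2000, arm_lengths_mb = lens, seed = 7)
  p <- 22 / sum(lens)
  expected <- 2000 * p
  sd4 <- 4 * sqrt(2000 * p * (1 - p))
  expect_lt(abs(sum(ann$arm == "X") - expected), sd4)
})

test_that("truth effects scale exactly with severity and respect nulls", {
  ann <- generate_annotation(2000, seed = 2)
  tr <- generate_truth(ann, frac_sensitive = 0.1,
                       severity = c(wt = 0, mild = 0.35, gross = 1),
                       seed = 5)
  g <- tr$genes
  expect_equal(sum(g$sensitive), 200)
  expect_equal(g$effect_mild, g$base_effect * 0.35)
  expect_equal(g$effect_gross, g$base_effect)
  expect_true(all(g$effect_wt == 0))
  expect_true(all(g$base_effect[!g$sensitive] == 0))
  # sign consistency and magnitude ordering across contrasts
  s <- g$sensitive & g$base_effect != 0
  expect_true(all(sign(g$effect_mild[s]) == sign(g$effect_gross[s])))
  expect_true(all(abs(g$effect_mild[s]) <= abs(g$base_effect[s])))
})

test_that("default effect profile keeps most sensitive genes under 50% change", {
  ann <- generate_annotation(8000, seed = 11)
  tr <- generate_truth(ann, frac_sensitive = 0.1, seed = 12)
  e <- tr$genes$base_effect[tr$genes$sensitive]
  expect_true(all(abs(e) <= 2))
  frac_small <- mean(2^abs(e) - 1 <= 0.5)
  expect_gte(frac_small, 0.80)
})

test_that("planted clusters are honoured and validated", {
  ann <- generate_annotation(3000, seed = 4)
  pc <- list(arm = "3R", start_mb = 10, end_mb = 12, n_genes = 40)
  tr <- generate_truth(ann, frac_sensitive = 0.05, planted_cluster = pc,
                       seed = 6)
  sens <- tr$genes$gene_id[tr$genes$sensitive]
  in_int <- ann$gene_id[ann$arm == "3R" & ann$position_mb >= 10 &
                          ann$position_mb < 12]
  expect_gte(length(intersect(sens, in_int)), 40)
  expect_error(
    generate_truth(ann, planted_cluster = list(arm = "4", start_mb = 50,
                                               end_mb = 52, n_genes = 5)),
    "cluster")
})

test_that("noise-free null arrays have identical channel intensities", {
  ann <- generate_annotation(50, seed = 1)
  tr <- generate_truth(ann, frac_sensitive = 0.5,
                       severity = c(wt = 0, gross = 0), seed = 2)
  des <- make_design("gross", n_rep = 2)
  spots <- simulate_arrays(ann, tr, des, noise_sd = 0,
                           dye_bias_coeffs = 0, qc_dropout = 0, seed = 3)
  expect_equal(spots$intensity_red, spots$intensity_green)
})

test_that("simulated mean M recovers a known effect", {
  ann <- generate_annotation(30, seed = 1)
  genes <- ann$gene_id
  g <- data.frame(gene_id = genes, sensitive = genes == genes[5],
                  base_effect = ifelse(genes == genes[5], 1.0, 0))
  tr <- truth_table(g, severity = c(wt = 0, gross = 1))
  des <- make_design("gross", n_rep = 10)
  noise_sd <- 0.1
  spots <- simulate_arrays(ann, tr, des, noise_sd = noise_sd,
                           dye_bias_coeffs = 0, qc_dropout = 0, seed = 9)
  ma <- spots_to_ma(spots, des)
  swap <- ifelse(des$channel_red_genotype == "gross", 1, -1)
  oriented <- sweep(ma$M, 2, swap, `*`)
  expect_lt(abs(mean(oriented[5, ]) - 1.0), 3 * noise_sd / sqrt(10))
  expect_lt(max(abs(rowMeans(oriented[-5, ]))), 4 * noise_sd / sqrt(10))
})

test_that("qc dropout flags the expected fraction of spots", {
  ann <- generate_annotation(8073, seed = 1)
  tr <- generate_truth(ann, seed = 2)
  des <- make_design(c("mild1", "gross"), n_rep = 5)
  spots <- simulate_arrays(ann, tr, des, qc_dropout = 0.1, seed = 3)
  n <- nrow(spots)
  fails <- sum(!spots$pass_qc)
  expect_lt(abs(fails - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9))
})

test_that("unknown design genotypes are rejected", {
  ann <- generate_annotation(20, seed = 1)
  tr <- generate_truth(ann, severity = c(wt = 0, gross = 1), seed = 2)
  des <- make_design("nosuch", n_rep = 2)
  expect_error(simulate_arrays(ann, tr, des), "not in truth")
})

test_that("dye orientation is balanced within each comparison", {
  des <- make_design(c("mild1", "gross"), n_rep = 6)
  for (g in c("mild1", "gross")) {
    sub <- des[des$channel_red_genotype == g | des$channel_green_genotype == g, ]
    expect_equal(sum(sub$channel_red_genotype == g), 3)
    expect_equal(sum(sub$channel_green_genotype == g), 3)
  }
})

test_that("qPCR Ct tables follow the doubling model", {
  # noise-free: halving copy number costs exactly one cycle
  ct0 <- simulate_qpcr(c(ref = 1, half = 0.5), n_bio = 2, n_tech = 2,
                       ct_sd = 0, seed = 1)
  expect_equal(unique(ct0$ct[ct0$genotype == "half"]) -
                 unique(ct0$ct[ct0$genotype == "ref"]), 1.0)
  # gross deletion at 46%: delta-Ct = log2(1/0.46)
  ct1 <- simulate_qpcr(c(ref = 1, gross = 0.46), n_bio = 1, n_tech = 1,
                       ct_sd = 0, seed = 1)
  expect_equal(ct1$ct[ct1$genotype == "gross"] - ct1$ct[ct1$genotype == "ref"],
               log2(1 / 0.46), tolerance = 1e-12)
  # full genotype panel row count: 4 genotypes x 5 bio x 3 tech
  ct2 <- simulate_qpcr(n_bio = 5, n_tech = 3, seed = 2)
  expect_equal(nrow(ct2), 4 * 15)
  expect_error(simulate_qpcr(c(ref = 1, bad = 0)), "fractions")
})

test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- small_study(n_genes = 100, n_rep = 2, seed = 42)
  s2 <- small_study(n_genes = 100, n_rep = 2, seed = 42)
  expect_identical(s1$spots, s2$spots)
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(simulate_qpcr(seed = 9), simulate_qpcr(seed = 9))
})

test_that("TSV and BED writers round-trip annotations", {
  ann <- generate_annotation(25, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  write_tsv_prov(ann, tsv, params = list(seed = 1))
  back <- read_tsv_plain(tsv)
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$position_mb, ann$position_mb, tolerance = 1e-6)
  expect_true(file.exists(paste0(tsv, ".prov")))
  bed <- tempfile(fileext = ".bed")
  write_annotation_bed(ann, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(nrow(b), 25)
  expect_equal(b$V3 - b$V2, rep(1, 25))   # 0-based half-open point features
})
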