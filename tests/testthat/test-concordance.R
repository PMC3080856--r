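# Overlap nulls, direction concordance, fold-change correlations, sharing.

test_that("Monte-Carlo overlap null matches the hypergeometric oracle", {
  ov <- mc_overlap_null(20, 30, 100, observed_k = 10, reps = 2000, seed = 1)
  hy <- hypergeometric_overlap(20, 30, 100, 10)
  expect_lt(abs(ov$null_mean - hy$mean), 4 * sqrt(hy$variance / 2000))
  expect_lt(abs(ov$null_sd^2 - hy$variance), 0.35 * hy$variance)
  # empirical tail near the exact tail
  emp_tail <- mean(ov$null_counts >= 10)
  expect_lt(abs(emp_tail - hy$p_ge), 2 * sqrt(hy$p_ge * (1 - hy$p_ge) / 2000) +
              1 / 2000)
  expect_identical(ov$null_counts,
                   mc_overlap_null(20, 30, 100, 10, 2000, seed = 1)$null_counts)
})

test_that("overlap null handles degenerate set sizes", {
  ov0 <- mc_overlap_null(0, 30, 100, observed_k = 0, reps = 100, seed = 2)
  expect_equal(ov0$null_mean, 0)
  expect_equal(ov0$empirical_p, 1)
  ovN <- mc_overlap_null(50, 50, 50, observed_k = 50, reps = 100, seed = 3)
  expect_true(all(ovN$null_counts == 50))
  expect_error(mc_overlap_null(60, 10, 50, 5, 100), "universe")
  # add-one rule keeps p strictly positive
  ov <- mc_overlap_null(5, 5, 1000, observed_k = 5, reps = 100, seed = 4)
  expect_gte(ov$empirical_p, 1 / 101)
})

test_that("hypergeometric overlap gives exact closed forms", {
  hy <- hypergeometric_overlap(568, 683, 8073, 124)
  expect_equal(hy$mean, 568 * 683 / 8073)
  expect_equal(hy$mean, 48.055, tolerance = 1e-4)
  expect_equal(hypergeometric_overlap(1, 1, 2, 1)$p_ge, 0.5)
  expect_equal(hypergeometric_overlap(10, 10, 50, 0)$p_ge, 1)
})

test_that("hypergeometric tail equals subset enumeration on a small universe", {
  # oracle: fix set A = first n1 genes, enumerate all subsets B of size n2
  N <- 8; n1 <- 3; n2 <- 4
  combos <- combn(N, n2)
  overlaps <- colSums(combos <= n1)
  for (k in 0:3) {
    exact <- mean(overlaps >= k)
    expect_equal(hypergeometric_overlap(n1, n2, N, k)$p_ge, exact,
                 tolerance = 1e-12)
  }
})

test_that("permuted dataset overlap is reproducible and null-consistent", {
  ma_a <- null_ma(800, 6, seed = 11)
  ma_b <- null_ma(800, 6, seed = 12)
  po <- permuted_dataset_overlap(ma_a, ma_b, c("mut", "wt"), c("mut", "wt"),
                                 p_cut = 0.05, n_perm = 10, seed = 13)
  expect_identical(po$shared_counts,
                   permuted_dataset_overlap(ma_a, ma_b, c("mut", "wt"),
                                            c("mut", "wt"), p_cut = 0.05,
                                            n_perm = 10,
                                            seed = 13)$shared_counts)
  expect_equal(po$universe_n, 800)
  # permuted DE sets behave like independent random draws: mean shared count
  # tracks the per-permutation hypergeometric expectation
  expect_lt(abs(po$mean_shared - po$expected_hyper),
            3 * max(1, sd(po$shared_counts)) / sqrt(10) + 1)
})

test_that("direction tables partition the intersection", {
  mk <- function(members, dirs, label) {
    structure(list(label = label, threshold = list(p_cut = 0.05),
                   members = members,
                   direction = stats::setNames(dirs, members)),
              class = "de_gene_set")
  }
  a <- mk(c("g1", "g2", "g3", "g4"), c(1, 1, -1, -1), "a")
  b <- mk(c("g2", "g3", "g4", "g9"), c(1, -1, 1, -1), "b")
  dt <- direction_table(a, b)
  expect_equal(sum(dt$counts), dt$n_shared)
  expect_equal(dt$n_shared, 3)
  expect_equal(dt$counts["up", "up"], c(up = 1), ignore_attr = TRUE)
  expect_equal(dt$counts["down", "up"], c(down = 1), ignore_attr = TRUE)

  ident <- direction_table(a, a)
  expect_equal(ident$counts["up", "down"] + ident$counts["down", "up"], 0,
               ignore_attr = TRUE)

  empty <- direction_table(a, mk("zz", 1, "c"))
  expect_true(empty$undefined)
  expect_true(all(empty$counts == 0))
})

test_that("sign-consistent simulations enrich the concordant cells", {
  study <- small_study(n_genes = 1500, n_rep = 6, noise_sd = 0.15,
                       severity = c(wt = 0, mild = 0.5, gross = 1),
                       seed = 21)
  ma <- study$ma
  res_g <- contrast_results(ma, c("gross", "wt"))
  res_m <- contrast_results(ma, c("mild", "wt"))
  dt <- direction_table(call_de(res_g, 0.01), call_de(res_m, 0.01))
  concordant <- dt$counts["up", "up"] + dt$counts["down", "down"]
  expect_gt(concordant / sum(dt$counts), 0.9)
  expect_lt(dt$p, 0.01)
})

test_that("fold-change correlations are rank-invariant and filterable", {
  set.seed(22)
  res <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    log_fc = rnorm(50), tested = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(foldchange_correlation(res, res)$rho, 1)
  cubed <- res
  cubed$log_fc <- res$log_fc^3
  expect_equal(foldchange_correlation(res, cubed)$rho, 1)
  # brute-force rank oracle on noisy pairs
  noisy <- res
  noisy$log_fc <- res$log_fc + rnorm(50, 0, 0.5)
  fc <- foldchange_correlation(res, noisy)
  expect_equal(fc$rho, cor(rank(res$log_fc), rank(noisy$log_fc)))
  abs_fc <- foldchange_correlation(res, noisy, absolute = TRUE)
  expect_equal(abs_fc$rho, cor(rank(abs(res$log_fc)), rank(abs(noisy$log_fc))))
  expect_error(foldchange_correlation(res[1:2, ], res[1:2, ]), "3 shared")
})

test_that("scaled effects plus noise give strongly positive signed rho", {
  study <- small_study(n_genes = 2000, n_rep = 6, noise_sd = 0.2,
                       severity = c(wt = 0, mild = 0.35, gross = 1),
                       seed = 23)
  res_g <- contrast_results(study$ma, c("gross", "wt"))
  res_m <- contrast_results(study$ma, c("mild", "wt"))
  de_g <- call_de(res_g, 0.001)
  fc <- foldchange_correlation(res_g, res_m, gene_filter = de_g)
  expect_gte(fc$rho, 0.5)
  expect_lt(fc$p, 1e-6)
})

test_that("multiway sharing covers identity, disjointness and Venn cells", {
  s1 <- c("a", "b", "c")
  s2 <- c("a", "b", "c")
  s3 <- c("a", "b", "c")
  expect_equal(multiway_sharing(list(s1, s2, s3))$fraction, 1.0)
  expect_equal(multiway_sharing(list(c("a"), c("b"), c("c")))$fraction, 0.0)
  mw <- multiway_sharing(list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(mw$n_union, 4)
  expect_equal(mw$n_shared, 2)           # b and c
  expect_equal(sum(mw$venn), mw$n_union) # cells partition the union
  expect_error(multiway_sharing(list(s1)), "2 sets")
})

test_that("random independent sets share at the inclusion-exclusion rate", {
  N <- 500
  sizes <- c(100, 150, 200)
  p <- sizes / N
  # per-gene probability of belonging to >= 2 of the 3 independent sets
  q2 <- p[1] * p[2] * (1 - p[3]) + p[1] * p[3] * (1 - p[2]) +
    p[2] * p[3] * (1 - p[1]) + p[1] * p[2] * p[3]
  q_union <- 1 - prod(1 - p)
  expected_fraction <- q2 / q_union
  set.seed(24)
  fr <- replicate(40, {
    sets <- lapply(sizes, function(s) sample(N, s))
    multiway_sharing(sets)$fraction
  })
  expect_lt(abs(mean(fr) - expected_fraction),
            3 * sd(fr) / sqrt(40) + 0.005)
})
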