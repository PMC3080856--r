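# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# ma_matrix from an already-oriented M matrix: columns become forward
# hybridizations of a single mutant-vs-wt comparison.
ma_from_oriented <- function(M, A = NULL, mutant = "mut") {
  n <- ncol(M)
  design <- data.frame(
    hybridization_id = paste0("h", seq_len(n)),
    channel_red_genotype = mutant,
    channel_green_genotype = "wt",
    replicate_index = seq_len(n),
    stringsAsFactors = FALSE
  )
  colnames(M) <- design$hybridization_id
  if (is.null(A)) A <- matrix(10, nrow(M), n, dimnames = dimnames(M))
  if (is.null(rownames(M))) {
    rownames(M) <- rownames(A) <- sprintf("g%04d", seq_len(nrow(M)))
  }
  structure(list(M = M, A = A, design = design), class = "ma_matrix")
}

# oriented null M matrix: pure Gaussian noise, no effects
null_ma <- function(n_genes, n_rep, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_genes * n_rep, 0, noise_sd), n_genes, n_rep)
  ma_from_oriented(M)
}

# one-hybridization spot table with prescribed M and A vectors
spots_one_hyb <- function(M, A, hyb = "h1", mutant = "mut") {
  design <- data.frame(hybridization_id = hyb,
                       channel_red_genotype = mutant,
                       channel_green_genotype = "wt",
                       replicate_index = 1L, stringsAsFactors = FALSE)
  spots <- data.frame(
    gene_id = sprintf("g%04d", seq_along(M)),
    hybridization_id = hyb,
    intensity_red = 2^(A + M / 2),
    intensity_green = 2^(A - M / 2),
    pass_qc = TRUE, stringsAsFactors = FALSE
  )
  list(spots = spots, design = design)
}

# a small simulated study: annotation + truth + arrays for one contrast
small_study <- function(n_genes = 400, n_rep = 6, frac_sensitive = 0.1,
                        noise_sd = 0.2, severity = c(wt = 0, gross = 1),
                        effect_sd = 0.4, seed = 1, dye_bias = c(0, 0, 0),
                        qc_dropout = 0) {
  ann <- generate_annotation(n_genes, seed = seed)
  truth <- generate_truth(ann, frac_sensitive = frac_sensitive,
                          effect_sd = effect_sd, severity = severity,
                          seed = seed + 1)
  design <- make_design(setdiff(names(severity), "wt"), n_rep = n_rep)
  spots <- simulate_arrays(ann, truth, design, noise_sd = noise_sd,
                           dye_bias_coeffs = dye_bias,
                           qc_dropout = qc_dropout, seed = seed + 2)
  list(annotation = ann, truth = truth, design = design, spots = spots,
       ma = spots_to_ma(spots, design))
}
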