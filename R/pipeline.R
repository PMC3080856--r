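# End-to-end orchestration: one validated config drives simulate ->
# normalize -> DE -> concordance -> genome scan -> extrapolation ->
# enrichment -> copy number, with per-stage seeds derived deterministically
# from one global seed.

#' Build and validate a pipeline run configuration
#'
#' Captures every tunable of the full analysis. Defaults mirror the study
#' design: 8073 genes, four Y-chromosome genotypes (wild type, two mild
#' deletions, one gross deletion) with severity factors 0/0.3/0.35/1.0,
#' 10% rDNA-sensitive genes, six dye-balanced replicate hybridizations per
#' direct comparison, the p-value ladder {0.05, 0.01, 0.005, 0.001} with
#' FDR < 0.05, 10,000 overlap-null replicates and 1000 window-scan random
#' sets.
#'
#' @param n_genes genes on the simulated array.
#' @param frac_sensitive fraction of rDNA-sensitive genes.
#' @param effect_sd SD of the base log2 effect of sensitive genes.
#' @param severity named genotype severity factors (reference must be 0).
#' @param copy_fractions named true rDNA copy fractions for qPCR.
#' @param n_rep replicate hybridizations per comparison.
#' @param noise_sd per-spot M noise SD.
#' @param qc_dropout fraction of spots failing QC.
#' @param span loess span.
#' @param p_cuts raw p-value ladder.
#' @param fdr_cut FDR threshold used for the primary DE sets.
#' @param primary_p_cut raw p threshold of the primary DE sets.
#' @param overlap_reps Monte-Carlo overlap replicates (>= 100).
#' @param window_random window-scan random sets (>= 100).
#' @param n_perm permutations for the permutation FDR (>= 10).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir optional output directory for TSV reports.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(n_genes = 8073, frac_sensitive = 0.1, effect_sd = 0.4,
                       severity = default_severity(),
                       copy_fractions = default_copy_fractions(),
                       n_rep = 6, noise_sd = 0.2, qc_dropout = 0.02,
                       span = 0.4, p_cuts = c(0.05, 0.01, 0.005, 0.001),
                       fdr_cut = 0.05, primary_p_cut = 0.001,
                       overlap_reps = 10000, window_random = 1000,
                       n_perm = 20, seed = 1, outdir = NULL) {
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  if (any(p_cuts <= 0 | p_cuts > 1)) stop_bad_arg("p_cuts must lie in (0, 1]")
  check_number(fdr_cut, "fdr_cut", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(overlap_reps, "overlap_reps", lower = 100, integer = TRUE)
  check_number(window_random, "window_random", lower = 100, integer = TRUE)
  check_number(n_perm, "n_perm", lower = 10, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (!"wt" %in% names(severity) || severity[["wt"]] != 0) {
    stop_bad_arg("severity must include the reference 'wt' at 0")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes every stage in dependency order from one config: simulate the
#' study (annotation, truth, dye-balanced arrays, qPCR), loess-normalise,
#' call differential expression per contrast across the threshold ladder,
#' quantify cross-contrast sharing (Venn cells, overlap nulls, fold-change
#' correlations, direction tables), scan the genome for positional
#' clustering, project undetected small-effect genes, test category
#' enrichment, and estimate rDNA copy number. Identical config and seed
#' give identical outputs. When `config$outdir` is set, per-stage TSVs and
#' a manifest are written there.
#'
#' @param config a [run_config()].
#' @return Named list with elements `annotation`, `truth`, `design`,
#'   `results` (per-contrast ContrastResults), `de_counts` (contrast x
#'   threshold table), `de_sets`, `perm_fdr`, `sharing`, `overlap`,
#'   `correlations`, `direction`, `division_profile`, `window_scan`,
#'   `arm_test`, `decile`, `projection`, `missed`, `enrichment`,
#'   `copy_number`, `manifest`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  mutants <- setdiff(names(cfg$severity), "wt")

  # --- simulate -------------------------------------------------------------
  ann <- generate_annotation(cfg$n_genes, seed = stage_seed(cfg$seed, "annotation"))
  truth <- generate_truth(ann, frac_sensitive = cfg$frac_sensitive,
                          effect_sd = cfg$effect_sd, severity = cfg$severity,
                          enriched_category = list(id = "planted", baseline = 0.05,
                                                   fold = 3),
                          seed = stage_seed(cfg$seed, "truth"))
  design <- make_design(mutants, "wt", n_rep = cfg$n_rep)
  spots <- simulate_arrays(ann, truth, design, noise_sd = cfg$noise_sd,
                           qc_dropout = cfg$qc_dropout,
                           seed = stage_seed(cfg$seed, "arrays"))
  ct <- simulate_qpcr(cfg$copy_fractions, seed = stage_seed(cfg$seed, "qpcr"))

  # --- normalize + DE -------------------------------------------------------
  norm <- loess_normalize(spots, design, span = cfg$span)
  results <- lapply(mutants, function(g) contrast_results(norm, c(g, "wt")))
  names(results) <- mutants
  de_counts <- do.call(rbind, lapply(mutants, function(g) {
    data.frame(contrast = g, p_cut = cfg$p_cuts,
               n_de = vapply(cfg$p_cuts, function(pc) {
                 length(call_de(results[[g]], pc)$members)
               }, numeric(1)), stringsAsFactors = FALSE)
  }))
  de_sets <- lapply(mutants, function(g) {
    call_de(results[[g]], cfg$primary_p_cut, cfg$fdr_cut, label = g)
  })
  names(de_sets) <- mutants
  perm_fdr <- permutation_fdr(norm, c(mutants[length(mutants)], "wt"),
                              p_cut = cfg$primary_p_cut, n_perm = cfg$n_perm,
                              seed = stage_seed(cfg$seed, "permfdr"))

  # --- concordance ----------------------------------------------------------
  gross <- mutants[which.max(cfg$severity[mutants])]
  milds <- setdiff(mutants, gross)
  sharing <- multiway_sharing(de_sets, min_sets = 2)
  tested_all <- Reduce(intersect, lapply(results, function(r) r$gene_id[r$tested]))
  overlap <- lapply(milds, function(g) {
    k <- length(intersect(de_sets[[g]]$members, de_sets[[gross]]$members))
    mc_overlap_null(length(de_sets[[g]]$members),
                    length(de_sets[[gross]]$members),
                    universe_n = length(tested_all), observed_k = k,
                    reps = cfg$overlap_reps,
                    seed = stage_seed(cfg$seed, paste0("overlap_", g)))
  })
  names(overlap) <- milds
  # correlate over the gross DE genes; with a near-empty DE set (e.g. a
  # null run) fall back to all tested genes
  correlations <- lapply(milds, function(g) {
    filt <- if (length(de_sets[[gross]]$members) >= 3) de_sets[[gross]]
    foldchange_correlation(results[[gross]], results[[g]], gene_filter = filt)
  })
  names(correlations) <- milds
  direction <- lapply(milds, function(g) direction_table(de_sets[[gross]],
                                                         de_sets[[g]]))
  names(direction) <- milds

  # --- genome scan ----------------------------------------------------------
  profile <- division_profile(de_sets[[gross]], ann)
  profile$smoothed_ratio <- scanning_average(
    ifelse(is.na(profile$ratio), 0, profile$ratio), profile$arm, 5)
  scan <- sliding_window_scan(de_sets[[gross]], ann,
                              n_random = cfg$window_random,
                              seed = stage_seed(cfg$seed, "scan"))
  arm_test <- arm_frequency_test(de_sets[[gross]], ann)
  boundary <- boundary_check(ann, "X", "proximal", 20, de_sets[[gross]])

  # --- extrapolation --------------------------------------------------------
  decile <- decile_histogram(results[[gross]], p_cut = 0.05)
  projection <- project_first_decile(decile[2:5])
  missed <- estimate_missed(projection, decile[1],
                            universe_n = sum(results[[gross]]$tested))

  # --- enrichment -----------------------------------------------------------
  tested_gross <- results[[gross]]$gene_id[results[[gross]]$tested]
  enr_set <- intersect(de_sets[[gross]]$members, tested_gross)
  enrich <- category_enrichment(enr_set, tested_gross, truth$categories)

  # --- copy number ----------------------------------------------------------
  cn <- relative_copy_number(ct, "wt")

  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), "outdir")],
                   contrasts = mutants, gross = gross,
                   stage_seeds = vapply(c("annotation", "truth", "arrays",
                                          "qpcr", "permfdr", "scan"),
                                        function(s) stage_seed(cfg$seed, s),
                                        integer(1)))
  out <- list(annotation = ann, truth = truth, design = design,
              results = results, de_counts = de_counts, de_sets = de_sets,
              perm_fdr = perm_fdr, sharing = sharing, overlap = overlap,
              correlations = correlations, direction = direction,
              division_profile = profile, window_scan = scan,
              arm_test = arm_test, boundary = boundary, decile = decile,
              projection = projection, missed = missed, enrichment = enrich,
              copy_number = cn, manifest = manifest)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(seed = cfg$seed)
    write_tsv_prov(ann, file.path(cfg$outdir, "annotation.tsv"), prov)
    write_tsv_prov(design, file.path(cfg$outdir, "design.tsv"), prov)
    write_tsv_prov(de_counts, file.path(cfg$outdir, "de_counts.tsv"), prov)
    for (g in mutants) {
      write_tsv_prov(results[[g]][, c("gene_id", "log_fc", "t_mod", "p",
                                      "p_adj", "n_obs")],
                     file.path(cfg$outdir, paste0("contrast_", g, ".tsv")),
                     prov)
    }
    write_tsv_prov(scan, file.path(cfg$outdir, "window_scan.tsv"), prov)
    write_tsv_prov(profile, file.path(cfg$outdir, "division_profile.tsv"), prov)
    write_tsv_prov(enrich, file.path(cfg$outdir, "enrichment.tsv"), prov)
    write_tsv_prov(cn, file.path(cfg$outdir, "copy_number.tsv"), prov)
  }
  out
}
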