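# Synthetic study-design generator: gene annotations on a fly-like
# cytological map, ground-truth rDNA-sensitive effects, dye-balanced
# two-colour hybridizations, and qPCR Ct tables.

ARM_DIVISIONS <- list(
  X  = c(1L, 20L),
  `2L` = c(21L, 40L),
  `2R` = c(41L, 60L),
  `3L` = c(61L, 80L),
  `3R` = c(81L, 100L),
  `4`  = c(101L, 102L)
)

#' Default chromosome-arm lengths (megabases)
#'
#' Euchromatic arm lengths approximating the D. melanogaster genome; used to
#' place synthetic genes. Names are the arm labels `X, 2L, 2R, 3L, 3R, 4`.
#'
#' @return Named numeric vector of lengths in Mb.
#' @export
default_arm_lengths <- function() {
  c(X = 22, `2L` = 23, `2R` = 21, `3L` = 24, `3R` = 28, `4` = 1.3)
}

#' Default genotype severity factors
#'
#' Multipliers applied to each gene's base (gross-deletion) log2 effect to
#' obtain the per-genotype effect. Free parameters of the simulator, chosen
#' so mild differential-expression sets nest within the gross set under
#' realistic noise; zero for wild type.
#'
#' @return Named numeric vector in `[0, 1]`.
#' @export
default_severity <- function() {
  c(wt = 0, mild1 = 0.3, mild2 = 0.35, gross = 1.0)
}

#' Default true rDNA copy fractions per genotype
#'
#' Relative rDNA array sizes of the four Y chromosomes (wild type = 1; two
#' mild deletions at 87% and 85%; one gross deletion at 46%).
#'
#' @return Named numeric vector in `(0, 1]`.
#' @export
default_copy_fractions <- function() {
  c(wt = 1.0, mild1 = 0.87, mild2 = 0.85, gross = 0.46)
}

division_for_position <- function(arm, position_mb, arm_lengths) {
  rng <- ARM_DIVISIONS[[arm]]
  n_div <- rng[2] - rng[1] + 1L
  idx <- floor(position_mb / arm_lengths[[arm]] * n_div)
  idx <- pmin(pmax(idx, 0), n_div - 1L)
  as.integer(rng[1] + idx)
}

#' Generate synthetic gene annotations on a cytological map
#'
#' Genes are assigned to chromosome arms with probability proportional to arm
#' length, placed uniformly along the arm, and binned into cytological
#' divisions (X: 1-20, 2L: 21-40, 2R: 41-60, 3L: 61-80, 3R: 81-100, 4:
#' 101-102) by linear division of the arm.
#'
#' @param n_genes number of genes (>= 1).
#' @param arm_lengths_mb named vector of arm lengths in Mb; names must be a
#'   subset of the six standard arms.
#' @param seed integer seed for reproducibility.
#' @return data.frame with columns `gene_id`, `arm`, `division`,
#'   `position_mb`.
#' @examples
#' ann <- generate_annotation(100, seed = 1)
#' table(ann$arm)
#' @export
generate_annotation <- function(n_genes, arm_lengths_mb = default_arm_lengths(),
                                seed = NULL) {
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  if (!is.numeric(arm_lengths_mb) || is.null(names(arm_lengths_mb)) ||
      any(arm_lengths_mb <= 0)) {
    stop_bad_arg("`arm_lengths_mb` must be a named vector of positive lengths")
  }
  bad <- setdiff(names(arm_lengths_mb), names(ARM_DIVISIONS))
  if (length(bad)) stop_bad_arg("unknown arm(s): ", paste(bad, collapse = ", "))
  with_seed(seed, {
    arms <- sample(names(arm_lengths_mb), n_genes, replace = TRUE,
                   prob = arm_lengths_mb / sum(arm_lengths_mb))
    pos <- stats::runif(n_genes) * arm_lengths_mb[arms]
    div <- integer(n_genes)
    for (a in unique(arms)) {
      i <- arms == a
      div[i] <- division_for_position(a, pos[i], arm_lengths_mb)
    }
    data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      arm = arms,
      division = div,
      position_mb = unname(pos),
      stringsAsFactors = FALSE
    )
  })
}

#' Construct and validate a truth table
#'
#' A truth table records, per gene, whether it is rDNA-sensitive, its base
#' log2 fold-change under the gross deletion, and the per-genotype effects
#' (base effect times that genotype's severity factor). Used both by
#' [generate_truth()] and for hand-built simulation designs.
#'
#' @param genes data.frame with columns `gene_id`, `sensitive`, `base_effect`.
#' @param severity named numeric vector of per-genotype severity factors in
#'   `[0, 1]`.
#' @param categories optional data.frame `(gene_id, category_id)` of flat
#'   functional-category labels.
#' @return Object of class `truth_table`: list with elements `genes` (the
#'   input plus one `effect_<genotype>` column per genotype), `severity`,
#'   `categories`.
#' @export
truth_table <- function(genes, severity = default_severity(),
                        categories = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "sensitive", "base_effect") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop_bad_arg("duplicate gene_id in truth")
  if (any(severity < 0 | severity > 1)) {
    stop_bad_arg("severity factors must lie in [0, 1]")
  }
  if (any(!genes$sensitive & genes$base_effect != 0)) {
    stop_bad_arg("non-sensitive genes must have base_effect 0")
  }
  for (g in names(severity)) {
    genes[[paste0("effect_", g)]] <- genes$base_effect * severity[[g]]
  }
  structure(list(genes = genes, severity = severity,
                 categories = categories),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$genes), "genes,",
      sum(x$genes$sensitive), "sensitive;",
      "genotypes:", paste(names(x$severity), collapse = ", "), "\n")
  invisible(x)
}

# effect column for a genotype, zero vector for the reference
truth_effect <- function(truth, genotype) {
  col <- paste0("effect_", genotype)
  if (!col %in% names(truth$genes)) {
    stop_bad_arg("genotype not in truth table: ", genotype)
  }
  truth$genes[[col]]
}

#' Generate ground-truth rDNA-sensitive effects
#'
#' Marks a fraction of genes as rDNA-sensitive and draws their base
#' (gross-deletion) log2 fold-changes from a zero-mean Gaussian truncated at
#' `±max_abs_effect`. Per-genotype effects are the base effect scaled by that
#' genotype's severity factor, so signs are consistent across genotypes and
#' magnitudes shrink with milder deletions. The default `effect_sd` makes
#' ~85% of sensitive genes change by no more than 50% on the natural scale.
#'
#' @param annotation annotation data.frame from [generate_annotation()].
#' @param frac_sensitive fraction of genes that respond, in (0, 1).
#' @param effect_sd standard deviation of the base log2 effect.
#' @param severity named vector of genotype severity factors in `[0, 1]`.
#' @param max_abs_effect truncation bound for |base effect| (log2 scale).
#' @param planted_cluster optional list `(arm, start_mb, end_mb, n_genes)`
#'   forcing that many sensitive genes into the stated interval (used to
#'   test positional-clustering detection).
#' @param n_categories number of flat functional-category labels assigned at
#'   random (1-3 labels per gene).
#' @param enriched_category optional list `(id, baseline, fold)`: every gene
#'   receives label `id` with probability `baseline`, sensitive genes with
#'   probability `baseline * fold` (planted category enrichment).
#' @param seed integer seed.
#' @return A [truth_table()].
#' @export
generate_truth <- function(annotation, frac_sensitive = 0.1, effect_sd = 0.4,
                           severity = default_severity(),
                           max_abs_effect = 2.0, planted_cluster = NULL,
                           n_categories = 50, enriched_category = NULL,
                           seed = NULL) {
  check_number(frac_sensitive, "frac_sensitive", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (frac_sensitive >= 1) stop_bad_arg("`frac_sensitive` must be < 1")
  check_number(effect_sd, "effect_sd", lower = 0, strict_lower = TRUE)
  check_number(max_abs_effect, "max_abs_effect", lower = 0, strict_lower = TRUE)
  n <- nrow(annotation)
  with_seed(seed, {
    n_sens <- round(n * frac_sensitive)
    sensitive <- logical(n)
    if (!is.null(planted_cluster)) {
      pc <- planted_cluster
      in_int <- annotation$arm == pc$arm &
        annotation$position_mb >= pc$start_mb &
        annotation$position_mb < pc$end_mb
      if (!any(in_int)) stop_bad_arg("planted cluster interval contains no genes")
      if (sum(in_int) < pc$n_genes) {
        stop_bad_arg("planted cluster asks for ", pc$n_genes,
                     " genes but interval holds ", sum(in_int))
      }
      forced <- sample(which(in_int), pc$n_genes)
      sensitive[forced] <- TRUE
      remaining <- max(0, n_sens - pc$n_genes)
      pool <- setdiff(seq_len(n), forced)
      sensitive[sample(pool, min(remaining, length(pool)))] <- TRUE
    } else {
      sensitive[sample.int(n, n_sens)] <- TRUE
    }
    base <- numeric(n)
    k <- sum(sensitive)
    if (k > 0) {
      # truncated zero-mean Gaussian: redraw outside the bound
      draw <- stats::rnorm(k, 0, effect_sd)
      while (any(bad <- abs(draw) > max_abs_effect)) {
        draw[bad] <- stats::rnorm(sum(bad), 0, effect_sd)
      }
      base[sensitive] <- draw
    }
    cats <- NULL
    if (n_categories > 0) {
      per_gene <- sample(1:3, n, replace = TRUE)
      cats <- data.frame(
        gene_id = rep(annotation$gene_id, per_gene),
        category_id = sprintf("cat%03d",
                              sample.int(n_categories, sum(per_gene),
                                         replace = TRUE)),
        stringsAsFactors = FALSE
      )
      if (!is.null(enriched_category)) {
        ec <- enriched_category
        p_hit <- ifelse(sensitive, pmin(1, ec$baseline * ec$fold), ec$baseline)
        hit <- stats::runif(n) < p_hit
        if (any(hit)) {
          cats <- rbind(cats, data.frame(gene_id = annotation$gene_id[hit],
                                         category_id = ec$id,
                                         stringsAsFactors = FALSE))
        }
      }
      cats <- unique(cats)
    }
    truth_table(
      data.frame(gene_id = annotation$gene_id, sensitive = sensitive,
                 base_effect = base, stringsAsFactors = FALSE),
      severity = severity, categories = cats
    )
  })
}

#' Build a dye-balanced direct-comparison hybridization design
#'
#' Each mutant genotype is compared directly against the reference on
#' `n_rep` arrays, with dye orientation alternating so each comparison is
#' dye-balanced (reference in the green channel on odd replicates, in the
#' red channel on even replicates).
#'
#' @param genotypes character vector of mutant genotype labels.
#' @param reference reference genotype label (default `"wt"`).
#' @param n_rep replicates per comparison (default 6).
#' @return data.frame with columns `hybridization_id`,
#'   `channel_red_genotype`, `channel_green_genotype`, `replicate_index`.
#' @export
make_design <- function(genotypes = c("mild1", "mild2", "gross"),
                        reference = "wt", n_rep = 6) {
  check_number(n_rep, "n_rep", lower = 1, integer = TRUE)
  rows <- lapply(genotypes, function(g) {
    swap <- seq_len(n_rep) %% 2 == 0
    data.frame(
      hybridization_id = sprintf("%s_vs_%s_r%d", g, reference, seq_len(n_rep)),
      channel_red_genotype = ifelse(swap, reference, g),
      channel_green_genotype = ifelse(swap, g, reference),
      replicate_index = seq_len(n_rep),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate two-colour microarray spot intensities
#'
#' For every (gene, hybridization) pair, the true log2 ratio is the red
#' channel genotype's effect minus the green channel genotype's effect, plus
#' an intensity-dependent dye bias (a low-order polynomial in the average
#' log2 intensity A, which loess normalisation should remove) and Gaussian
#' noise. Intensities are reconstructed as
#' `R = 2^(A + M/2)`, `G = 2^(A - M/2)`. A `qc_dropout` fraction of spots is
#' flagged as failing quality control at random.
#'
#' @param annotation annotation data.frame (defines the gene list).
#' @param truth a [truth_table()] covering every non-reference genotype in
#'   the design.
#' @param design design data.frame from [make_design()].
#' @param noise_sd per-spot Gaussian noise SD on the M scale.
#' @param dye_bias_coeffs polynomial coefficients `c(b0, b1, b2, ...)` of the
#'   dye bias in centred A: `bias = b0 + b1*(A - mean) + b2*(A - mean)^2 ...`.
#' @param intensity_model_params list with `a_mean`, `a_sd`: distribution of
#'   per-spot average log2 intensity.
#' @param qc_dropout fraction of spots flagged `pass_qc = FALSE`.
#' @param effect_scale global multiplier on all true effects (e.g. a
#'   sex-attenuation factor of 0.6 to emulate XXY females, which show the
#'   same sensitive genes with damped magnitudes).
#' @param seed integer seed.
#' @return SpotTable data.frame: `gene_id`, `hybridization_id`,
#'   `intensity_red`, `intensity_green`, `pass_qc`.
#' @export
simulate_arrays <- function(annotation, truth, design, noise_sd = 0.2,
                            dye_bias_coeffs = c(0.2, -0.1, 0.05),
                            intensity_model_params = list(a_mean = 10, a_sd = 1.5),
                            qc_dropout = 0.02, effect_scale = 1, seed = NULL) {
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(qc_dropout, "qc_dropout", lower = 0, upper = 1)
  genos <- unique(c(design$channel_red_genotype, design$channel_green_genotype))
  known <- sub("^effect_", "", grep("^effect_", names(truth$genes), value = TRUE))
  bad <- setdiff(genos, known)
  if (length(bad)) stop_bad_arg("genotype(s) not in truth table: ",
                                paste(bad, collapse = ", "))
  n_genes <- nrow(annotation)
  if (!identical(annotation$gene_id, truth$genes$gene_id)) {
    stop_bad_arg("annotation and truth must list the same genes in order")
  }
  with_seed(seed, {
    out <- vector("list", nrow(design))
    for (j in seq_len(nrow(design))) {
      red <- design$channel_red_genotype[j]
      green <- design$channel_green_genotype[j]
      m_true <- (truth_effect(truth, red) - truth_effect(truth, green)) *
        effect_scale
      a <- stats::rnorm(n_genes, intensity_model_params$a_mean,
                        intensity_model_params$a_sd)
      z <- a - intensity_model_params$a_mean
      bias <- 0
      for (k in seq_along(dye_bias_coeffs)) {
        bias <- bias + dye_bias_coeffs[k] * z^(k - 1)
      }
      m <- m_true + bias + stats::rnorm(n_genes, 0, noise_sd)
      out[[j]] <- data.frame(
        gene_id = annotation$gene_id,
        hybridization_id = design$hybridization_id[j],
        intensity_red = 2^(a + m / 2),
        intensity_green = 2^(a - m / 2),
        pass_qc = stats::runif(n_genes) >= qc_dropout,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate a qPCR Ct table for rDNA copy-number quantification
#'
#' Threshold cycles follow the exponential-amplification model: a genotype
#' carrying a fraction `f` of the reference rDNA copy number crosses
#' threshold `log2(1/f)` cycles later than the reference (at efficiency 2),
#' plus Gaussian measurement noise.
#'
#' @param true_copy_fraction named vector of copy fractions in (0, 1]; the
#'   reference genotype has fraction 1.
#' @param n_bio biological replicates per genotype (>= 1).
#' @param n_tech technical replicates per biological replicate (>= 1).
#' @param ct_sd Gaussian noise SD on Ct, in cycles.
#' @param ct_ref mean threshold cycle of the reference genotype.
#' @param seed integer seed.
#' @return data.frame: `genotype`, `bio_rep`, `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(true_copy_fraction = default_copy_fractions(),
                          n_bio = 5, n_tech = 3, ct_sd = 0.05,
                          ct_ref = 15, seed = NULL) {
  if (any(true_copy_fraction <= 0) || any(true_copy_fraction > 1)) {
    stop_bad_arg("copy fractions must lie in (0, 1]")
  }
  check_number(n_bio, "n_bio", lower = 1, integer = TRUE)
  check_number(n_tech, "n_tech", lower = 1, integer = TRUE)
  check_number(ct_sd, "ct_sd", lower = 0)
  with_seed(seed, {
    rows <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                        genotype = names(true_copy_fraction),
                        stringsAsFactors = FALSE)
    mu <- ct_ref - log2(true_copy_fraction[rows$genotype])
    rows$ct <- mu + stats::rnorm(nrow(rows), 0, ct_sd)
    rows[, c("genotype", "bio_rep", "tech_rep", "ct")]
  })
}

#' Write gene annotations as BED
#'
#' Emits genes as 0-based half-open point features (`start = floor(position
#' in bp)`, `end = start + 1`), with the arm as chromosome name and an unused
#' score column of 0.
#'
#' @param annotation annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  start <- floor(annotation$position_mb * 1e6)
  bed <- data.frame(chrom = annotation$arm, start = start, end = start + 1,
                    name = annotation$gene_id, score = 0)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
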