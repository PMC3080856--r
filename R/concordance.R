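# Sharing of DE genes across contrasts and sexes: Monte-Carlo and exact
# hypergeometric overlap nulls, permuted-dataset overlap expectation,
# direction-concordance tables, fold-change correlations, multiway sharing.

#' Monte-Carlo null for the overlap of two gene sets
#'
#' Each replicate draws two independent uniform subsets without replacement,
#' of sizes `n1` and `n2`, from a universe of `universe_n` genes and counts
#' their intersection. The empirical p-value for an observed overlap uses
#' the add-one convention `(1 + #{null >= observed}) / (reps + 1)` so it is
#' never zero.
#'
#' @param n1,n2 sizes of the two DE sets.
#' @param universe_n number of genes in the universe.
#' @param observed_k observed overlap (<= min(n1, n2)).
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed integer seed.
#' @return Object of class `overlap_test`: list with the inputs plus
#'   `null_mean`, `null_sd`, `null_max`, `empirical_p`, and `null_counts`
#'   (the full replicate distribution).
#' @examples
#' ov <- mc_overlap_null(568, 683, 8073, observed_k = 124, reps = 1000,
#'                       seed = 1)
#' ov$null_mean     # close to 568 * 683 / 8073 = 48.06
#' @export
mc_overlap_null <- function(n1, n2, universe_n, observed_k, reps = 10000,
                            seed = NULL) {
  check_number(n1, "n1", lower = 0, integer = TRUE)
  check_number(n2, "n2", lower = 0, integer = TRUE)
  check_number(universe_n, "universe_n", lower = 1, integer = TRUE)
  check_number(reps, "reps", lower = 100, integer = TRUE)
  if (n1 > universe_n || n2 > universe_n) {
    stop_bad_arg("set sizes cannot exceed the universe")
  }
  check_number(observed_k, "observed_k", lower = 0, upper = min(n1, n2),
               integer = TRUE)
  counts <- with_seed(seed, {
    member <- logical(universe_n)
    vapply(seq_len(reps), function(i) {
      a <- sample.int(universe_n, n1)
      b <- sample.int(universe_n, n2)
      member[a] <- TRUE
      k <- sum(member[b])
      member[a] <- FALSE
      k
    }, numeric(1))
  })
  structure(list(
    n1 = n1, n2 = n2, universe_n = universe_n, observed_k = observed_k,
    reps = reps, null_counts = counts,
    null_mean = mean(counts), null_sd = stats::sd(counts),
    null_max = max(counts),
    empirical_p = (1 + sum(counts >= observed_k)) / (reps + 1)
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("overlap_test: k =", x$observed_k, "shared of", x$n1, "and", x$n2,
      "in universe", x$universe_n, "\n  null mean", round(x$null_mean, 2),
      "sd", round(x$null_sd, 2), "max", x$null_max,
      "in", x$reps, "trials; empirical P =",
      format(x$empirical_p, digits = 3), "\n")
  invisible(x)
}

#' Exact hypergeometric overlap distribution
#'
#' Closed-form counterpart of [mc_overlap_null()]: the intersection of two
#' independent uniform subsets of sizes `n1` and `n2` from `universe_n`
#' genes is hypergeometric, with mean `n1*n2/N`.
#'
#' @inheritParams mc_overlap_null
#' @return list: `mean`, `variance`, `p_ge` (upper-tail probability of an
#'   overlap >= `observed_k`).
#' @export
hypergeometric_overlap <- function(n1, n2, universe_n, observed_k) {
  check_number(n1, "n1", lower = 0, integer = TRUE)
  check_number(n2, "n2", lower = 0, integer = TRUE)
  check_number(universe_n, "universe_n", lower = 1, integer = TRUE)
  if (n1 > universe_n || n2 > universe_n) {
    stop_bad_arg("set sizes cannot exceed the universe")
  }
  check_number(observed_k, "observed_k", lower = 0, upper = min(n1, n2),
               integer = TRUE)
  m <- n1 * n2 / universe_n
  v <- n2 * (n1 / universe_n) * (1 - n1 / universe_n) *
    (universe_n - n2) / (universe_n - 1)
  p_ge <- if (observed_k == 0) 1 else {
    stats::phyper(observed_k - 1, n1, universe_n - n1, n2, lower.tail = FALSE)
  }
  list(mean = m, variance = v, p_ge = p_ge)
}

#' Expected DE-set overlap between permuted datasets
#'
#' Applies the same null permutation (random re-signing of oriented
#' hybridization vectors) independently to two datasets, calls DE in each at
#' `p_cut`, and counts the genes shared by both permuted DE sets. The mean
#' of this distribution is the "shared by chance" expectation for the
#' observed overlap between the two real datasets.
#'
#' @param ma_a,ma_b `ma_matrix` objects for the two datasets.
#' @param contrast_a,contrast_b `c(mutant, reference)` pairs.
#' @param p_cut raw p-value threshold used to call DE.
#' @param n_perm permutations (>= 10).
#' @param min_obs minimum observations per gene.
#' @param seed integer seed.
#' @return list: `shared_counts` (per permutation), `mean_shared`,
#'   `n_a`, `n_b` (per-permutation DE-set sizes), `expected_hyper`
#'   (per-permutation hypergeometric expectation `n_a*n_b/N` averaged over
#'   permutations, with N the genes tested in both).
#' @export
permuted_dataset_overlap <- function(ma_a, ma_b, contrast_a, contrast_b,
                                     p_cut = 0.005, n_perm = 20, min_obs = 2,
                                     seed = NULL) {
  check_number(n_perm, "n_perm", lower = 10, integer = TRUE)
  xa <- oriented_matrix(ma_a, contrast_a)
  xb <- oriented_matrix(ma_b, contrast_b)
  de_once <- function(x) {
    res <- moderate_and_test(summarize_oriented(x, min_obs))
    res$gene_id[!is.na(res$p) & res$p < p_cut]
  }
  tested_a <- rownames(xa)[rowSums(!is.na(xa)) >= min_obs]
  tested_b <- rownames(xb)[rowSums(!is.na(xb)) >= min_obs]
  universe_n <- length(intersect(tested_a, tested_b))
  with_seed(seed, {
    n_a <- n_b <- shared <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      pa <- de_once(sweep(xa, 2, sample(c(-1, 1), ncol(xa), TRUE), `*`))
      pb <- de_once(sweep(xb, 2, sample(c(-1, 1), ncol(xb), TRUE), `*`))
      n_a[i] <- length(pa)
      n_b[i] <- length(pb)
      shared[i] <- length(intersect(pa, pb))
    }
    list(shared_counts = shared, mean_shared = mean(shared),
         n_a = n_a, n_b = n_b, universe_n = universe_n,
         expected_hyper = mean(n_a * n_b / universe_n))
  })
}

#' Direction-concordance table for two DE sets
#'
#' Cross-tabulates up/down regulation over the genes shared by two DE sets
#' and tests for association with Fisher's exact test (two-sided).
#'
#' @param set_a,set_b `de_gene_set` objects carrying direction maps.
#' @return list: `counts` (2x2 matrix, rows = set A up/down, columns =
#'   set B up/down), `n_shared`, `p` (NA with `undefined = TRUE` when the
#'   intersection is empty or degenerate).
#' @export
direction_table <- function(set_a, set_b) {
  shared <- intersect(set_a$members, set_b$members)
  counts <- matrix(0L, 2, 2,
                   dimnames = list(a = c("up", "down"), b = c("up", "down")))
  if (length(shared)) {
    da <- factor(ifelse(set_a$direction[shared] > 0, "up", "down"),
                 levels = c("up", "down"))
    db <- factor(ifelse(set_b$direction[shared] > 0, "up", "down"),
                 levels = c("up", "down"))
    counts[] <- table(da, db)
  }
  p <- NA_real_
  undefined <- TRUE
  if (length(shared)) {
    ft <- try(stats::fisher.test(counts), silent = TRUE)
    if (!inherits(ft, "try-error")) {
      p <- ft$p.value
      undefined <- FALSE
    }
  }
  list(counts = counts, n_shared = length(shared), p = p,
       undefined = undefined)
}

#' Spearman correlation of fold-changes between two contrasts
#'
#' Rank correlation of (optionally absolute) log2 fold-changes over the
#' genes shared by two contrast results, optionally restricted to a DE set.
#' Ties get average ranks; the p-value uses the large-sample t
#' approximation.
#'
#' @param res_a,res_b ContrastResult data.frames.
#' @param gene_filter optional `de_gene_set` (or character vector)
#'   restricting the genes used.
#' @param absolute correlate `|log_fc|` instead of signed values.
#' @return list: `rho`, `p`, `n_genes`, `absolute`.
#' @export
foldchange_correlation <- function(res_a, res_b, gene_filter = NULL,
                                   absolute = FALSE) {
  genes <- intersect(res_a$gene_id[res_a$tested], res_b$gene_id[res_b$tested])
  if (!is.null(gene_filter)) {
    keep <- if (inherits(gene_filter, "de_gene_set")) gene_filter$members
            else gene_filter
    genes <- intersect(genes, keep)
  }
  if (length(genes) < 3) {
    stop_bad_arg("fewer than 3 shared genes after filtering")
  }
  xa <- res_a$log_fc[match(genes, res_a$gene_id)]
  xb <- res_b$log_fc[match(genes, res_b$gene_id)]
  if (absolute) {
    xa <- abs(xa)
    xb <- abs(xb)
  }
  rho <- stats::cor(rank(xa), rank(xb))
  n <- length(genes)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), n - 2)
  list(rho = rho, p = p, n_genes = n, absolute = absolute)
}

#' Multiway sharing of DE genes and Venn cell counts
#'
#' Fraction of the union of several DE sets that appears in at least
#' `min_sets` of them, plus the full Venn cell occupancy for 2 or 3 sets.
#'
#' @param sets list of 2 or more `de_gene_set` objects (or character
#'   vectors).
#' @param min_sets minimum number of sets a gene must appear in (default 2).
#' @return list: `fraction`, `n_union`, `n_shared`, `membership_counts`
#'   (table of how many sets each union gene belongs to), and `venn` (named
#'   cell counts, for up to 3 sets).
#' @export
multiway_sharing <- function(sets, min_sets = 2) {
  if (length(sets) < 2) stop_bad_arg("need at least 2 sets")
  check_number(min_sets, "min_sets", lower = 1, integer = TRUE)
  memb <- lapply(sets, function(s) {
    if (inherits(s, "de_gene_set")) s$members else as.character(s)
  })
  universe <- unique(unlist(memb))
  counts <- rowSums(vapply(memb, function(m) universe %in% m,
                           logical(length(universe))))
  n_shared <- sum(counts >= min_sets)
  fraction <- if (length(universe) == 0) 0 else n_shared / length(universe)
  venn <- NULL
  if (length(memb) <= 3) {
    inds <- vapply(memb, function(m) universe %in% m,
                   logical(length(universe)))
    if (length(universe) == 0) {
      inds <- matrix(logical(0), 0, length(memb))
    }
    labs <- apply(inds, 1, function(r) paste(ifelse(r, "1", "0"),
                                             collapse = ""))
    all_cells <- apply(expand.grid(rep(list(c("0", "1")), length(memb))),
                       1, paste, collapse = "")
    all_cells <- setdiff(all_cells, paste(rep("0", length(memb)),
                                          collapse = ""))
    venn <- vapply(all_cells, function(cl) sum(labs == cl), numeric(1))
  }
  list(fraction = fraction, n_union = length(universe), n_shared = n_shared,
       membership_counts = table(counts), venn = venn)
}
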