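# Per-contrast differential expression: oriented per-gene summaries, an
# empirical-Bayes moderated t with moment-matched hyperparameters,
# Benjamini-Hochberg adjustment, permutation FDR, and DE-set thresholding.

# Oriented M submatrix for a (mutant, reference) contrast: one column per
# hybridization comparing the two genotypes, signed mutant-minus-reference.
oriented_matrix <- function(ma, contrast) {
  des <- ma$design
  mutant <- contrast[1]
  reference <- contrast[2]
  fwd <- des$channel_red_genotype == mutant &
    des$channel_green_genotype == reference
  rev <- des$channel_red_genotype == reference &
    des$channel_green_genotype == mutant
  if (!any(fwd | rev)) {
    stop_bad_arg("no hybridizations compare ", mutant, " vs ", reference)
  }
  sel <- which(fwd | rev)
  sign <- ifelse(fwd[sel], 1, -1)
  sweep(ma$M[, sel, drop = FALSE], 2, sign, `*`)
}

#' Per-gene summaries for one genotype contrast
#'
#' Collects the M values of all hybridizations comparing the two genotypes,
#' re-oriented so positive means higher expression in the mutant, and
#' summarises each gene by its mean log2 fold-change, unbiased variance and
#' residual degrees of freedom. Genes with fewer than `min_obs` usable
#' observations are flagged untested.
#'
#' @param ma an `ma_matrix` (normally loess-normalised).
#' @param contrast character pair `c(mutant, reference)`.
#' @param min_obs minimum usable observations per gene (>= 2).
#' @return data.frame `gene_id, log_fc, s2, df, n_obs, tested` with
#'   attribute `contrast` = `"mutant_vs_reference"`.
#' @export
fit_contrast <- function(ma, contrast, min_obs = 2) {
  check_number(min_obs, "min_obs", lower = 2, integer = TRUE)
  x <- oriented_matrix(ma, contrast)
  out <- summarize_oriented(x, min_obs)
  attr(out, "contrast") <- paste0(contrast[1], "_vs_", contrast[2])
  out
}

# Invert the trigamma function by Newton iteration on 1/x scaling
# (monotone decreasing; convergence is quadratic from the asymptotic start).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t test per gene
#'
#' Estimates a scaled inverse-chi-square prior for the per-gene variances by
#' matching moments of `log(s2)` across genes (trigamma inversion for the
#' prior degrees of freedom `d0`, digamma correction for the prior variance
#' `s0^2`), shrinks each variance to
#' `s2_post = (d0*s0^2 + df*s2) / (d0 + df)`, and tests
#' `t = log_fc / sqrt(s2_post / n_obs)` against a t distribution on
#' `df + d0` degrees of freedom. As `d0 -> Inf` every variance collapses to
#' `s0^2`; at `d0 = 0` the statistic is the ordinary one-sample t.
#'
#' @param fits data.frame from [fit_contrast()].
#' @param prior_df optional fixed `d0` (bypasses estimation); `0` gives the
#'   ordinary t, `Inf` full shrinkage to `prior_var`.
#' @param prior_var optional fixed `s0^2`, used with `prior_df`; defaults to
#'   the mean observed variance.
#' @return ContrastResult data.frame adding `s2_post, t_mod, p, p_adj`
#'   columns; attributes `d0`, `s0_2` and `contrast` record the prior.
#' @export
moderate_and_test <- function(fits, prior_df = NULL, prior_var = NULL) {
  use <- fits$tested & !is.na(fits$df) & fits$df > 0
  d0_cap <- 1e6
  if (is.null(prior_df)) {
    if (sum(use) < 10) {
      stop_bad_arg("need at least 10 genes with positive df to estimate the prior")
    }
    s2 <- fits$s2[use]
    df <- fits$df[use]
    if (all(s2 == 0)) {
      warning("all residual variances are zero; using a point prior at machine precision")
      d0 <- d0_cap
      s0_2 <- .Machine$double.eps
    } else {
      pos <- s2 > 0
      z <- log(s2[pos])
      dfp <- df[pos]
      e <- z - digamma(dfp / 2) + log(dfp / 2)
      ebar <- mean(e)
      v <- stats::var(z)
      if (!is.finite(v) || v < 1e-12) {
        # point-mass empirical distribution: no spread to match, prior sits
        # exactly on the common variance
        d0 <- d0_cap
        s0_2 <- exp(mean(z))
      } else {
        resid_var <- mean((e - ebar)^2) * length(e) / (length(e) - 1) -
          mean(trigamma(dfp / 2))
        if (resid_var <= 0) {
          d0 <- d0_cap
        } else {
          d0 <- min(2 * trigamma_inverse(resid_var), d0_cap)
        }
        s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    d0 <- prior_df
    s0_2 <- prior_var %||% mean(fits$s2[use], na.rm = TRUE)
  }
  out <- fits
  out$s2_post <- if (is.infinite(d0)) {
    ifelse(out$tested, s0_2, NA_real_)
  } else {
    ifelse(out$tested,
           (d0 * s0_2 + out$df * out$s2) / (d0 + out$df),
           NA_real_)
  }
  out$t_mod <- out$log_fc / sqrt(out$s2_post / out$n_obs)
  df_total <- pmin(out$df + d0, 1e7)
  out$p <- 2 * stats::pt(-abs(out$t_mod), df_total)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- adjust_bh(out$p[out$tested])
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "contrast") <- attr(fits, "contrast")
  out
}

#' Fit and test one contrast in a single call
#'
#' Convenience wrapper: [fit_contrast()] followed by [moderate_and_test()].
#'
#' @inheritParams fit_contrast
#' @inheritParams moderate_and_test
#' @return ContrastResult data.frame.
#' @export
contrast_results <- function(ma, contrast, min_obs = 2, prior_df = NULL,
                             prior_var = NULL) {
  moderate_and_test(fit_contrast(ma, contrast, min_obs = min_obs),
                    prior_df = prior_df, prior_var = prior_var)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone in rank,
#' capped at 1), with input validation.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop_bad_arg("`p` must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_bad_arg("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Threshold a contrast into a differentially expressed gene set
#'
#' Members are the tested genes with raw `p < p_cut` and, when `fdr_cut` is
#' given, BH-adjusted `p_adj < fdr_cut`; each member carries the sign of its
#' log2 fold-change.
#'
#' @param results ContrastResult data.frame.
#' @param p_cut raw p-value threshold in (0, 1].
#' @param fdr_cut optional adjusted-p threshold in (0, 1].
#' @param label contrast label; defaults to the results' `contrast`
#'   attribute.
#' @return Object of class `de_gene_set`: list with `label`, `threshold`,
#'   `members` (character vector) and `direction` (named +1/-1 vector).
#' @export
call_de <- function(results, p_cut, fdr_cut = NULL, label = NULL) {
  check_number(p_cut, "p_cut", lower = 0, upper = 1, strict_lower = TRUE)
  if (!is.null(fdr_cut)) {
    check_number(fdr_cut, "fdr_cut", lower = 0, upper = 1, strict_lower = TRUE)
  }
  keep <- results$tested & !is.na(results$p) & results$p < p_cut
  if (!is.null(fdr_cut)) keep <- keep & results$p_adj < fdr_cut
  members <- results$gene_id[keep]
  direction <- sign(results$log_fc[keep])
  names(direction) <- members
  structure(list(label = label %||% attr(results, "contrast") %||% "contrast",
                 threshold = list(p_cut = p_cut, fdr_cut = fdr_cut),
                 members = members, direction = direction),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat("de_gene_set '", x$label, "': ", length(x$members), " genes (p < ",
      x$threshold$p_cut,
      if (!is.null(x$threshold$fdr_cut))
        paste0(", FDR < ", x$threshold$fdr_cut) else "",
      "); ", sum(x$direction > 0), " up / ", sum(x$direction < 0),
      " down\n", sep = "")
  invisible(x)
}

#' Permutation-based false discovery rate for one contrast
#'
#' Re-signs the oriented per-hybridization M vectors at random (a valid null
#' for dye-balanced direct two-colour comparisons), reruns the moderated
#' test, and records the number of genes passing `p_cut` in each permuted
#' dataset. The FDR estimate is the mean permuted discovery count divided by
#' the observed count, capped at 1.
#'
#' @param ma an `ma_matrix`.
#' @param contrast character pair `c(mutant, reference)`.
#' @param p_cut raw p-value threshold.
#' @param n_perm number of permutations (>= 10).
#' @param min_obs minimum observations per gene.
#' @param seed integer seed.
#' @return list: `observed_count`, `perm_counts` (length `n_perm`), `fdr`
#'   (NA with `undefined = TRUE` when the observed count is 0).
#' @export
permutation_fdr <- function(ma, contrast, p_cut, n_perm = 100, min_obs = 2,
                            seed = NULL) {
  check_number(n_perm, "n_perm", lower = 10, integer = TRUE)
  check_number(p_cut, "p_cut", lower = 0, upper = 1, strict_lower = TRUE)
  x <- oriented_matrix(ma, contrast)
  count_de <- function(xm) {
    fits <- summarize_oriented(xm, min_obs)
    res <- moderate_and_test(fits)
    sum(res$p < p_cut, na.rm = TRUE)
  }
  observed <- count_de(x)
  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), ncol(x), replace = TRUE)
      count_de(sweep(x, 2, flips, `*`))
    }, numeric(1))
  })
  fdr <- if (observed == 0) NA_real_ else min(1, mean(perm_counts) / observed)
  list(observed_count = observed, perm_counts = perm_counts, fdr = fdr,
       undefined = observed == 0)
}

# fit_contrast's per-gene summary applied to an already-oriented matrix
summarize_oriented <- function(x, min_obs = 2) {
  n_obs <- rowSums(!is.na(x))
  log_fc <- rowMeans(x, na.rm = TRUE)
  mu <- ifelse(n_obs > 0, log_fc, 0)
  s2 <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(n_obs - 1, 1)
  tested <- n_obs >= min_obs
  data.frame(gene_id = rownames(x),
             log_fc = ifelse(tested, log_fc, NA_real_),
             s2 = ifelse(tested, s2, NA_real_),
             df = ifelse(tested, n_obs - 1, NA_integer_),
             n_obs = n_obs, tested = tested, stringsAsFactors = FALSE)
}
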