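# qPCR relative quantification of rDNA copy number from Ct tables.

#' Relative rDNA copy number from qPCR threshold cycles
#'
#' Single-reference delta-Ct quantification: technical replicates are
#' averaged within each biological replicate; each biological replicate's
#' relative quantity is `efficiency^(mean reference Ct - sample Ct)`; the
#' genotype estimate is 100 times the mean across biological replicates,
#' reported with its standard deviation across biological replicates. The
#' reference genotype is 100% by construction.
#'
#' @param ct_table data.frame `(genotype, bio_rep, tech_rep, ct)`; rows with
#'   non-finite Ct are dropped with a warning.
#' @param reference_genotype label of the 100% reference.
#' @param efficiency per-cycle amplification efficiency in (1, 2]
#'   (default 2, perfect doubling).
#' @return data.frame: `genotype`, `percent_of_reference`, `sd`, `n_bio`,
#'   `n_tech`.
#' @examples
#' ct <- simulate_qpcr(seed = 1)
#' relative_copy_number(ct, "wt")
#' @export
relative_copy_number <- function(ct_table, reference_genotype,
                                 efficiency = 2.0) {
  need <- c("genotype", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(ct_table))) {
    stop_bad_arg("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (efficiency <= 1 || efficiency > 2) {
    stop_bad_arg("`efficiency` must lie in (1, 2]")
  }
  if (!reference_genotype %in% ct_table$genotype) {
    stop_bad_arg("reference genotype '", reference_genotype,
                 "' absent from Ct table")
  }
  bad <- !is.finite(ct_table$ct)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite Ct rejected")
    ct_table <- ct_table[!bad, ]
  }
  ref_mean <- mean(ct_table$ct[ct_table$genotype == reference_genotype])
  out <- do.call(rbind, lapply(unique(ct_table$genotype), function(g) {
    sub <- ct_table[ct_table$genotype == g, ]
    bio_ct <- tapply(sub$ct, sub$bio_rep, mean)
    q <- efficiency^(ref_mean - bio_ct)
    data.frame(genotype = g,
               percent_of_reference = 100 * mean(q),
               sd = 100 * stats::sd(q),
               n_bio = length(bio_ct),
               n_tech = round(nrow(sub) / length(bio_ct)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  # pin the reference at exactly 100%, rescaling every genotype by the same
  # factor so ratios between genotypes are untouched
  ref_pct <- out$percent_of_reference[out$genotype == reference_genotype]
  out$percent_of_reference <- out$percent_of_reference * 100 / ref_pct
  out$sd <- out$sd * 100 / ref_pct
  out
}
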