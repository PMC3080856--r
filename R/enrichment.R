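# Flat-category over-representation of DE genes: one-sided hypergeometric
# tests with a GeneMerge-style modified Bonferroni correction.

#' Category over-representation of a DE gene set
#'
#' For each category, the upper-tail hypergeometric probability of drawing
#' at least the observed number of category genes when sampling `|de_set|`
#' genes from the universe. The modified Bonferroni correction multiplies
#' each raw p by the number of categories represented by at least one
#' DE-set gene (the testable categories); plain Bonferroni over all
#' categories is available as an option. Categories are flat labels; no
#' ontology structure is assumed.
#'
#' @param de_set `de_gene_set` or character vector; must be a subset of
#'   `universe`.
#' @param universe character vector of all analysable genes.
#' @param categories data.frame `(gene_id, category_id)`; memberships
#'   outside the universe are ignored.
#' @param correction `"modified-bonferroni"` (default) or `"bonferroni"`.
#' @return data.frame sorted by corrected p: `category_id`, `n_in_set`,
#'   `n_in_universe`, `p_raw`, `p_corrected`.
#' @examples
#' cats <- data.frame(gene_id = paste0("g", 1:5), category_id = "c1")
#' category_enrichment(paste0("g", 1:5), paste0("g", 1:20), cats)
#' @export
category_enrichment <- function(de_set, universe, categories,
                                correction = c("modified-bonferroni",
                                               "bonferroni")) {
  correction <- match.arg(correction)
  de <- de_members(de_set)
  if (length(setdiff(de, universe))) {
    stop_bad_arg("DE gene(s) absent from the universe")
  }
  if (!is.data.frame(categories) ||
      !all(c("gene_id", "category_id") %in% names(categories)) ||
      nrow(categories) == 0) {
    stop_bad_arg("`categories` must be a nonempty (gene_id, category_id) table")
  }
  cats <- unique(categories[categories$gene_id %in% universe, ])
  split_genes <- split(cats$gene_id, cats$category_id)
  n_univ <- length(unique(universe))
  n_de <- length(unique(de))
  res <- do.call(rbind, lapply(names(split_genes), function(cid) {
    g <- split_genes[[cid]]
    k <- sum(de %in% g)
    K <- length(g)
    p <- if (k == 0) 1 else {
      stats::phyper(k - 1, K, n_univ - K, n_de, lower.tail = FALSE)
    }
    data.frame(category_id = cid, n_in_set = k, n_in_universe = K,
               p_raw = p, stringsAsFactors = FALSE)
  }))
  m <- if (correction == "modified-bonferroni") {
    sum(res$n_in_set >= 1)
  } else {
    nrow(res)
  }
  res$p_corrected <- pmin(1, res$p_raw * m)
  res[order(res$p_corrected, res$p_raw, res$category_id), ]
}
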