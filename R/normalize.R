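# Two-colour array preprocessing: spot tables -> M/A matrices -> loess
# normalisation within each hybridization.

#' Assemble M and A matrices from a spot table
#'
#' Computes per-spot `M = log2(R/G)` and `A = (log2 R + log2 G)/2` and
#' arranges them as genes x hybridizations matrices, with `NA` wherever a
#' spot failed quality control or is absent.
#'
#' @param spots SpotTable data.frame (see [simulate_arrays()] for schema).
#' @param design design data.frame; defines hybridization order and the
#'   genotype in each channel.
#' @return Object of class `ma_matrix`: list with `M`, `A` (matrices with
#'   gene rownames and hybridization colnames) and `design`.
#' @export
spots_to_ma <- function(spots, design) {
  need <- c("gene_id", "hybridization_id", "intensity_red",
            "intensity_green", "pass_qc")
  if (!all(need %in% names(spots))) {
    stop_bad_arg("spot table must have columns: ", paste(need, collapse = ", "))
  }
  ok <- spots$pass_qc
  if (any(ok & (spots$intensity_red <= 0 | spots$intensity_green <= 0))) {
    stop_bad_arg("non-positive intensities among pass_qc spots")
  }
  genes <- unique(spots$gene_id)
  hybs <- design$hybridization_id
  M <- A <- matrix(NA_real_, length(genes), length(hybs),
                   dimnames = list(genes, hybs))
  s <- spots[ok & spots$hybridization_id %in% hybs, ]
  i <- match(s$gene_id, genes)
  j <- match(s$hybridization_id, hybs)
  lr <- log2(s$intensity_red)
  lg <- log2(s$intensity_green)
  M[cbind(i, j)] <- lr - lg
  A[cbind(i, j)] <- (lr + lg) / 2
  structure(list(M = M, A = A, design = design), class = "ma_matrix")
}

#' @export
print.ma_matrix <- function(x, ...) {
  cat("ma_matrix:", nrow(x$M), "genes x", ncol(x$M), "hybridizations;",
      sum(is.na(x$M)), "missing cells\n")
  invisible(x)
}

#' Loess-normalise two-colour arrays
#'
#' Within each hybridization, replaces M by the residuals of a robust local
#' linear regression of M on A, removing intensity-dependent dye bias. Uses
#' degree-1 loess with a symmetric (redescending) loss and three robustness
#' iterations.
#'
#' @param spots a SpotTable data.frame, or an `ma_matrix` from
#'   [spots_to_ma()].
#' @param design design data.frame; required when `spots` is a spot table.
#' @param span loess span in (0, 1], default 0.4.
#' @return An `ma_matrix` with normalised M values.
#' @examples
#' ann <- generate_annotation(200, seed = 1)
#' tr <- generate_truth(ann, seed = 2)
#' des <- make_design(n_rep = 2)
#' spots <- simulate_arrays(ann, tr, des, seed = 3)
#' norm <- loess_normalize(spots, des)
#' @export
loess_normalize <- function(spots, design = NULL, span = 0.4) {
  check_number(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  ma <- if (inherits(spots, "ma_matrix")) spots else {
    if (is.null(design)) stop_bad_arg("`design` is required with a spot table")
    spots_to_ma(spots, design)
  }
  n_ok <- colSums(!is.na(ma$M))
  if (any(n_ok < 20)) {
    stop_bad_arg("hybridization(s) with fewer than 20 usable spots: ",
                 paste(colnames(ma$M)[n_ok < 20], collapse = ", "))
  }
  for (j in seq_len(ncol(ma$M))) {
    use <- !is.na(ma$M[, j])
    m <- ma$M[use, j]
    a <- ma$A[use, j]
    # robust (symmetric) fit; degenerate residual spread (e.g. noise-free
    # data) breaks the redescending weights, so fall back to least squares
    fit <- tryCatch(
      stats::loess(m ~ a, span = span, degree = 1, family = "symmetric",
                   control = stats::loess.control(iterations = 4,
                                                  surface = "interpolate")),
      error = function(e) stats::loess(m ~ a, span = span, degree = 1))
    ma$M[use, j] <- stats::residuals(fit)
  }
  ma
}
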