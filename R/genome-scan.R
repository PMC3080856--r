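# Positional analysis of DE genes: cytological-division profiles with
# representation correction, scanning window averages, sliding megabase
# window scans with an empirical null, heterochromatin-boundary checks, and
# chromosome-arm frequency tests.

de_members <- function(de_set) {
  if (inherits(de_set, "de_gene_set")) de_set$members else as.character(de_set)
}

#' Per-division DE profile with representation correction
#'
#' Counts DE genes and array-represented genes per cytological division
#' (1-102) and forms their ratio, correcting positional summaries for uneven
#' gene density and array representation. The ratio is flagged undefined
#' where no genes are represented.
#'
#' @param de_set `de_gene_set` or character vector of DE gene ids.
#' @param annotation annotation data.frame covering every DE gene.
#' @param represented character vector of genes represented on the array
#'   (defaults to all annotated genes).
#' @return data.frame: `division`, `arm`, `n_de`, `n_rep`, `ratio` (NA where
#'   `n_rep` is 0).
#' @export
division_profile <- function(de_set, annotation,
                             represented = annotation$gene_id) {
  de <- de_members(de_set)
  missing <- setdiff(de, annotation$gene_id)
  if (length(missing)) {
    stop_bad_arg("DE gene(s) missing from annotation: ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..." else "")
  }
  divs <- unlist(lapply(ARM_DIVISIONS, function(r) r[1]:r[2]))
  arm_of <- rep(names(ARM_DIVISIONS),
                vapply(ARM_DIVISIONS, function(r) r[2] - r[1] + 1L, 1L))
  idx_rep <- annotation$gene_id %in% represented
  n_rep <- vapply(divs, function(d) {
    sum(annotation$division[idx_rep] == d)
  }, numeric(1))
  idx_de <- annotation$gene_id %in% de
  n_de <- vapply(divs, function(d) {
    sum(annotation$division[idx_de] == d)
  }, numeric(1))
  data.frame(division = divs, arm = arm_of, n_de = n_de, n_rep = n_rep,
             ratio = ifelse(n_rep > 0, n_de / n_rep, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scanning moving average within chromosome arms
#'
#' Centred moving average of a per-division series, computed within each arm
#' separately and truncated at arm boundaries (no wraparound between arms).
#' A window of 1 returns the series unchanged.
#'
#' @param values numeric per-division values.
#' @param arms character vector, same length, giving each division's arm.
#' @param window_divs odd window width in divisions (default 5).
#' @return Smoothed numeric vector.
#' @export
scanning_average <- function(values, arms, window_divs = 5) {
  check_number(window_divs, "window_divs", lower = 1, integer = TRUE)
  if (window_divs %% 2 == 0) stop_bad_arg("`window_divs` must be odd")
  if (length(values) != length(arms)) {
    stop_bad_arg("`values` and `arms` must have equal length")
  }
  half <- (window_divs - 1) / 2
  out <- numeric(length(values))
  for (a in unique(arms)) {
    i <- which(arms == a)
    v <- values[i]
    out[i] <- vapply(seq_along(v), function(j) {
      lo <- max(1, j - half)
      hi <- min(length(v), j + half)
      mean(v[lo:hi])
    }, numeric(1))
  }
  out
}

# Window start positions tiling an arm: half-open [start, start + width),
# with the final window truncated at the arm end so the tiling covers the
# whole arm. An arm shorter than the window gets a single window.
window_starts <- function(arm_len, width, step) {
  if (arm_len <= width) return(0)
  n <- ceiling((arm_len - width) / step) + 1
  (seq_len(n) - 1) * step
}

#' Sliding-window scan for positional DE enrichment
#'
#' Tiles every chromosome arm with windows of `width_mb` at `step_mb`
#' increments (half-open intervals), counts DE genes per window, and
#' compares each window's count with the counts obtained from `n_random`
#' random gene sets of the same size as the DE set, drawn uniformly from the
#' represented genes. Per-window empirical p-values use the add-one rule;
#' a family-wise mode compares each window against the maximum count over
#' all windows in each random set.
#'
#' @param de_set `de_gene_set` or character vector.
#' @param annotation annotation data.frame.
#' @param represented universe the random sets are drawn from (defaults to
#'   all annotated genes).
#' @param width_mb window width in Mb (default 2).
#' @param step_mb step in Mb (default 1); must satisfy `width >= step > 0`.
#' @param n_random random sets (>= 100; default 1000).
#' @param arm_lengths_mb named arm lengths.
#' @param null one of `"per-window"` (each window against its own null) or
#'   `"max-over-windows"` (family-wise).
#' @param seed integer seed.
#' @return data.frame: `arm`, `start_mb`, `end_mb`, `n_de`, `n_total`,
#'   `empirical_p`; attributes record the scan parameters.
#' @export
sliding_window_scan <- function(de_set, annotation,
                                represented = annotation$gene_id,
                                width_mb = 2, step_mb = 1, n_random = 1000,
                                arm_lengths_mb = default_arm_lengths(),
                                null = c("per-window", "max-over-windows"),
                                seed = NULL) {
  null <- match.arg(null)
  check_number(width_mb, "width_mb", lower = 0, strict_lower = TRUE)
  check_number(step_mb, "step_mb", lower = 0, strict_lower = TRUE)
  if (width_mb < step_mb) stop_bad_arg("need width_mb >= step_mb")
  check_number(n_random, "n_random", lower = 100, integer = TRUE)
  de <- de_members(de_set)
  rep_idx <- which(annotation$gene_id %in% represented)
  n_rep <- length(rep_idx)
  n_de <- length(intersect(de, annotation$gene_id[rep_idx]))

  # window table over all arms restricted to arms present in the annotation
  arms <- intersect(names(arm_lengths_mb), unique(annotation$arm))
  wins <- do.call(rbind, lapply(arms, function(a) {
    st <- window_starts(arm_lengths_mb[[a]], width_mb, step_mb)
    data.frame(arm = a, start_mb = st,
               end_mb = pmin(st + width_mb, arm_lengths_mb[[a]]),
               stringsAsFactors = FALSE)
  }))
  n_win <- nrow(wins)

  # gene -> windows incidence (each represented gene hits the windows whose
  # half-open interval contains its point position)
  gene_windows <- vector("list", n_rep)
  counts_total <- integer(n_win)
  for (w in seq_len(n_win)) {
    hit <- annotation$arm[rep_idx] == wins$arm[w] &
      annotation$position_mb[rep_idx] >= wins$start_mb[w] &
      annotation$position_mb[rep_idx] < wins$start_mb[w] + width_mb
    counts_total[w] <- sum(hit)
    for (g in which(hit)) gene_windows[[g]] <- c(gene_windows[[g]], w)
  }
  count_in_windows <- function(idx) {
    w <- unlist(gene_windows[idx])
    if (is.null(w)) integer(n_win) else tabulate(w, nbins = n_win)
  }
  obs <- count_in_windows(which(annotation$gene_id[rep_idx] %in% de))

  exceed <- integer(n_win)
  with_seed(seed, {
    for (r in seq_len(n_random)) {
      rnd <- count_in_windows(sample.int(n_rep, n_de))
      if (null == "per-window") {
        exceed <- exceed + (rnd >= obs)
      } else {
        exceed <- exceed + (max(rnd) >= obs)
      }
    }
  })
  out <- data.frame(wins, n_de = obs, n_total = counts_total,
                    empirical_p = (1 + exceed) / (n_random + 1),
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(width_mb = width_mb, step_mb = step_mb,
                              n_random = n_random, null = null,
                              n_de = n_de, seed = seed)
  out
}

#' DE count among the genes nearest a chromosome-arm end
#'
#' Sorts an arm's genes by distance from the chosen end (proximal = the
#' centromeric end at maximal Mb position, distal = the telomeric end at
#' position 0), counts DE genes among the nearest `n_genes`, and reports the
#' upper-tail binomial probability of a count at least that large under the
#' genome-wide DE rate.
#'
#' @param annotation annotation data.frame.
#' @param arm arm label.
#' @param from_end `"proximal"` or `"distal"`.
#' @param n_genes number of boundary genes to inspect (default 20).
#' @param de_set `de_gene_set` or character vector.
#' @param de_rate genome-wide DE rate used for the binomial reference;
#'   defaults to `|DE| / n_annotated`.
#' @return list: `count`, `n_genes`, `genes` (ids inspected), `binom_p`.
#' @export
boundary_check <- function(annotation, arm, from_end = c("proximal", "distal"),
                           n_genes = 20, de_set, de_rate = NULL) {
  from_end <- match.arg(from_end)
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  sub <- annotation[annotation$arm == arm, ]
  if (nrow(sub) < n_genes) {
    stop_bad_arg("arm ", arm, " has only ", nrow(sub), " genes")
  }
  ord <- order(sub$position_mb, decreasing = (from_end == "proximal"))
  nearest <- sub$gene_id[ord][seq_len(n_genes)]
  de <- de_members(de_set)
  count <- sum(nearest %in% de)
  rate <- de_rate %||% (length(intersect(de, annotation$gene_id)) /
                          nrow(annotation))
  binom_p <- if (count == 0) 1 else {
    stats::pbinom(count - 1, n_genes, rate, lower.tail = FALSE)
  }
  list(count = count, n_genes = n_genes, genes = nearest, binom_p = binom_p)
}

#' Per-arm DE frequency versus array representation
#'
#' Compares the observed number of DE genes per chromosome arm with the
#' expectation under proportional allocation across represented genes, and
#' reports each arm's DE rate relative to the rest of the genome. The
#' global test is a chi-square goodness of fit; when any expected count is
#' below 5 an exact binomial test per arm (Bonferroni-combined minimum) is
#' used instead.
#'
#' @param de_set `de_gene_set` or character vector.
#' @param annotation annotation data.frame.
#' @param represented character vector of represented genes.
#' @return list: `table` (data.frame `arm, n_rep, observed, expected,
#'   relative_frequency`), `p`, `method`.
#' @export
arm_frequency_test <- function(de_set, annotation,
                               represented = annotation$gene_id) {
  de <- intersect(de_members(de_set), represented)
  sub <- annotation[annotation$gene_id %in% represented, ]
  arms <- sort(unique(sub$arm))
  n_rep <- vapply(arms, function(a) sum(sub$arm == a), numeric(1))
  if (any(n_rep == 0)) stop_bad_arg("arm with no represented genes")
  is_de <- sub$gene_id %in% de
  obs <- vapply(arms, function(a) sum(is_de & sub$arm == a), numeric(1))
  expected <- length(de) * n_rep / sum(n_rep)
  rate_on <- obs / n_rep
  rate_off <- (length(de) - obs) / (sum(n_rep) - n_rep)
  rel <- ifelse(rate_off > 0, rate_on / rate_off,
                ifelse(rate_on > 0, Inf, NA_real_))
  if (length(de) == 0) {
    p <- 1
    method <- "degenerate"
  } else if (any(expected < 5)) {
    pb <- vapply(seq_along(arms), function(i) {
      stats::binom.test(obs[i], length(de), n_rep[i] / sum(n_rep))$p.value
    }, numeric(1))
    p <- min(1, min(pb) * length(arms))
    method <- "binomial-bonferroni"
  } else {
    p <- suppressWarnings(
      stats::chisq.test(obs, p = n_rep / sum(n_rep))$p.value)
    method <- "chi-square"
  }
  list(table = data.frame(arm = arms, n_rep = n_rep, observed = obs,
                          expected = expected, relative_frequency = rel,
                          row.names = NULL, stringsAsFactors = FALSE),
       p = p, method = method)
}
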