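# Internal helpers: argument checking, seeded evaluation, TSV I/O with
# provenance sidecars.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg("`", name, "` must be a single finite number")
  }
  if (integer && x != round(x)) {
    stop_bad_arg("`", name, "` must be an integer")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop_bad_arg("`", name, "` must be in ",
                 if (strict_lower) "(" else "[", lower, ", ", upper, "]")
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed", integer = TRUE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage label;
# kept below 2^31 so it is a valid R integer.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483563) + 1L
}

#' Write a table as TSV with a provenance sidecar
#'
#' Writes `x` tab-separated with a header line, plus `<path>.prov` recording
#' the generating parameters and seed, so any stage can be re-run from its
#' inputs alone.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param params named list recorded in the sidecar (may be empty).
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, params = list()) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(paste0("written\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             paste0("rows\t", nrow(x)))
  if (length(params)) {
    lines <- c(lines, vapply(names(params), function(n) {
      paste0(n, "\t", paste(format(params[[n]]), collapse = ","))
    }, character(1)))
  }
  writeLines(lines, paste0(path, ".prov"))
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
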