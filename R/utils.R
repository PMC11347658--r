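#' @importFrom methods new validObject is as slot
#' @importFrom stats rnorm runif rbinom rnbinom rbeta rlnorm rmultinom
#'   pnorm p.adjust setNames coef logLik qlogis plogis sd cor quantile
#'   complete.cases aggregate
#' @importFrom utils read.delim write.table head combn
NULL

#' Derive a child seed from a master seed and a component key
#'
#' A single master seed streams per-component seeds so that sub-generators
#' (cohort, genome, counts, splits, permutations, ...) are independently
#' reproducible: regenerating one component never perturbs another.
#' The child seed is a deterministic hash of the key folded into the master
#' seed, kept below 2^31 so it is a valid R integer seed on all platforms.
#'
#' @param seed master integer seed
#' @param key character key naming the component (e.g. \code{"cohort"})
#' @return an integer seed
#' @export
childSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 0
  for (v in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + v) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

logit <- function(p) qlogis(p)

invLogit <- function(x) plogis(x)

#' @noRd
.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required field(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## Tab-separated tables: header row required, no quoting, UTF-8.
readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, check.names = FALSE)
}

writeTsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
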