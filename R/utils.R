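# shared helpers: seeding, table IO, small numeric utilities

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' The pipeline fans one user-facing seed out to per-stage (and per-species)
#' seeds so that each stage is independently reproducible. The derivation is
#' a small polynomial string hash folded into the master seed, kept strictly
#' below 2^31 so it is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param tag character tag naming the consumer (e.g. "simulate/cow")
#' @return a single integer seed
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% 2147483629
  as.integer((abs(seed) %% 2147483629 + h * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Write a data frame as a TSV file
#'
#' All inter-stage tables in the pipeline are plain TSV with a header line,
#' no quoting and no row names.
#'
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#' @param path input path
#' @return data frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# stable per-element pmin/pmax on two integer vectors without recycling
# surprises; used by the event bookkeeping
pos_part <- function(x) pmax(x, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
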