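# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the previous RNG state so
#' package internals never disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a label; stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.integer(seed) %% 1000000L) * 2049L + (h %% 2048L)
}

#' Short deterministic hash of an R object
#'
#' md5 of the deparsed object text, truncated to 10 hex characters. Used to
#' stamp run configurations into output artifacts.
#' @param x any serializable R object.
#' @return character scalar.
#' @export
config_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x, control = c("exact")), f)
  unname(substr(tools::md5sum(f), 1L, 10L))
}

# Format numerics so that write -> read round-trips are exact.
num_chr <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

stop_rp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_rp <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
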