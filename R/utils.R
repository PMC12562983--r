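# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator internals never disturb
#' the caller's RNG stream. Seeds must stay below 2^31 - 1.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage substream seed from the master seed by fixed offset,
# folded into [0, 2^31 - 2] so it is always a valid 32-bit seed.
stage_seed <- function(seed, offset) {
  (as.numeric(seed) + as.numeric(offset)) %% 2147483646
}

# Sample an integer uniformly from an inclusive [lo, hi] range given as a
# length-2 vector (single-valued ranges allowed).
sample_range <- function(range, n = 1) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

sample_real_range <- function(range, n = 1) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
}

# Format numbers for on-disk text output: fixed notation, trailing zeros
# trimmed, locale-independent. Guarantees byte-stable output across runs.
fmt_num <- function(x, digits = 6) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
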