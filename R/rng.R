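#' Derive a reproducible substream seed
#'
#' Hashes a base seed together with a character label (typically an operation
#' name plus indices) into a 31-bit integer seed. Each operation draws from
#' its own named substream so that adding variables or stages to a pipeline
#' does not perturb the random numbers used by earlier stages.
#'
#' @param seed Integer base seed.
#' @param ... Further components (coerced to character) identifying the
#'   substream, e.g. an operation name and an imputation index.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  # FNV-1a style 31-bit hash; arithmetic kept below 2^53 so it is exact
  h <- 216613626
  for (ch in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483647)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that package internals never disturb the user's random stream.
#'
#' @param seed Integer seed for the temporary stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
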