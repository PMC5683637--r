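# internal helpers: seeded evaluation and per-cell seed derivation

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL evaluates expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Deterministic 31-bit hash of the master seed and any number of factor
#' labels, so every cell of a factorial design gets an independent,
#' order-free, reproducible seed.
#'
#' @param master integer master seed
#' @param ... further atomic values (factor levels, replicate ids, ...)
#' @return a single integer in `[0, 2^31 - 2]`
#' @examples
#' deriveSeed(42, "generalist", "GLM", 10, 0)
#' @export
deriveSeed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character,
    character(1))), collapse = "|")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
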