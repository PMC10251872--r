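# internal helpers shared across modules

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# One stream per generated study: reproducibility of whole studies, not of
# individual draws.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0/1 indicator matrix of a grouping vector (works for single-level groups,
# unlike model.matrix without intercept)
indicator_matrix <- function(f) {
  f <- factor(f)
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# zero-padded id vectors: gene_001, PW_01, ...
padded_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(1L, nchar(as.character(n))), "d"), seq_len(n))
}
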