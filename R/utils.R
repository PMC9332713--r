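#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary label tuple
#' (polynomial rolling hash over the labels' UTF-8 bytes) into a 31-bit
#' integer seed. Every seeded stage of the pipeline derives its seed
#' this way from the experiment's master seed and its grid coordinates,
#' so any subset of an experiment grid can be recomputed independently.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return An integer in `[1, 2^31 - 2]`, safe for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "\x1f")
  for (b in utf8ToInt(labels)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a single nonnegative number", name))
  }
  invisible(as.numeric(x))
}

# Provenance key used to index feature matrices by (subject, session,
# segment).
prov_key <- function(subject, session, segment) {
  paste(subject, session, segment, sep = "|")
}
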