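# internal helpers: seeded RNG scoping and deterministic seed derivation

# evaluate `code` under set.seed(seed) without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic per-(id, index) seed derived from a master seed, so that
# adding a specimen to a sample never perturbs the others' subsamples.
# Kept below 2^31 - 1; arithmetic stays exact in doubles (< 2^53).
derive_seed <- function(seed, id, index) {
  stopifnot(length(id) == 1L, length(index) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 97 + index * 1009) %%
               2147483629 + 1)
}

stop_usage <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
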