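`%||%` <- function(a, b) if (is.null(a)) b else a

# Run fn() under a temporary RNG state so library internals (e.g. optimizer
# restarts with their fixed seed) do not disturb the caller's stream.
with_preserved_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

stop_riacd <- function(msg, class) {
  stop(structure(
    class = c(class, "riacd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

# Tiny deterministic content hash for provenance headers (no digest dependency).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
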