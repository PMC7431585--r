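# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Hemisphere of a 10/20 label: odd trailing number = left, even = right,
# 'z' suffix (or no digits) = midline.
channel_side <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  side <- ifelse(is.na(num), "midline", ifelse(num %% 2L == 1L, "left", "right"))
  side
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
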