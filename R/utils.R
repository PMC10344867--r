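#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulators never leak global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop_input("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  expr
}

# Derive a well-specific 31-bit seed from a base seed and a well index.
# Products stay far below 2^53 so double arithmetic is exact.
derive_seed <- function(seed, index) {
  as.integer(((abs(seed) %% 100000) * 20011 + index * 7919 + 1) %% 2147483646L) + 1L
}

# Error helpers carrying condition classes the CLI maps to exit codes:
# input errors -> 2, degenerate-statistics errors -> 3.
stop_input <- function(...) {
  stop(structure(class = c("liposcreen_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("liposcreen_degenerate_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Well address helpers: rows A..P as letters, columns as integers.
well_name <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

# FNV-1a hash of a deparsed object, used to stamp outputs with a config hash.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
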