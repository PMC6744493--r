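#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG stream started at `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber the
# global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-task seed from a base seed, staying inside 32-bit integer
# range whatever the base is.
derive_seed <- function(base_seed, offset) {
  as.integer((as.numeric(base_seed) + 104729 * as.numeric(offset)) %% .Machine$integer.max)
}

stop_missing_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Canonical unordered gene pair: lexicographically smaller symbol first.
order_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}
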