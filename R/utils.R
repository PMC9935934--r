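#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_that <- function(cond, ...) if (!isTRUE(cond)) stop_input(...)

# row-wise Euclidean norm of an n x 3 matrix
row_norm <- function(m) sqrt(rowSums(m * m))

unit <- function(v) v / sqrt(sum(v * v))

deg2rad <- function(d) d * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a
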