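# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic child seed from a master seed; kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483646L) + 1L
}

# Coordinates (voxel index triples) of TRUE voxels, in array scan order.
which_coords <- function(x) {
  arrayInd(which(x), dim(x))
}

assert_same_grid <- function(a, b, what = "maps") {
  if (!identical(dim(a), dim(b))) {
    stopf("%s do not share the same grid: %s vs %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
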