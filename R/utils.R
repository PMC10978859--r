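# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Spatial dimensionality of an array-backed object (2 or 3).
ndim_of <- function(x) length(dim(x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# TRUE when two spatial shapes agree.
same_shape <- function(a, b) identical(dim(a), dim(b))

# Clamp numeric vector to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Linear index arithmetic ------------------------------------------------

# Row/col(/plane) integer coordinates of linear indices in an array of
# dimensions `dm` (column-major, 1-based).
index_to_coord <- function(idx, dm) {
  nd <- length(dm)
  out <- matrix(0L, length(idx), nd)
  rem <- idx - 1L
  for (a in seq_len(nd)) {
    out[, a] <- as.integer(rem %% dm[a]) + 1L
    rem <- rem %/% dm[a]
  }
  out
}

coord_to_index <- function(co, dm) {
  co <- as.matrix(co)
  idx <- co[, 1]
  mult <- 1
  for (a in seq_len(ncol(co))[-1]) {
    mult <- mult * dm[a - 1]
    idx <- idx + (co[, a] - 1) * mult
  }
  as.integer(idx)
}

# All 8- (2D) or 26- (3D) neighbour integer offsets as a matrix, one row
# per offset; `half = TRUE` returns only the lexicographically positive half.
neighbour_offsets <- function(nd, half = FALSE) {
  stopifnot(nd %in% c(2L, 3L))
  g <- if (nd == 2L) expand.grid(dr = -1:1, dc = -1:1)
       else expand.grid(dr = -1:1, dc = -1:1, dp = -1:1)
  g <- as.matrix(g)
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (half) {
    keep <- apply(g, 1, function(v) {
      nz <- which(v != 0)[1]
      v[nz] > 0
    })
    g <- g[keep, , drop = FALSE]
  }
  g
}
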