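# Connected-component labelling.
#
# Foreground connectivity is 8-connected in 2D and 26-connected in 3D
# throughout the package (matching the skeleton neighbour taxonomy).
# Labelling builds the pixel-adjacency graph over foreground pixels and
# takes its connected components via igraph, which keeps the
# implementation independent of the flood-fill oracle used in the tests.

#' Label connected components of a mask
#'
#' @param mask a [binary_mask()] or logical array.
#' @return Integer array of the same shape: 0 for background, components
#'   numbered 1..n in order of their first pixel (column-major scan).
#' @export
label_components <- function(mask) {
  fg <- if (inherits(mask, "binary_mask")) mask$data else mask
  dm <- dim(fg)
  nd <- length(dm)
  labels <- array(0L, dm)
  n_fg <- sum(fg)
  if (n_fg == 0L) return(labels)
  rank <- array(0L, dm)
  rank[fg] <- seq_len(n_fg)
  offs <- neighbour_offsets(nd, half = TRUE)
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    v <- offs[k, ]
    # region of source pixels whose neighbour p + v stays in bounds
    src <- Map(function(d, o) max(1, 1 - o):min(d, d - o), dm, v)
    a <- do.call(`[`, c(list(fg), src, list(drop = FALSE)))
    dst <- Map(function(r, o) r + o, src, v)
    b <- do.call(`[`, c(list(fg), dst, list(drop = FALSE)))
    hit <- which(a & b)
    if (!length(hit)) next
    co <- index_to_coord(hit, vapply(src, length, 1L))
    co <- sweep(co, 2L, vapply(src, function(r) r[1] - 1L, 1L), `+`)
    ia <- coord_to_index(co, dm)
    ib <- coord_to_index(sweep(co, 2L, v, `+`), dm)
    edges <- c(edges, rbind(rank[ia], rank[ib]))
  }
  g <- igraph::make_graph(edges = edges, n = n_fg, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber so labels follow first-pixel scan order
  relab <- integer(max(memb))
  relab[unique(memb[order(seq_len(n_fg))])] <- seq_along(unique(memb))
  labels[fg] <- relab[memb]
  labels
}

#' Number of connected components of a mask
#' @inheritParams label_components
#' @return Integer count.
#' @export
count_components <- function(mask) {
  lab <- label_components(mask)
  max(lab)
}
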