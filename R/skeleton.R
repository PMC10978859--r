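# Topology-preserving thinning and skeleton accounting.
#
# A single sequential border-peeling scheme serves 2D and 3D: in each
# cycle, every face direction contributes a sub-iteration that deletes
# border pixels which are "simple" (deletion preserves local topology) and
# not line endpoints, re-checking simpleness at deletion time so no
# parallel-deletion artefacts arise. Simpleness uses the crossing-number
# test in 2D (8-connected foreground, 4-connected background) and the
# Malandain-Bertrand characterisation in 3D (26/6 connectivity). Because
# any thinning erodes terminal segments by roughly the local radius,
# skeleton endpoints are optionally extended along their own direction to
# the mask boundary, which keeps centerline lengths of tube-like objects
# close to the true length.

#' Skeletonize a mask to one-pixel-wide lines
#'
#' @param mask a [binary_mask()] (2D or 3D).
#' @param extend_ends extend each skeleton endpoint along its local
#'   direction until the mask boundary, compensating the end erosion
#'   inherent to thinning (default `TRUE`).
#' @return An object of class `skeleton_image`: a logical raster that is a
#'   subset of the mask foreground, thin (no pixel has a fully-foreground
#'   3x3(x3) neighbourhood) and component-preserving.
#' @export
skeletonize_mask <- function(mask, extend_ends = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  fg <- thin_mask(mask$data)
  if (extend_ends) fg <- extend_skeleton_ends(fg, mask$data)
  structure(list(data = fg, calibration = mask$calibration,
                 unit = mask$unit),
            class = c("skeleton_image", "binary_mask"))
}

#' @export
print.skeleton_image <- function(x, ...) {
  cat(sprintf("<skeleton_image> %s, %d skeleton pixels\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# -- thinning ---------------------------------------------------------------

thin_mask <- function(fg) {
  dm <- dim(fg)
  nd <- length(dm)
  # work on a background-padded copy so neighbour indexing never leaves
  # the raster
  pdm <- dm + 2L
  pad <- array(FALSE, pdm)
  core <- lapply(dm, function(d) 2:(d + 1L))
  pad <- do.call(`[<-`, c(list(pad), core, list(fg)))
  offs <- neighbour_offsets(nd)
  off_lin <- as.integer(offs %*% cumprod(c(1L, pdm[-nd])))
  dirs <- face_directions(nd)
  dir_lin <- as.integer(dirs %*% cumprod(c(1L, pdm[-nd])))
  simple_test <- if (nd == 2L) simple2d_factory(off_lin, offs)
                 else simple3d_factory(off_lin, offs)
  repeat {
    deleted <- 0L
    for (d in seq_len(nrow(dirs))) {
      cand <- which(pad)
      cand <- cand[!pad[cand + dir_lin[d]]]
      for (p in cand) {
        if (!pad[p]) next
        nb <- pad[p + off_lin]
        if (sum(nb) < 2L) next              # endpoint or isolated
        if (simple_test(nb)) {
          pad[p] <- FALSE
          deleted <- deleted + 1L
        }
      }
    }
    if (deleted == 0L) break
  }
  out <- do.call(`[`, c(list(pad), core, list(drop = FALSE)))
  array(out, dm)
}

face_directions <- function(nd) {
  if (nd == 2L)
    matrix(c(0L, 1L, 0L, -1L, 1L, 0L, -1L, 0L), ncol = 2, byrow = TRUE)
  else rbind(
    c(0L, 0L, 1L), c(0L, 0L, -1L), c(0L, 1L, 0L),
    c(0L, -1L, 0L), c(1L, 0L, 0L), c(-1L, 0L, 0L))
}

# 2D: deletable iff the 8-neighbour ring has exactly one foreground run
# (crossing number A == 1). `offs` rows follow neighbour_offsets(2).
simple2d_factory <- function(off_lin, offs) {
  # ring order: E, NE, N, NW, W, SW, S, SE by angle
  ang <- atan2(-offs[, 1], offs[, 2])
  ring <- order(ang)
  function(nb) {
    r <- nb[ring]
    sum(r & !r[c(8L, 1:7)]) == 1L
  }
}

# 3D: Malandain-Bertrand simpleness. C* = number of 26-components of
# foreground in the 26-neighbourhood; Cbar = number of 6-components of
# background within the 18-neighbourhood that touch a face neighbour.
simple3d_factory <- function(off_lin, offs) {
  n_off <- nrow(offs)
  cheb <- as.matrix(dist(offs, method = "maximum")) <= 1
  diag(cheb) <- FALSE
  adj26 <- lapply(seq_len(n_off), function(i) which(cheb[i, ]))
  manh <- as.matrix(dist(offs, method = "manhattan"))
  is18 <- rowSums(abs(offs)) <= 2L
  isface <- rowSums(abs(offs)) == 1L
  adj6 <- lapply(seq_len(n_off), function(i)
    which(manh[i, ] == 1 & is18))
  function(nb) {
    # C*: components of foreground under 26-adjacency
    fgi <- which(nb)
    if (count_nbhd_components(fgi, adj26) != 1L) return(FALSE)
    # Cbar: 6-components of background among the 18-neighbourhood that
    # contain at least one face neighbour
    bgi <- which(!nb & is18)
    if (!length(bgi)) return(FALSE)
    comp <- nbhd_components(bgi, adj6)
    face_comp <- unique(comp[isface[bgi]])
    face_comp <- face_comp[!is.na(face_comp)]
    length(face_comp) == 1L
  }
}

# Number of connected components of the index set `set` under the
# precomputed neighbourhood adjacency lists.
count_nbhd_components <- function(set, adj) {
  if (!length(set)) return(0L)
  comp <- nbhd_components(set, adj)
  max(comp)
}

nbhd_components <- function(set, adj) {
  comp <- integer(length(set))
  pos <- integer(max(vapply(adj, function(a) if (length(a)) max(a) else 0L, 0L),
                     set))
  pos[set] <- seq_along(set)
  cur <- 0L
  for (i in seq_along(set)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[set[v]]]) {
        j <- if (w <= length(pos)) pos[w] else 0L
        if (j > 0L && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# Extend every skeleton endpoint along its own direction (estimated from
# the last few skeleton steps) until the mask boundary, using an
# 8/26-connected digital ray.
extend_skeleton_ends <- function(skel, mask) {
  dm <- dim(skel)
  nd <- length(dm)
  nbc <- neighbour_count(skel)
  ends <- which(skel & nbc == 1L)
  if (!length(ends)) return(skel)
  offs <- neighbour_offsets(nd)
  adj <- adjacency_lists(skel)
  for (e in ends) {
    # walk back up to 4 steps along the (unbranched) path
    path <- e
    prev <- -1L
    cur <- e
    for (step in 1:4) {
      nxt <- setdiff(adj[[as.character(cur)]], prev)
      if (length(nxt) != 1L) break
      prev <- cur; cur <- nxt
      path <- c(path, cur)
    }
    if (length(path) < 2L) next
    a <- index_to_coord(path[length(path)], dm)[1, ]
    b <- index_to_coord(path[1], dm)[1, ]
    dirv <- (b - a) / sqrt(sum((b - a)^2))
    ray <- digital_ray(b, dirv, dm)
    for (ri in seq_len(nrow(ray))) {
      pi_ <- coord_to_index(ray[ri, , drop = FALSE], dm)
      if (!mask[pi_]) break
      skel[pi_] <- TRUE
    }
  }
  skel
}

# 8/26-connected digital ray from `start` (excluded) along unit vector
# `dirv`, clipped to the raster.
digital_ray <- function(start, dirv, dm) {
  max_len <- ceiling(sqrt(sum(dm^2)))
  step <- dirv / max(abs(dirv))        # dominant-axis DDA, step <= 1 per axis
  pts <- sweep(outer(seq_len(max_len), step), 2, start, `+`)
  pts <- round(pts)
  keep <- rowSums(pts < 1 | sweep(pts, 2, dm, `>`)) == 0
  pts <- pts[keep, , drop = FALSE]
  pts[!duplicated(pts), , drop = FALSE]
}

# Per-pixel count of foreground neighbours (8/26).
neighbour_count <- function(fg) {
  dm <- dim(fg)
  nd <- length(dm)
  out <- array(0L, dm)
  for (k in seq_len(nrow(neighbour_offsets(nd)))) {
    v <- neighbour_offsets(nd)[k, ]
    out <- out + shift_logical(fg, v)
  }
  out
}

# fg shifted so result[p] = fg[p + v], FALSE outside.
shift_logical <- function(fg, v) {
  dm <- dim(fg)
  out <- array(0L, dm)
  src <- Map(function(d, o) max(1, 1 + o):min(d, d + o), dm, v)
  dst <- Map(function(r, o) r - o, src, v)
  do.call(`[<-`, c(list(out), dst,
                   list(do.call(`[`, c(list(fg), src, list(drop = FALSE))) * 1L)))
}

# Foreground adjacency lists keyed by linear index (as character).
adjacency_lists <- function(fg) {
  dm <- dim(fg)
  nd <- length(dm)
  idx <- which(fg)
  offs <- neighbour_offsets(nd, half = TRUE)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (k in seq_len(nrow(offs))) {
    v <- offs[k, ]
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
    pairs_a <- c(pairs_a, ia, ib)
    pairs_b <- c(pairs_b, ib, ia)
  }
  adj <- split(pairs_b, pairs_a)
  # ensure isolated pixels are present
  missing <- setdiff(as.character(idx), names(adj))
  adj[missing] <- list(integer(0))
  adj
}

# -- skeleton analysis ------------------------------------------------------

#' Analyze a skeleton: branches, junctions, endpoints, lengths
#'
#' Pixels are classified by their skeleton-neighbour count (8-connected in
#' 2D, 26-connected in 3D): endpoint (< 2), slab (= 2), junction (> 2).
#' Adjacent junction pixels merge into one junction node; a node with
#' exactly three incident branch ends is a triple point, with four a
#' quadruple point. Branch length is the sum of Euclidean steps between
#' consecutive pixel centres with per-axis calibrated deltas. Loops yield
#' branches whose two ends meet the same node; an isolated pixel is a
#' skeleton with one endpoint pixel and no branches.
#'
#' @param skel a [skeletonize_mask()] result (or a thin [binary_mask()]).
#' @return An object of class `skeleton_report`: `$skeletons` has one row
#'   per connected skeleton (counts and branch-length statistics),
#'   `$branches` one row per branch; `$n_skeletons` is the global count.
#' @export
analyze_skeleton <- function(skel) {
  stopifnot(inherits(skel, "binary_mask") || inherits(skel, "skeleton_image"))
  fg <- skel$data
  cal <- skel$calibration
  dm <- dim(fg)
  nd <- length(dm)
  if (any(fg & full_neighbourhood(fg)))
    stopf("input is not thin: a pixel has a fully-foreground neighbourhood")
  sk_lab <- label_components(mask_like(skel, fg))
  n_sk <- max(sk_lab)
  nbc <- neighbour_count(fg)
  cls <- array("", dm)
  cls[fg & nbc < 2L] <- "end"
  cls[fg & nbc == 2L] <- "slab"
  cls[fg & nbc > 2L] <- "junction"
  # merged junction nodes
  jn_lab <- label_components(mask_like(skel, fg & nbc > 2L))
  n_jn_total <- max(jn_lab)
  adj <- adjacency_lists(fg)
  step_len <- function(a, b) {
    d <- index_to_coord(a, dm)[1, ] - index_to_coord(b, dm)[1, ]
    sqrt(sum((d * cal)^2))
  }
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  branches <- list()
  add_branch <- function(sk, n1, n2, len) {
    branches[[length(branches) + 1L]] <<-
      data.frame(skeleton_id = sk, node_a = n1, node_b = n2, length = len)
  }
  node_id_of <- function(p) {
    if (cls[p] == "junction") paste0("J", jn_lab[p]) else paste0("E", p)
  }
  node_pixels <- which(fg & (nbc != 2L))
  for (np in node_pixels) {
    for (q in adj[[as.character(np)]]) {
      if (cls[np] == "junction" && cls[q] == "junction" &&
          jn_lab[np] == jn_lab[q]) next          # intra-node edge
      key <- edge_key(np, q)
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, envir = visited)
      len <- step_len(np, q)
      prev <- np; cur <- q
      while (cls[cur] == "slab") {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        if (length(nxt) != 1L) break   # defensive; slab has exactly 2 nbrs
        assign(edge_key(cur, nxt), TRUE, envir = visited)
        len <- len + step_len(cur, nxt)
        prev <- cur; cur <- nxt
      }
      add_branch(sk_lab[np], node_id_of(np), node_id_of(cur), len)
    }
  }
  # pure slab cycles (rings with no endpoint/junction pixel)
  slab_idx <- which(fg & nbc == 2L)
  for (s in slab_idx) {
    nbrs <- adj[[as.character(s)]]
    un <- nbrs[vapply(nbrs, function(q)
      is.null(visited[[edge_key(s, q)]]), TRUE)]
    if (length(un) < 2L) next   # touched by node traversal already
    start <- s
    prev <- start; cur <- un[1]
    assign(edge_key(start, cur), TRUE, envir = visited)
    len <- step_len(start, cur)
    while (cur != start) {
      nxt <- setdiff(adj[[as.character(cur)]], prev)[1]
      assign(edge_key(cur, nxt), TRUE, envir = visited)
      len <- len + step_len(cur, nxt)
      prev <- cur; cur <- nxt
    }
    add_branch(sk_lab[start], "cycle", "cycle", len)
  }
  br <- if (length(branches)) do.call(rbind, branches)
        else data.frame(skeleton_id = integer(0), node_a = character(0),
                        node_b = character(0), length = numeric(0))
  # per-skeleton accounting
  sk_rows <- lapply(seq_len(n_sk), function(sk) {
    in_sk <- sk_lab == sk
    b <- br[br$skeleton_id == sk, , drop = FALSE]
    ends_here <- c(b$node_a, b$node_b)
    jn_here <- unique(jn_lab[in_sk & jn_lab > 0L])
    incidence <- table(ends_here[startsWith(ends_here, "J")])
    data.frame(
      skeleton_id = sk,
      n_branches = nrow(b),
      n_junctions = length(jn_here),
      n_endpoint_voxels = sum(in_sk & cls == "end"),
      n_junction_voxels = sum(in_sk & cls == "junction"),
      n_slab_voxels = sum(in_sk & cls == "slab"),
      n_triple_points = sum(incidence == 3L),
      n_quadruple_points = sum(incidence == 4L),
      branch_length_max = if (nrow(b)) max(b$length) else 0,
      branch_length_mean = if (nrow(b)) mean(b$length) else 0,
      branch_length_sum = sum(b$length)
    )
  })
  skeletons <- if (n_sk) do.call(rbind, sk_rows) else data.frame()
  structure(list(skeletons = skeletons, branches = br, n_skeletons = n_sk),
            class = "skeleton_report")
}

#' @export
print.skeleton_report <- function(x, ...) {
  cat(sprintf("<skeleton_report> %d skeletons, %d branches, total length %g\n",
              x$n_skeletons, nrow(x$branches), sum(x$branches$length)))
  invisible(x)
}

# TRUE where a pixel's full 3x3(x3) neighbourhood is foreground.
full_neighbourhood <- function(fg) {
  dm <- dim(fg)
  nd <- length(dm)
  offs <- neighbour_offsets(nd)
  out <- array(TRUE, dm)
  for (k in seq_len(nrow(offs)))
    out <- out & (shift_logical(fg, offs[k, ]) == 1L)
  out
}

#' Count attachment points of a skeleton onto a body mask
#'
#' An attachment point is a distinct entry of the skeleton into the halo
#' of the body mask: the number of connected components of the skeleton
#' restricted to the dilated body, minus those components lying entirely
#' inside the undilated body.
#'
#' @param skel a skeleton (any [binary_mask()]).
#' @param body_mask the cell-body mask.
#' @param halo dilation radius in pixels applied to `body_mask`.
#' @return Integer count.
#' @export
count_attachment_points <- function(skel, body_mask, halo = 2) {
  stopifnot(inherits(skel, "binary_mask"), inherits(body_mask, "binary_mask"))
  if (!same_shape(skel$data, body_mask$data)) stopf("shapes differ")
  dil <- dilate_mask(body_mask, halo)
  inter <- skel$data & dil$data
  if (!any(inter)) return(0L)
  lab <- label_components(mask_like(skel, inter))
  n <- max(lab)
  fully_inside <- vapply(seq_len(n), function(o)
    all(body_mask$data[lab == o]), TRUE)
  sum(!fully_inside)
}
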