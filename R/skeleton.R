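# Skeletonization (Zhang-Suen thinning) and skeleton-graph extraction.
# No installed R package provides 2-D topological thinning, so it is
# implemented here, vectorized over whole-image neighbor shifts.

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning: alternating sub-iterations delete boundary
#' pixels that do not break 8-connectivity, until the mask is a one-pixel
#' medial network. Skeleton pixels are always a subset of mask pixels.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  .zs_thin(mask)
}

# connected-component labelling on a logical matrix via igraph
# (conn = 8 for foreground objects, 4 for holes)
label_components <- function(mask, conn = 8L) {
  n_fg <- sum(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (n_fg == 0L) return(labels)
  idx <- which(mask)
  ord <- matrix(0L, nrow(mask), ncol(mask))
  ord[idx] <- seq_along(idx)
  offs <- list(c(0, 1), c(1, 0))
  if (conn == 8L) offs <- c(offs, list(c(1, 1), c(1, -1)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    sh <- shift_mat(mask, o[1], o[2])
    both <- mask & sh
    if (!any(both)) next
    j <- which(both)
    # neighbor at offset -o from j
    nr <- nrow(mask)
    rj <- ((j - 1L) %% nr) + 1L
    cj <- ((j - 1L) %/% nr) + 1L
    k <- (cj - o[2] - 1L) * nr + (rj - o[1])
    from <- c(from, ord[j]); to <- c(to, ord[k])
  }
  if (length(from) == 0L) {
    labels[idx] <- seq_along(idx)
    return(labels)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_fg - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  labels[idx] <- as.integer(memb)
  labels
}

# Euler number (8-connected objects, 4-connected holes) via bit-quad counts
euler_number <- function(mask) {
  p <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(p); nc <- ncol(p)
  a <- p[-nr, -nc]; b <- p[-nr, -1]; c_ <- p[-1, -nc]; d <- p[-1, -1]
  s <- a + b + c_ + d
  n1 <- sum(s == 1L)
  n3 <- sum(s == 3L)
  nd <- sum(s == 2L & ((a & d & !b & !c_) | (b & c_ & !a & !d)))
  (n1 - n3 - 2L * nd) / 4
}

#' Extract the skeleton graph of a binary fiber mask
#'
#' Thins the mask to a one-pixel skeleton, then decomposes it into nodes
#' (skeleton pixels whose 8-connected degree differs from 2: endpoints and
#' branchpoints) and segments (maximal degree-2 paths between nodes, plus
#' closed loops). Per segment it records the ordered pixel path, geodesic
#' length (sum of 1 or sqrt(2) pixel steps, in um), end-to-end chord length
#' (um), mean half-width sampled from the Euclidean distance transform of
#' the mask along the path (um), and the axial orientation of the chord in
#' \[0, pi) measured from the +x axis.
#'
#' @param mask logical matrix (fiber mask).
#' @param pixel_size um per pixel.
#' @return object of class \code{"skeleton_graph"}: list with
#'   \code{skeleton} (logical matrix), \code{nodes} (data.frame: row, col,
#'   degree), \code{segments} (data.frame: geodesic_um, chord_um,
#'   halfwidth_um, orientation, n_px, node_a, node_b), \code{paths} (list of
#'   pixel-index matrices), \code{pixel_size}, \code{dim}.
#' @examples
#' m <- matrix(FALSE, 20, 40); m[9:11, 5:35] <- TRUE
#' g <- skeletonize_network(m, pixel_size = 0.5)
#' g$segments$geodesic_um
#' @export
skeletonize_network <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size > 0)
  skel <- thin_mask(mask)
  empty <- list(
    skeleton = skel,
    nodes = data.frame(row = integer(0), col = integer(0), degree = integer(0)),
    segments = data.frame(geodesic_um = numeric(0), chord_um = numeric(0),
                          halfwidth_um = numeric(0), orientation = numeric(0),
                          n_px = integer(0), node_a = integer(0), node_b = integer(0)),
    paths = list(), pixel_size = pixel_size, dim = dim(mask)
  )
  if (!any(skel)) return(structure(empty, class = "skeleton_graph"))

  idx <- which(skel)
  n <- length(idx)
  nr <- nrow(skel)
  ord <- matrix(0L, nr, ncol(skel))
  ord[idx] <- seq_len(n)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L

  # adjacency lists over the 8-neighborhood; redundant diagonal edges
  # (those with an orthogonal elbow pixel also on the skeleton) are dropped,
  # otherwise every staircase corner reads as a spurious junction
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    sh <- shift_mat(skel, o[1], o[2])
    both <- skel & sh
    if (o[1] != 0L && o[2] != 0L) {
      elbow <- (skel & shift_mat(skel, o[1], 0L)) | (skel & shift_mat(skel, 0L, o[2]))
      both <- both & !elbow
    }
    if (!any(both)) next
    j <- which(both)
    rj <- ((j - 1L) %% nr) + 1L
    cj <- ((j - 1L) %/% nr) + 1L
    k <- (cj - o[2] - 1L) * nr + (rj - o[1])
    from <- c(from, ord[j]); to <- c(to, ord[k])
  }
  adj <- vector("list", n)
  if (length(from)) {
    sp <- split(to, factor(from, levels = seq_len(n)))
    adj <- lapply(sp, as.integer)
  }
  degree <- lengths(adj)
  is_node <- degree != 2L

  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))

  used <- lapply(adj, function(a) rep(FALSE, length(a)))
  mark_used <- function(a, b) {
    i <- match(b, adj[[a]])
    u <- used[[a]]; u[i] <- TRUE
    used[[a]][i] <<- TRUE
    j <- match(a, adj[[b]])
    used[[b]][j] <<- TRUE
  }
  paths <- list()
  seg_ab <- list()

  walk <- function(start, nxt) {
    path <- c(start, nxt)
    mark_used(start, nxt)
    prev <- start; cur <- nxt
    while (!is_node[cur]) {
      nbrs <- adj[[cur]]
      nx <- nbrs[nbrs != prev][1]
      if (is.na(nx)) break  # degenerate: dead end on a degree-2 pixel
      mark_used(cur, nx)
      path <- c(path, nx)
      prev <- cur; cur <- nx
      if (cur == start) break  # closed loop back to origin
    }
    path
  }

  for (v in which(is_node)) {
    for (b in adj[[v]]) {
      i <- match(b, adj[[v]])
      if (used[[v]][i]) next
      p <- walk(v, b)
      paths[[length(paths) + 1L]] <- p
      seg_ab[[length(seg_ab) + 1L]] <- c(p[1], p[length(p)])
    }
  }
  # pure cycles: remaining unused edges among degree-2 pixels
  for (v in seq_len(n)) {
    for (i in seq_along(adj[[v]])) {
      if (used[[v]][i]) next
      p <- walk(v, adj[[v]][i])
      paths[[length(paths) + 1L]] <- p
      seg_ab[[length(seg_ab) + 1L]] <- c(p[1], p[length(p)])
    }
  }

  seg_stats <- lapply(paths, function(p) {
    r <- rows[p]; c_ <- cols[p]
    # stride-3 chord sum: cuts digital staircase corners, so straight
    # strokes at any angle measure their true length (still >= the chord)
    i3 <- unique(c(seq.int(1L, length(p), by = 3L), length(p)))
    steps <- sqrt(diff(r[i3])^2 + diff(c_[i3])^2)
    geo <- sum(steps) * pixel_size
    dx <- c_[length(c_)] - c_[1]
    dy <- r[length(r)] - r[1]
    chord <- sqrt(dx^2 + dy^2) * pixel_size
    orient <- if (chord > 0) atan2(dy, dx) %% pi else 0
    hw <- mean(dist[cbind(r, c_)]) * pixel_size
    c(geo, chord, hw, orient, length(p))
  })
  ss <- do.call(rbind, seg_stats)
  segments <- data.frame(
    geodesic_um = ss[, 1], chord_um = ss[, 2], halfwidth_um = ss[, 3],
    orientation = ss[, 4], n_px = as.integer(ss[, 5]),
    node_a = vapply(seg_ab, `[`, numeric(1), 1),
    node_b = vapply(seg_ab, `[`, numeric(1), 2)
  )
  nodes <- data.frame(row = rows[is_node], col = cols[is_node],
                      degree = degree[is_node])
  structure(list(skeleton = skel, nodes = nodes, segments = segments,
                 paths = lapply(paths, function(p) cbind(row = rows[p], col = cols[p])),
                 pixel_size = pixel_size, dim = dim(mask)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("Skeleton graph: ", sum(x$skeleton), " px, ", nrow(x$nodes),
      " nodes (", sum(x$nodes$degree >= 3L), " junction px), ",
      nrow(x$segments), " segments\n", sep = "")
  invisible(x)
}

# number of branchpoints after merging junction pixels closer than merge_px
# (thinning splits an X-crossing into nearby T-junctions nondeterministically)
count_branchpoints <- function(graph, merge_px = 2) {
  j <- graph$nodes[graph$nodes$degree >= 3L, , drop = FALSE]
  nj <- nrow(j)
  if (nj == 0L) return(0L)
  if (nj == 1L) return(1L)
  d <- as.matrix(stats::dist(j[, c("row", "col")]))
  close <- d <= merge_px
  g <- igraph::graph_from_adjacency_matrix(close, mode = "undirected", diag = FALSE)
  igraph::components(g)$no
}
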