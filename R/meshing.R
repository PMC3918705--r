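#' Triangulate the LV domain bounded by a contour
#'
#' Conforming triangulation of the region enclosed by a closed contour.
#' The boundary is resampled to edge length `target_edge`, interior nodes
#' are laid on a hexagonal lattice of the same spacing (kept clear of the
#' boundary), the point set is Delaunay-triangulated, triangles outside the
#' polygon are discarded and interior nodes are Laplacian-smoothed to
#' improve element quality.  All elements are oriented anticlockwise.
#'
#' @param boundary an [contour()] object (simple, closed).
#' @param target_edge target element edge length in pixels; default
#'   `perimeter/64`.
#' @param smooth_iters Laplacian smoothing sweeps over interior nodes
#'   (default 2).
#' @return an object of class `lv_mesh`: `nodes` (n x 2), `elements`
#'   (m x 3 node indices, anticlockwise), `n_boundary` (the first
#'   `n_boundary` nodes are the boundary ring, in anticlockwise order).
#'   Boundary faces / SURFACE are filled in by [find_boundary()] and
#'   [assemble_surface()].
#' @export
triangulate_region <- function(boundary, target_edge = NULL, smooth_iters = 2) {
  stopifnot(inherits(boundary, "lv_contour"))
  per <- perimeter(boundary)
  if (is.null(target_edge)) target_edge <- per / 64
  if (target_edge <= 0) stop("target_edge must be positive")
  n_b <- max(4L, as.integer(round(per / target_edge)))
  bpts <- resample_closed(boundary, n_b)$points
  h <- per / n_b

  ipts <- hex_interior_points(bpts, h, margin = 0.7 * h)
  nodes <- rbind(bpts, ipts)
  mesh <- delaunay_in_polygon(nodes, bpts)

  if (smooth_iters > 0 && nrow(nodes) > n_b) {
    for (it in seq_len(smooth_iters)) {
      nodes <- smooth_interior(mesh$nodes, mesh$elements, n_b)
      mesh <- delaunay_in_polygon(nodes, bpts)
    }
  }

  # conformity: every consecutive boundary pair must be a mesh edge
  if (!boundary_conforming(mesh$elements, n_b)) {
    ipts <- hex_interior_points(bpts, h, margin = 0.95 * h)
    nodes <- rbind(bpts, ipts)
    mesh <- delaunay_in_polygon(nodes, bpts)
    if (!boundary_conforming(mesh$elements, n_b)) {
      stop("triangulation does not conform to the boundary; ",
           "reduce target_edge")
    }
  }
  structure(list(nodes = mesh$nodes, elements = mesh$elements,
                 n_boundary = n_b),
            class = "lv_mesh")
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("lv_mesh: %d nodes, %d elements, %d boundary nodes\n",
              nrow(x$nodes), nrow(x$elements), x$n_boundary))
  if (!is.null(x$surface_faces)) {
    cat(sprintf("  SURFACE: %d faces; basal nodes: %d\n",
                nrow(x$surface_faces), length(x$basal_nodes)))
  }
  invisible(x)
}

hex_interior_points <- function(bpts, h, margin) {
  xr <- range(bpts[, 1]); yr <- range(bpts[, 2])
  dy <- h * sqrt(3) / 2
  ys <- seq(yr[1] + dy / 2, yr[2], by = dy)
  if (!length(ys)) return(matrix(numeric(0), 0, 2))
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) h / 2 else 0
    xs <- seq(xr[1] + off, xr[2], by = h)
    if (!length(xs)) return(NULL)
    cbind(xs, ys[i])
  }))
  if (is.null(pts) || !nrow(pts)) return(matrix(numeric(0), 0, 2))
  inside <- sp::point.in.polygon(pts[, 1], pts[, 2],
                                 bpts[, 1], bpts[, 2]) == 1
  pts <- pts[inside, , drop = FALSE]
  if (!nrow(pts)) return(pts)
  d <- dist_to_polyline(pts, bpts)
  pts[d >= margin, , drop = FALSE]
}

# minimum distance from each point to the closed polyline through pts
dist_to_polyline <- function(p, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[nxt, 1]; by <- poly[nxt, 2]
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2
  m <- nrow(p)
  PX <- matrix(p[, 1], m, n)
  PY <- matrix(p[, 2], m, n)
  AX <- matrix(ax, m, n, byrow = TRUE)
  AY <- matrix(ay, m, n, byrow = TRUE)
  EX <- matrix(ex, m, n, byrow = TRUE)
  EY <- matrix(ey, m, n, byrow = TRUE)
  EL2 <- matrix(el2, m, n, byrow = TRUE)
  t <- pmin(1, pmax(0, ((PX - AX) * EX + (PY - AY) * EY) / EL2))
  dx <- PX - (AX + t * EX)
  dy <- PY - (AY + t * EY)
  sqrt(apply(dx^2 + dy^2, 1, min))
}

delaunay_in_polygon <- function(nodes, bpts) {
  dd <- deldir::deldir(nodes[, 1], nodes[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tri <- t(vapply(tl, function(tr) tr$ptNum, integer(3)))
  # orient anticlockwise
  a <- tri_signed_areas(nodes, tri)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  # keep triangles whose centroid is inside the polygon
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  keep <- sp::point.in.polygon(cx, cy, bpts[, 1], bpts[, 2]) == 1
  tri <- tri[keep, , drop = FALSE]
  # drop nodes that ended up unused (should not happen with hex margin)
  used <- sort(unique(as.vector(tri)))
  if (length(used) < nrow(nodes)) {
    remap <- integer(nrow(nodes))
    remap[used] <- seq_along(used)
    tri <- matrix(remap[tri], ncol = 3)
    nodes <- nodes[used, , drop = FALSE]
  }
  list(nodes = nodes, elements = tri)
}

tri_signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

smooth_interior <- function(nodes, tri, n_b) {
  n <- nrow(nodes)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  sx <- rowsum(nodes[edges[, 2], 1], edges[, 1])
  sy <- rowsum(nodes[edges[, 2], 2], edges[, 1])
  cnt <- rowsum(rep(1, nrow(edges)), edges[, 1])
  ids <- as.integer(rownames(sx))
  new <- nodes
  new[ids, 1] <- sx[, 1] / cnt[, 1]
  new[ids, 2] <- sy[, 1] / cnt[, 1]
  new[seq_len(n_b), ] <- nodes[seq_len(n_b), ]   # boundary ring fixed
  new
}

boundary_conforming <- function(tri, n_b) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]),
          key(tri[, 3], tri[, 1]))
  want <- key(seq_len(n_b), c(2:n_b, 1))
  all(want %in% ek)
}

#' Identify boundary nodes and element faces of a mesh
#'
#' An edge is a boundary edge iff it belongs to exactly one element.  Faces
#' follow the anticlockwise convention: face f of an element connects local
#' nodes f and `f %% 3 + 1` (face 1: nodes 1-2, face 2: nodes 2-3,
#' face 3: nodes 3-1).
#'
#' @param mesh an `lv_mesh`.
#' @return list with `boundary_nodes` (sorted node indices) and
#'   `boundary_faces` (data frame: `element`, `face`, `from`, `to`, with
#'   `from -> to` the anticlockwise direction of the edge).
#' @export
find_boundary <- function(mesh) {
  tri <- mesh$elements
  m <- nrow(tri)
  from <- c(tri[, 1], tri[, 2], tri[, 3])
  to <- c(tri[, 2], tri[, 3], tri[, 1])
  elem <- rep(seq_len(m), 3)
  face <- rep(1:3, each = m)
  key <- paste(pmin(from, to), pmax(from, to))
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold mesh: an edge belongs to >2 elements")
  isb <- cnt[key] == 1
  bf <- data.frame(element = elem[isb], face = face[isb],
                   from = from[isb], to = to[isb])
  list(boundary_nodes = sort(unique(c(bf$from, bf$to))),
       boundary_faces = bf)
}

#' Assemble the endocardial SURFACE and the basal node set
#'
#' Orders the boundary faces into a single closed anticlockwise chain,
#' marks the `basal_fraction` of the chain (by arc length) nearest the
#' topmost boundary point (minimum y: the basal/valve end under the
#' apex-down convention) as the basal segment, and takes the remaining
#' chain as the pressure SURFACE.  Basal nodes are held fixed by the
#' solver to suppress rigid-body motion.
#'
#' @param mesh an `lv_mesh`.
#' @param basal_fraction fraction of the boundary chain assigned to the
#'   basal segment (default 0.1); 0 gives an all-SURFACE boundary.
#' @return the mesh with `boundary_faces`, `chain` (anticlockwise node
#'   order), `surface_faces`, `basal_nodes` filled in.
#' @export
assemble_surface <- function(mesh, basal_fraction = 0.1) {
  stopifnot(inherits(mesh, "lv_mesh"))
  fb <- find_boundary(mesh)
  bf <- fb$boundary_faces
  # order directed edges into a chain
  nb <- nrow(bf)
  succ <- integer(0)
  succ[bf$from] <- seq_len(nb)
  chain_edges <- integer(nb)
  e <- 1L
  for (i in seq_len(nb)) {
    chain_edges[i] <- e
    nxt_node <- bf$to[e]
    e <- succ[nxt_node]
    if (is.na(e) || e == 0L) {
      if (i < nb) stop("disconnected boundary chain")
      e <- chain_edges[1]
    }
  }
  if (length(unique(chain_edges)) != nb) stop("disconnected boundary chain")
  bf <- bf[chain_edges, ]
  chain <- bf$from

  if (basal_fraction <= 0) {
    basal <- integer(0)
    surf <- bf
  } else {
    pts <- mesh$nodes[chain, , drop = FALSE]
    n <- nrow(pts)
    seg <- sqrt(rowSums((mesh$nodes[bf$to, , drop = FALSE] - pts)^2))
    L <- sum(seg)
    # arc-length positions of chain nodes, centred on the min-y node
    s <- c(0, cumsum(seg))[seq_len(n)]
    i_top <- which.min(pts[, 2])
    half <- basal_fraction * L / 2
    ds <- (s - s[i_top]) %% L
    ds <- pmin(ds, L - ds)                       # cyclic distance
    node_in <- ds <= half + 1e-9
    # an edge is basal iff both endpoints are in the basal window
    idx_to <- c(2:n, 1)
    edge_basal <- node_in & node_in[idx_to]
    basal <- sort(unique(c(chain[edge_basal], chain[idx_to][edge_basal])))
    surf <- bf[!edge_basal, ]
  }
  mesh$boundary_faces <- bf
  mesh$chain <- chain
  mesh$surface_faces <- surf
  mesh$basal_nodes <- basal
  mesh
}

#' Minimum interior angle of a mesh (degrees)
#' @param mesh an `lv_mesh`.
#' @return smallest angle over all elements, in degrees.
#' @export
mesh_min_angle <- function(mesh) {
  tri <- mesh$elements
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    acos(pmin(1, pmax(-1, rowSums(u * v) /
                        sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  min(c(ang(p1, p2, p3), ang(p2, p3, p1), ang(p3, p1, p2))) * 180 / pi
}

#' Read / write meshes in a plain text format
#'
#' One `node id x y` line per node, then one `element id n1 n2 n3` line per
#' element, prefixed by a `nodes <n>` / `elements <m>` count header.
#'
#' @param mesh an `lv_mesh`.
#' @param path file path.
#' @return `read_mesh()` returns an `lv_mesh`; `write_mesh()` the path,
#'   invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("nodes %d", nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.10g %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("elements %d", nrow(mesh$elements)), con)
  writeLines(sprintf("%d %d %d %d", seq_len(nrow(mesh$elements)),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  nn <- as.integer(strsplit(lines[1], " ")[[1]][2])
  nd <- do.call(rbind, lapply(lines[2:(1 + nn)], function(l)
    as.numeric(strsplit(l, " ")[[1]][2:3])))
  ne <- as.integer(strsplit(lines[2 + nn], " ")[[1]][2])
  el <- do.call(rbind, lapply(lines[(3 + nn):(2 + nn + ne)], function(l)
    as.integer(strsplit(l, " ")[[1]][2:4])))
  structure(list(nodes = nd, elements = el, n_boundary = NA_integer_),
            class = "lv_mesh")
}

#' Export a mesh in an ABAQUS-style .inp dialect (write-only)
#'
#' Emits `*NODE` (id, x, y), `*ELEMENT, TYPE=CPS3` (id, n1, n2, n3) and,
#' when the SURFACE has been assembled, `*SURFACE` cards listing
#' `element, Sf` face identifiers.  Intended for interoperability with
#' solvers that read this dialect; lvtrack never reads it back.
#'
#' @param mesh an `lv_mesh` (ideally after [assemble_surface()]).
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_abaqus_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines("*ELEMENT, TYPE=CPS3", con)
  writeLines(sprintf("%d, %d, %d, %d", seq_len(nrow(mesh$elements)),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3]), con)
  if (!is.null(mesh$surface_faces)) {
    writeLines("*SURFACE, NAME=ENDO, TYPE=ELEMENT", con)
    writeLines(sprintf("%d, S%d", mesh$surface_faces$element,
                       mesh$surface_faces$face), con)
  }
  invisible(path)
}
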