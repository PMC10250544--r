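# Convex-polyhedron geometry in 2-D/3-D used by the volume-based niche
# overlap. Pure R incremental hull; adequate for occurrence-scale point
# clouds (hundreds to a few thousand points).

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

face_plane <- function(P, f) {
  a <- P[f[1], ]; b <- P[f[2], ]; c <- P[f[3], ]
  n <- cross3(b - a, c - a)
  len <- sqrt(sum(n^2))
  if (len == 0) return(NULL)
  n <- n / len
  list(normal = n, offset = sum(n * a))
}

# Incremental 3-D convex hull. Returns triangular faces (outward-oriented
# vertex triples), unit outward normals, offsets, hull vertices, volume.
hull3d <- function(P, tol = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 4) stop("need at least 4 points in 3-D", call. = FALSE)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (!is.finite(scale) || scale == 0) {
    stop("degenerate point set: all points coincide", call. = FALSE)
  }
  if (is.null(tol)) tol <- 1e-9 * scale

  # initial simplex from extreme points
  i1 <- which.min(P[, 1])
  d1 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d1)
  ab <- P[i2, ] - P[i1, ]
  cr <- t(apply(sweep(P, 2, P[i1, ]), 1, function(v) cross3(ab, v)))
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (sqrt(d2[i3]) <= tol * sqrt(sum(ab^2))) {
    stop("degenerate point set: points are collinear", call. = FALSE)
  }
  pl <- face_plane(P, c(i1, i2, i3))
  d3 <- abs(as.vector(P %*% pl$normal) - pl$offset)
  i4 <- which.max(d3)
  if (d3[i4] <= tol) {
    stop("degenerate point set: points are coplanar", call. = FALSE)
  }
  c0 <- colMeans(P[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    p <- face_plane(P, f)
    if (sum(p$normal * c0) > p$offset) f[c(1, 3, 2)] else f
  }
  faces <- list(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))
  planes <- lapply(faces, function(f) face_plane(P, f))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (pi in rest) {
    p <- P[pi, ]
    vis <- vapply(planes, function(pl) sum(pl$normal * p) - pl$offset > tol,
                  logical(1))
    if (!any(vis)) next
    vis_faces <- faces[vis]
    # directed edges of visible faces; horizon = edges whose reverse is
    # not among them
    edges <- do.call(rbind, lapply(vis_faces, function(f) {
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(keys %in% rev_keys), , drop = FALSE]
    faces <- faces[!vis]
    planes <- planes[!vis]
    for (h in seq_len(nrow(horizon))) {
      f <- c(horizon[h, 1], horizon[h, 2], pi)
      pl <- face_plane(P, f)
      if (is.null(pl)) next
      if (sum(pl$normal * c0) > pl$offset + tol) {
        f <- f[c(1, 3, 2)]
        pl <- face_plane(P, f)
      }
      faces <- c(faces, list(f))
      planes <- c(planes, list(pl))
    }
  }
  fm <- do.call(rbind, faces)
  vol <- sum(vapply(faces, function(f) {
    det(rbind(P[f[1], ] - c0, P[f[2], ] - c0, P[f[3], ] - c0))
  }, numeric(1))) / 6
  normals <- do.call(rbind, lapply(planes, `[[`, "normal"))
  offsets <- vapply(planes, `[[`, numeric(1), "offset")
  list(faces = fm, normals = normals, offsets = offsets,
       vertices = sort(unique(as.vector(fm))), volume = abs(vol),
       tol = tol, interior = c0)
}

# distinct supporting planes (triangulated faces of one facet merged)
distinct_planes <- function(normals, offsets, digits = 7) {
  key <- apply(cbind(round(normals, digits), round(offsets, digits)), 1,
               paste, collapse = "|")
  keep <- !duplicated(key)
  list(normals = normals[keep, , drop = FALSE], offsets = offsets[keep])
}

in_halfspaces <- function(pts, normals, offsets, tol = 1e-9) {
  ex <- pts %*% t(normals)
  rowSums(ex > rep(offsets + tol, each = nrow(ex))) == 0
}

# 2-D convex hull: vertices counterclockwise, area, edge half-planes
hull2d <- function(P, tol = NULL) {
  P <- as.matrix(P)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (is.null(tol)) tol <- 1e-9 * max(scale, 1e-12)
  idx <- rev(grDevices::chull(P)) # chull is clockwise; reverse to ccw
  V <- P[idx, , drop = FALSE]
  if (nrow(V) < 3) stop("degenerate point set: points are collinear",
                        call. = FALSE)
  x <- V[, 1]; y <- V[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area <= tol^2) stop("degenerate point set: zero area", call. = FALSE)
  m <- nrow(V)
  normals <- t(vapply(seq_len(m), function(i) {
    a <- V[i, ]; b <- V[if (i == m) 1 else i + 1, ]
    e <- b - a
    nrm <- c(e[2], -e[1]) # outward for ccw polygon
    nrm / sqrt(sum(nrm^2))
  }, numeric(2)))
  offsets <- rowSums(normals * V)
  list(vertices_idx = idx, vertices = V, volume = area,
       normals = normals, offsets = offsets, tol = tol,
       interior = colMeans(V))
}

# Sutherland-Hodgman clip of convex polygon `subject` (ccw vertex matrix)
# by convex polygon `clip`
clip_convex_polygon <- function(subject, clip_normals, clip_offsets) {
  out <- subject
  for (i in seq_along(clip_offsets)) {
    if (nrow(out) == 0) return(out)
    n <- clip_normals[i, ]; off <- clip_offsets[i]
    inside <- as.vector(out %*% n) <= off + 1e-12
    new <- matrix(numeric(0), 0, 2)
    m <- nrow(out)
    for (j in seq_len(m)) {
      a <- out[j, ]; b <- out[if (j == m) 1 else j + 1, ]
      ia <- inside[j]; ib <- inside[if (j == m) 1 else j + 1]
      if (ia) new <- rbind(new, a)
      if (xor(ia, ib)) {
        da <- sum(n * a) - off; db <- sum(n * b) - off
        t <- da / (da - db)
        new <- rbind(new, a + t * (b - a))
      }
    }
    out <- new
  }
  out
}

poly_area <- function(V) {
  if (is.null(nrow(V)) || nrow(V) < 3) return(0)
  x <- V[, 1]; y <- V[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Exact intersection volume of two 3-D convex bodies given as half-space
# systems: vertex enumeration over plane triples, then a pyramid
# decomposition over the face polygons (robust to the many exactly
# coplanar vertices a polytope's faces carry).
halfspace_intersection_volume <- function(normals, offsets, tol = 1e-8) {
  pl <- distinct_planes(normals, offsets)
  normals <- pl$normals
  offsets <- pl$offsets
  m <- nrow(normals)
  combs <- utils::combn(m, 3)
  pts <- matrix(numeric(0), 0, 3)
  for (c_i in seq_len(ncol(combs))) {
    tri <- combs[, c_i]
    A <- normals[tri, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    p <- tryCatch(solve(A, offsets[tri]), error = function(e) NULL)
    if (is.null(p)) next
    if (all(normals %*% p - offsets <= tol)) pts <- rbind(pts, p)
  }
  if (nrow(pts) < 4) return(0)
  ctr <- colMeans(pts)
  eps <- max(tol, 1e-9 * max(abs(pts)))
  vol <- 0
  for (i in seq_len(m)) {
    height <- offsets[i] - sum(normals[i, ] * ctr)
    if (height <= eps) next # centre on (or outside) the plane: flat body
    on_face <- abs(pts %*% normals[i, ] - offsets[i]) <= 10 * eps
    face <- pts[on_face, , drop = FALSE]
    if (nrow(face) < 3) next
    # orthonormal in-plane basis for a 2-D hull of the face polygon
    n <- normals[i, ]
    u <- if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0))
    u <- u / sqrt(sum(u^2))
    v <- cross3(n, u)
    p2 <- cbind(face %*% u, face %*% v)
    idx <- tryCatch(grDevices::chull(p2), error = function(e) NULL)
    if (length(idx) < 3) next
    vol <- vol + poly_area(p2[idx, , drop = FALSE]) * height / 3
  }
  vol
}
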