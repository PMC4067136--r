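# Conforming meshes: 1D intervals and 2D triangulations (unit squares,
# squares with circular holes), quality metrics and mesh file I/O.
#
# Coordinates are in cm throughout. Triangles are stored counter-clockwise;
# edges are identified by their sorted vertex pair and carry a global
# orientation (low vertex index -> high vertex index).

new_mesh_1d <- function(vertices, elements) {
  structure(list(dimension = 1L,
                 vertices = matrix(vertices, ncol = 1L),
                 elements = elements,
                 n_vertices = length(vertices),
                 n_elements = nrow(elements)),
            class = "hp_mesh")
}

new_mesh_2d <- function(vertices, elements, holes = NULL, side = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  elements <- matrix(as.integer(as.matrix(elements)), nrow = NROW(elements))
  elements <- orient_ccw(vertices, elements)
  ed <- edge_table(elements)
  m <- structure(list(dimension = 2L,
                      vertices = vertices,
                      elements = elements,
                      edges = ed$edges,
                      elem_edges = ed$elem_edges,
                      elem_flip = ed$elem_flip,
                      edge_elem_count = ed$count,
                      n_vertices = nrow(vertices),
                      n_elements = nrow(elements),
                      n_edges = nrow(ed$edges),
                      holes = holes,
                      side = side),
                 class = "hp_mesh")
  m$edge_tags <- tag_boundary_edges(m)
  m
}

orient_ccw <- function(vertices, elements) {
  a <- signed_areas(vertices, elements)
  flip <- which(a < 0)
  if (length(flip)) {
    tmp <- elements[flip, 2L]
    elements[flip, 2L] <- elements[flip, 3L]
    elements[flip, 3L] <- tmp
  }
  a <- signed_areas(vertices, elements)
  bad <- which(a <= 0)
  if (length(bad)) stop(sprintf("degenerate element (zero area): index %d", bad[1L]))
  elements
}

signed_areas <- function(vertices, elements) {
  p1 <- vertices[elements[, 1L], , drop = FALSE]
  p2 <- vertices[elements[, 2L], , drop = FALSE]
  p3 <- vertices[elements[, 3L], , drop = FALSE]
  0.5 * ((p2[, 1L] - p1[, 1L]) * (p3[, 2L] - p1[, 2L]) -
           (p3[, 1L] - p1[, 1L]) * (p2[, 2L] - p1[, 2L]))
}

# Global edge table; per-element local edges (1,2), (2,3), (3,1) with a flag
# marking elements whose local edge runs against the global orientation.
edge_table <- function(elements) {
  nt <- nrow(elements)
  le <- local_edges()
  a <- c(elements[, le[1L, 1L]], elements[, le[2L, 1L]], elements[, le[3L, 1L]])
  b <- c(elements[, le[1L, 2L]], elements[, le[2L, 2L]], elements[, le[3L, 2L]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- as.numeric(lo) * (max(hi) + 1) + hi
  uk <- !duplicated(key)
  edges <- cbind(lo[uk], hi[uk])
  eid <- match(key, key[uk])
  elem_edges <- matrix(eid, nt, 3L)
  elem_flip <- matrix(a > b, nt, 3L)
  count <- tabulate(eid, nbins = nrow(edges))
  if (any(count > 2L)) stop("non-conforming mesh: an edge borders more than 2 elements")
  list(edges = edges, elem_edges = elem_edges, elem_flip = elem_flip, count = count)
}

# Boundary tags: 0 interior; squares get 1 = bottom, 2 = right, 3 = top,
# 4 = left; hole k gets tag 4 + k. Non-square geometries get tag 1.
tag_boundary_edges <- function(mesh, tol = 1e-8) {
  tags <- integer(mesh$n_edges)
  bnd <- which(mesh$edge_elem_count == 1L)
  if (!length(bnd)) return(tags)
  v <- mesh$vertices
  mid <- (v[mesh$edges[bnd, 1L], , drop = FALSE] + v[mesh$edges[bnd, 2L], , drop = FALSE]) / 2
  tags[bnd] <- 1L
  if (!is.null(mesh$side)) {
    s <- mesh$side
    tags[bnd[abs(mid[, 2L]) < tol]] <- 1L
    tags[bnd[abs(mid[, 1L] - s) < tol]] <- 2L
    tags[bnd[abs(mid[, 2L] - s) < tol]] <- 3L
    tags[bnd[abs(mid[, 1L]) < tol]] <- 4L
  }
  if (!is.null(mesh$holes)) {
    for (k in seq_along(mesh$holes)) {
      h <- mesh$holes[[k]]
      d1 <- sqrt((v[mesh$edges[bnd, 1L], 1L] - h$center[1L])^2 +
                   (v[mesh$edges[bnd, 1L], 2L] - h$center[2L])^2)
      d2 <- sqrt((v[mesh$edges[bnd, 2L], 1L] - h$center[1L])^2 +
                   (v[mesh$edges[bnd, 2L], 2L] - h$center[2L])^2)
      on_hole <- abs(d1 - h$radius) < 1e-7 & abs(d2 - h$radius) < 1e-7
      tags[bnd[on_hole]] <- 4L + k
    }
  }
  tags
}

#' @export
print.hp_mesh <- function(x, ...) {
  if (x$dimension == 1L) {
    cat(sprintf("1D mesh: %d vertices, %d elements, length %.4g cm\n",
                x$n_vertices, x$n_elements, diff(range(x$vertices))))
  } else {
    cat(sprintf("2D triangular mesh: %d vertices, %d edges, %d elements\n",
                x$n_vertices, x$n_edges, x$n_elements))
    if (!is.null(x$holes)) cat(sprintf("  %d hole(s)\n", length(x$holes)))
    cat(sprintf("  mean element diameter %.4g cm\n", mean_element_diameter(x)))
  }
  invisible(x)
}

#' Uniform 1D interval mesh
#'
#' @param length domain length in cm.
#' @param h target element size in cm.
#' @return an `hp_mesh` with `round(length/h)` uniform segments.
#' @export
build_interval_mesh <- function(length, h) {
  if (length <= 0 || h <= 0 || h > length) stop("non-positive or inconsistent arguments")
  n <- max(1L, round(length / h))
  vertices <- seq(0, length, length.out = n + 1L)
  elements <- cbind(seq_len(n), seq_len(n) + 1L)
  new_mesh_1d(vertices, elements)
}

# ---------------------------------------------------------------------------
# Bowyer-Watson Delaunay triangulation (pure R, vectorised in-circle tests)

circumcircle <- function(p1, p2, p3) {
  ax <- p1[, 1L]; ay <- p1[, 2L]
  bx <- p2[, 1L]; by <- p2[, 2L]
  cx <- p3[, 1L]; cy <- p3[, 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  cbind(ux, uy, r2)
}

delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  # shuffled insertion order (deterministic: derived from the point set)
  ord <- order(sin(seq_len(n) * 12.9898) * 43758.5453 %% 1)
  inv <- integer(n); inv[ord] <- seq_len(n)
  pts_s <- pts[ord, , drop = FALSE]
  ctr <- colMeans(pts)
  rad <- max(sqrt((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2)) * 4 + 1
  P <- rbind(pts_s,
             ctr + c(0, 2 * rad),
             ctr + c(-1.8 * rad, -rad),
             ctr + c(1.8 * rad, -rad))
  cap <- 12L * n + 64L
  tri <- matrix(0L, cap, 3L)
  ccx <- numeric(cap); ccy <- numeric(cap); r2 <- numeric(cap)
  active <- logical(cap)
  tri[1L, ] <- c(n + 1L, n + 2L, n + 3L)
  cc <- circumcircle(P[n + 1L, , drop = FALSE], P[n + 2L, , drop = FALSE],
                     P[n + 3L, , drop = FALSE])
  ccx[1L] <- cc[1L]; ccy[1L] <- cc[2L]; r2[1L] <- cc[3L]
  active[1L] <- TRUE
  ntri <- 1L
  for (i in seq_len(n)) {
    px <- P[i, 1L]; py <- P[i, 2L]
    idx <- which(active[seq_len(ntri)])
    dx <- ccx[idx] - px; dy <- ccy[idx] - py
    bad <- idx[dx * dx + dy * dy <= r2[idx] * (1 + 1e-12)]
    # cavity boundary: directed edges of bad triangles appearing once
    bt <- tri[bad, , drop = FALSE]
    ea <- c(bt[, 1L], bt[, 2L], bt[, 3L])
    eb <- c(bt[, 2L], bt[, 3L], bt[, 1L])
    key <- pmin(ea, eb) * (n + 4) + pmax(ea, eb)
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    ca <- ea[once]; cb <- eb[once]
    active[bad] <- FALSE
    m <- length(ca)
    if (ntri + m > cap) {
      grow <- cap
      tri <- rbind(tri, matrix(0L, grow, 3L))
      ccx <- c(ccx, numeric(grow)); ccy <- c(ccy, numeric(grow))
      r2 <- c(r2, numeric(grow)); active <- c(active, logical(grow))
      cap <- cap + grow
    }
    new_idx <- ntri + seq_len(m)
    tri[new_idx, ] <- cbind(ca, cb, rep.int(i, m))
    cc <- circumcircle(P[ca, , drop = FALSE], P[cb, , drop = FALSE],
                       P[rep.int(i, m), , drop = FALSE])
    ccx[new_idx] <- cc[, 1L]; ccy[new_idx] <- cc[, 2L]; r2[new_idx] <- cc[, 3L]
    active[new_idx] <- TRUE
    ntri <- ntri + m
  }
  keep <- which(active[seq_len(ntri)])
  tt <- tri[keep, , drop = FALSE]
  tt <- tt[tt[, 1L] <= n & tt[, 2L] <= n & tt[, 3L] <= n, , drop = FALSE]
  # undo the insertion shuffle
  tt[] <- ord[tt]
  tt
}

square_boundary_points <- function(side, s) {
  nb <- max(2L, round(side / s))
  t <- seq(0, side, length.out = nb + 1L)
  ti <- t[-c(1L, nb + 1L)]
  rbind(cbind(t, 0), cbind(side, ti), cbind(rev(t), side), cbind(0, rev(ti)))
}

# deduplicate coincident points (corners appear twice in the boundary loop)
dedup_points <- function(pts, tol = 1e-12) {
  key <- paste(round(pts[, 1L] / tol), round(pts[, 2L] / tol))
  pts[!duplicated(key), , drop = FALSE]
}

hex_lattice <- function(side, s, margin) {
  dy <- s * sqrt(3) / 2
  ys <- seq(dy, side - margin / 2, by = dy)
  out <- vector("list", length(ys))
  for (j in seq_along(ys)) {
    off <- if (j %% 2L == 0L) s / 2 else 0
    xs <- seq(off + s / 2, side - s / 4, by = s)
    keep <- xs >= margin & xs <= side - margin & ys[j] >= margin & ys[j] <= side - margin
    if (!any(keep)) next
    out[[j]] <- cbind(xs[keep], rep(ys[j], sum(keep)))
  }
  do.call(rbind, out)
}

generate_square_points <- function(side, s, jitter_frac = 0.18) {
  bpts <- dedup_points(square_boundary_points(side, s))
  ipts <- hex_lattice(side, s, margin = 0.55 * s)
  if (!is.null(ipts) && nrow(ipts)) {
    th <- stats::runif(nrow(ipts), 0, 2 * pi)
    rr <- jitter_frac * s * sqrt(stats::runif(nrow(ipts)))
    ipts <- ipts + cbind(rr * cos(th), rr * sin(th))
  }
  list(boundary = bpts, interior = ipts)
}

#' Unstructured triangulation of a square
#'
#' Delaunay-style unstructured triangulation of a `side` by `side` square
#' with approximately uniform elements. The generator lays down a jittered
#' hexagonal lattice plus uniform boundary points, triangulates (Bowyer-
#' Watson) and internally rescales the lattice spacing so the mean element
#' circumdiameter lands on `target_h`. Deterministic for a fixed `seed`.
#'
#' @param side square side in cm.
#' @param target_h target mean element diameter in cm.
#' @param seed integer RNG seed for the lattice jitter.
#' @return an `hp_mesh`.
#' @export
build_square_mesh <- function(side, target_h, seed = 1L) {
  if (side <= 0 || target_h <= 0 || target_h >= side) stop("invalid side/target_h")
  s <- target_h / 1.2
  mesh <- NULL
  for (iter in 1:4) {
    set.seed(seed)
    g <- generate_square_points(side, s)
    pts <- rbind(g$boundary, g$interior)
    tt <- delaunay_triangulate(pts)
    mesh <- new_mesh_2d(pts, tt, side = side)
    hm <- mean_element_diameter(mesh)
    if (abs(hm - target_h) / target_h < 0.02) break
    s <- s * target_h / hm
  }
  hm <- mean_element_diameter(mesh)
  if (abs(hm - target_h) / target_h > 0.15) stop("mesh generation failed to reach target_h")
  mesh
}

#' Triangulation of a square with circular holes
#'
#' Like [build_square_mesh()] but with circular holes (blood vessels) cut
#' out. Hole boundaries are resolved by point rings lying exactly on each
#' circle with spacing about half the background spacing, so elements grade
#' smaller near the holes. Hole boundary edges are tagged `4 + k` for hole
#' `k`.
#'
#' @inheritParams build_square_mesh
#' @param holes list of holes, each `list(center = c(x, y), radius = r)`.
#' @export
build_square_with_holes_mesh <- function(side, holes = default_holes(), target_h,
                                         seed = 1L) {
  if (side <= 0 || target_h <= 0 || target_h >= side) stop("invalid side/target_h")
  for (h in holes) {
    if (any(h$center - h$radius < 0) || any(h$center + h$radius > side))
      stop("holes must lie strictly inside the square")
  }
  if (length(holes) >= 2L) {
    for (i in seq_along(holes)) for (j in seq_along(holes)) {
      if (i < j) {
        d <- sqrt(sum((holes[[i]]$center - holes[[j]]$center)^2))
        if (d <= holes[[i]]$radius + holes[[j]]$radius) stop("holes overlap")
      }
    }
  }
  s <- target_h / 1.2
  mesh <- NULL
  for (iter in 1:4) {
    set.seed(seed)
    g <- generate_square_points(side, s)
    rings <- list()
    clear_radius <- numeric(length(holes))
    for (k in seq_along(holes)) {
      h <- holes[[k]]
      # boundary ring spacing resolves the circle (chord half-angle <= 1/28)
      # and never exceeds the graded background spacing
      srk <- min(0.55 * s, h$radius / 14)
      ring1 <- function(radius, spacing, jit) {
        nk <- max(12L, round(2 * pi * radius / spacing))
        th <- seq(0, 2 * pi, length.out = nk + 1L)[-1L]
        rj <- radius * (1 + jit * sin(7 * th + k))
        cbind(h$center[1L] + rj * cos(th), h$center[2L] + rj * sin(th))
      }
      # exact circle ring (sub-1e-9 jitter breaks cocircularity), then
      # geometrically graded outer rings up to the background spacing
      rings[[length(rings) + 1L]] <- ring1(h$radius, srk, 1e-10)
      rr <- h$radius; sp <- srk
      while (sp < 0.6 * s) {
        rr <- rr + 1.3 * sp
        sp <- min(1.5 * sp, 0.8 * s)
        rings[[length(rings) + 1L]] <- ring1(rr, sp, 1e-4)
      }
      clear_radius[k] <- rr + 0.75 * s
    }
    ring_pts <- do.call(rbind, rings)
    # graded outer rings of one hole must not invade another hole (or leave
    # the domain)
    keep_r <- ring_pts[, 1L] > 1e-9 & ring_pts[, 1L] < side - 1e-9 &
      ring_pts[, 2L] > 1e-9 & ring_pts[, 2L] < side - 1e-9
    for (k in seq_along(holes)) {
      h <- holes[[k]]
      srk <- min(0.55 * s, h$radius / 14)
      d <- sqrt((ring_pts[, 1L] - h$center[1L])^2 +
                  (ring_pts[, 2L] - h$center[2L])^2)
      # keep the hole's own boundary ring; other points stay clear of it
      keep_r <- keep_r & (abs(d - h$radius) < 1e-6 | d > h$radius + 0.5 * srk)
    }
    ring_pts <- ring_pts[keep_r, , drop = FALSE]
    ipts <- g$interior
    if (!is.null(ipts) && nrow(ipts)) {
      keep <- rep(TRUE, nrow(ipts))
      for (k in seq_along(holes)) {
        h <- holes[[k]]
        d <- sqrt((ipts[, 1L] - h$center[1L])^2 + (ipts[, 2L] - h$center[2L])^2)
        keep <- keep & d > clear_radius[k]
      }
      ipts <- ipts[keep, , drop = FALSE]
    }
    pts <- rbind(g$boundary, ring_pts, ipts)
    tt <- delaunay_triangulate(pts)
    # drop triangles inside the holes
    cen <- (pts[tt[, 1L], , drop = FALSE] + pts[tt[, 2L], , drop = FALSE] +
              pts[tt[, 3L], , drop = FALSE]) / 3
    inside <- rep(FALSE, nrow(tt))
    for (h in holes) {
      d <- sqrt((cen[, 1L] - h$center[1L])^2 + (cen[, 2L] - h$center[2L])^2)
      inside <- inside | d < h$radius
    }
    tt <- tt[!inside, , drop = FALSE]
    mesh <- new_mesh_2d(pts, tt, holes = holes, side = side)
    hm <- mean_element_diameter(mesh)
    if (abs(hm - target_h) / target_h < 0.05) break
    s <- s * target_h / hm
  }
  mesh
}

#' Default two-hole geometry
#'
#' Two circular holes representing blood vessels crossing the simulation
#' plane: radius 0.08 cm at (0.32, 0.60) and radius 0.10 cm at
#' (0.68, 0.34).
#' @export
default_holes <- function() {
  list(list(center = c(0.32, 0.60), radius = 0.08),
       list(center = c(0.68, 0.34), radius = 0.10))
}

# ---------------------------------------------------------------------------
# Quality metrics

element_diameters <- function(mesh) {
  if (mesh$dimension == 1L) {
    abs(mesh$vertices[mesh$elements[, 2L], 1L] - mesh$vertices[mesh$elements[, 1L], 1L])
  } else {
    v <- mesh$vertices; el <- mesh$elements
    e1 <- sqrt(rowSums((v[el[, 2L], , drop = FALSE] - v[el[, 1L], , drop = FALSE])^2))
    e2 <- sqrt(rowSums((v[el[, 3L], , drop = FALSE] - v[el[, 2L], , drop = FALSE])^2))
    e3 <- sqrt(rowSums((v[el[, 1L], , drop = FALSE] - v[el[, 3L], , drop = FALSE])^2))
    pmax(e1, e2, e3)
  }
}

#' Mean element diameter (mean of circumdiameters)
#' @param mesh an `hp_mesh`.
#' @export
mean_element_diameter <- function(mesh) {
  if (mesh$dimension == 1L) return(mean(element_diameters(mesh)))
  v <- mesh$vertices; el <- mesh$elements
  cc <- circumcircle(v[el[, 1L], , drop = FALSE], v[el[, 2L], , drop = FALSE],
                     v[el[, 3L], , drop = FALSE])
  mean(2 * sqrt(cc[, 3L]))
}

#' Mesh quality: maximum diameter and quasiuniformity/shape constants
#'
#' Returns `h = max h_i`, the quasiuniformity constant `Q = max h / h_i`
#' and (2D) the shape constant `R = max h_i / rho_i`, where `h_i` is the
#' element diameter (longest edge) and `rho_i` the inradius diameter.
#'
#' @param mesh an `hp_mesh`.
#' @return list with `h`, `Q`, `R` (R is `NA` in 1D).
#' @export
mesh_quality <- function(mesh) {
  hi <- element_diameters(mesh)
  if (any(hi <= 0)) stop(sprintf("degenerate element (zero area): index %d",
                                 which(hi <= 0)[1L]))
  h <- max(hi)
  Q <- max(h / hi)
  R <- NA_real_
  if (mesh$dimension == 2L) {
    v <- mesh$vertices; el <- mesh$elements
    a <- sqrt(rowSums((v[el[, 2L], , drop = FALSE] - v[el[, 1L], , drop = FALSE])^2))
    b <- sqrt(rowSums((v[el[, 3L], , drop = FALSE] - v[el[, 2L], , drop = FALSE])^2))
    c <- sqrt(rowSums((v[el[, 1L], , drop = FALSE] - v[el[, 3L], , drop = FALSE])^2))
    area <- signed_areas(v, el)
    if (any(area <= 0)) stop(sprintf("degenerate element (zero area): index %d",
                                     which(area <= 0)[1L]))
    rho <- 2 * (2 * area / (a + b + c))   # inradius diameter
    R <- max(hi / rho)
  }
  list(h = h, Q = Q, R = R)
}

# ---------------------------------------------------------------------------
# File I/O: Triangle .node/.ele, Gmsh MSH 2.2 ASCII, legacy VTK output

#' Read a 2D mesh from Triangle or Gmsh files
#'
#' @param path for `triangle_node_ele`, the path of the `.node` file (the
#'   matching `.ele` file must sit alongside); for `gmsh_msh2` a `.msh`
#'   (MSH version 2.2 ASCII) file.
#' @param format `"triangle_node_ele"` or `"gmsh_msh2"`.
#' @return an `hp_mesh`.
#' @export
read_mesh <- function(path, format = c("triangle_node_ele", "gmsh_msh2")) {
  format <- match.arg(format)
  if (format == "triangle_node_ele") read_triangle_mesh(path) else read_msh2(path)
}

read_triangle_mesh <- function(path) {
  node_path <- if (grepl("\\.node$", path)) path else paste0(path, ".node")
  ele_path <- sub("\\.node$", ".ele", node_path)
  nl <- readLines(node_path)
  nl <- nl[!grepl("^\\s*(#|$)", nl)]
  hd <- scan(text = nl[1L], quiet = TRUE)
  nv <- hd[1L]
  if (length(nl) < nv + 1L) stop(sprintf("malformed .node file at line %d", length(nl)))
  vertices <- matrix(0, nv, 2L)
  for (i in seq_len(nv)) {
    row <- scan(text = nl[i + 1L], quiet = TRUE)
    if (length(row) < 3L) stop(sprintf("malformed .node file at line %d", i + 1L))
    vertices[row[1L], ] <- row[2:3]
  }
  el <- readLines(ele_path)
  el <- el[!grepl("^\\s*(#|$)", el)]
  hd <- scan(text = el[1L], quiet = TRUE)
  nt <- hd[1L]
  if (hd[2L] != 3L) stop("unsupported element: only 3-node triangles are supported")
  elements <- matrix(0L, nt, 3L)
  for (i in seq_len(nt)) {
    row <- scan(text = el[i + 1L], quiet = TRUE)
    if (length(row) < 4L) stop(sprintf("malformed .ele file at line %d", i + 1L))
    elements[row[1L], ] <- as.integer(row[2:4])
  }
  new_mesh_2d(vertices, elements)
}

read_msh2 <- function(path) {
  ln <- readLines(path)
  fmt <- which(ln == "$MeshFormat")
  if (!length(fmt)) stop("malformed MSH file at line 1: missing $MeshFormat")
  ver <- scan(text = ln[fmt + 1L], quiet = TRUE)
  if (floor(ver[1L]) != 2) stop(sprintf("unsupported format version %s", ver[1L]))
  i0 <- which(ln == "$Nodes")
  nv <- as.integer(ln[i0 + 1L])
  vertices <- matrix(0, nv, 2L)
  for (i in seq_len(nv)) {
    row <- scan(text = ln[i0 + 1L + i], quiet = TRUE)
    vertices[row[1L], ] <- row[2:3]
  }
  i0 <- which(ln == "$Elements")
  ne <- as.integer(ln[i0 + 1L])
  tris <- list(); k <- 0L
  for (i in seq_len(ne)) {
    row <- scan(text = ln[i0 + 1L + i], quiet = TRUE)
    type <- row[2L]; ntags <- row[3L]
    if (type == 2) {
      k <- k + 1L
      tris[[k]] <- as.integer(row[(4L + ntags):(6L + ntags)])
    } else if (type %in% c(1, 15)) {
      next  # boundary lines and points are ignored
    } else {
      stop(sprintf("unsupported element type %d at line %d", type, i0 + 1L + i))
    }
  }
  if (!k) stop("no triangles found in MSH file")
  new_mesh_2d(vertices, do.call(rbind, tris))
}

#' Write a mesh to Triangle or Gmsh format
#'
#' @param mesh an `hp_mesh` (2D).
#' @param path output path: `.node` basename for Triangle format, `.msh`
#'   file for Gmsh.
#' @param format `"triangle_node_ele"` or `"gmsh_msh2"`.
#' @export
write_mesh <- function(mesh, path, format = c("triangle_node_ele", "gmsh_msh2")) {
  format <- match.arg(format)
  if (mesh$dimension != 2L) stop("mesh file output is 2D-only")
  if (format == "triangle_node_ele") {
    node_path <- if (grepl("\\.node$", path)) path else paste0(path, ".node")
    ele_path <- sub("\\.node$", ".ele", node_path)
    con <- c(sprintf("%d 2 0 0", mesh$n_vertices),
             sprintf("%d %.17g %.17g", seq_len(mesh$n_vertices),
                     mesh$vertices[, 1L], mesh$vertices[, 2L]))
    writeLines(con, node_path)
    con <- c(sprintf("%d 3 0", mesh$n_elements),
             sprintf("%d %d %d %d", seq_len(mesh$n_elements),
                     mesh$elements[, 1L], mesh$elements[, 2L], mesh$elements[, 3L]))
    writeLines(con, ele_path)
  } else {
    con <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
             "$Nodes", sprintf("%d", mesh$n_vertices),
             sprintf("%d %.17g %.17g 0", seq_len(mesh$n_vertices),
                     mesh$vertices[, 1L], mesh$vertices[, 2L]),
             "$EndNodes",
             "$Elements", sprintf("%d", mesh$n_elements),
             sprintf("%d 2 2 0 1 %d %d %d", seq_len(mesh$n_elements),
                     mesh$elements[, 1L], mesh$elements[, 2L], mesh$elements[, 3L]),
             "$EndElements")
    writeLines(con, path)
  }
  invisible(path)
}

#' Write a legacy-VTK ASCII snapshot
#'
#' Writes the mesh with per-vertex scalar fields (point data; the
#' transmembrane potential field is conventionally named `"Vm"`) and
#' optional per-element vector fields (cell data, e.g. fibre directions).
#'
#' @param mesh an `hp_mesh`.
#' @param fields named list; vectors of length `n_vertices` become point
#'   data, matrices with `n_elements` rows and 2 columns become cell
#'   vector data.
#' @param path output file path.
#' @export
write_vtk <- function(mesh, fields, path) {
  v <- mesh$vertices
  if (mesh$dimension == 1L) v <- cbind(v, 0)
  out <- c("# vtk DataFile Version 3.0", "monodomainhp output", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", mesh$n_vertices),
           sprintf("%.10g %.10g 0", v[, 1L], v[, 2L]))
  nt <- mesh$n_elements
  if (mesh$dimension == 1L) {
    out <- c(out, sprintf("CELLS %d %d", nt, 3L * nt),
             sprintf("2 %d %d", mesh$elements[, 1L] - 1L, mesh$elements[, 2L] - 1L),
             sprintf("CELL_TYPES %d", nt), rep("3", nt))
  } else {
    out <- c(out, sprintf("CELLS %d %d", nt, 4L * nt),
             sprintf("3 %d %d %d", mesh$elements[, 1L] - 1L,
                     mesh$elements[, 2L] - 1L, mesh$elements[, 3L] - 1L),
             sprintf("CELL_TYPES %d", nt), rep("5", nt))
  }
  pf <- Filter(function(f) is.null(dim(f)), fields)
  cf <- Filter(function(f) !is.null(dim(f)), fields)
  if (length(pf)) {
    out <- c(out, sprintf("POINT_DATA %d", mesh$n_vertices))
    for (nm in names(pf)) {
      out <- c(out, sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
               sprintf("%.10g", pf[[nm]]))
    }
  }
  if (length(cf)) {
    out <- c(out, sprintf("CELL_DATA %d", nt))
    for (nm in names(cf)) {
      out <- c(out, sprintf("VECTORS %s double", nm),
               sprintf("%.10g %.10g 0", cf[[nm]][, 1L], cf[[nm]][, 2L]))
    }
  }
  writeLines(out, path)
  invisible(path)
}
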