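# Conductivity tensor fields built from fibre orientation: isotropic,
# fixed-axis anisotropic, cubic-polynomial angle fields, and rule-based
# Laplace-Dirichlet fields that negotiate around holes (blood vessels).
#
# sigma(x) = sigma_t I + (sigma_l - sigma_t) f f^T, with f(x) the unit
# fibre direction; eigenvalues are exactly {sigma_l, sigma_t} everywhere.

#' Conductivity tensor field from a fibre direction field
#'
#' @param fibre either a fixed unit vector `c(fx, fy)` or a function
#'   `function(pts, elem)` returning one unit row vector per point (`elem`
#'   gives the element id of each point when known, for mesh-based fields).
#' @param sigma_l,sigma_t longitudinal and transverse conductivities (S/m),
#'   `sigma_l >= sigma_t > 0`.
#' @return object of class `conductivity_field`.
#' @export
tensor_from_fibre <- function(fibre, sigma_l, sigma_t) {
  if (!(sigma_l >= sigma_t && sigma_t > 0)) stop("need sigma_l >= sigma_t > 0")
  if (is.numeric(fibre)) {
    nrm <- sqrt(sum(fibre^2))
    if (nrm < 1e-14) stop("zero-length fibre vector")
    fv <- fibre / nrm
    fibre_fun <- function(pts, elem = NULL) {
      matrix(fv, nrow(pts), 2L, byrow = TRUE)
    }
  } else {
    fibre_fun <- fibre
  }
  structure(list(dimension = 2L, sigma_l = sigma_l, sigma_t = sigma_t,
                 fibre = fibre_fun),
            class = "conductivity_field")
}

#' Homogeneous isotropic conductivity
#'
#' @param value conductivity (S/m).
#' @param dimension 1 or 2.
#' @export
isotropic_conductivity <- function(value, dimension = 2L) {
  structure(list(dimension = as.integer(dimension), sigma_l = value,
                 sigma_t = value, fibre = NULL),
            class = "conductivity_field")
}

#' @export
print.conductivity_field <- function(x, ...) {
  if (is.null(x$fibre)) {
    cat(sprintf("Isotropic conductivity: %g S/m\n", x$sigma_l))
  } else {
    cat(sprintf("Anisotropic conductivity: %g S/m along fibres, %g S/m across\n",
                x$sigma_l, x$sigma_t))
  }
  invisible(x)
}

#' Evaluate a conductivity field at points
#'
#' @param conductivity a `conductivity_field` or a single number.
#' @param mesh the mesh (used by mesh-based fibre fields).
#' @param pts evaluation points, one per row.
#' @param elem optional element id per point.
#' @return in 2D a matrix with columns `s11`, `s12`, `s22`; in 1D a vector.
#' @export
conductivity_values <- function(conductivity, mesh, pts, elem = NULL) {
  n <- nrow(pts)
  if (is.numeric(conductivity) && length(conductivity) == 1L) {
    if (mesh$dimension == 1L) return(rep(conductivity, n))
    return(cbind(s11 = rep(conductivity, n), s12 = 0, s22 = conductivity))
  }
  stopifnot(inherits(conductivity, "conductivity_field"))
  if (mesh$dimension == 1L) return(rep(conductivity$sigma_l, n))
  if (is.null(conductivity$fibre)) {
    return(cbind(s11 = rep(conductivity$sigma_l, n), s12 = 0,
                 s22 = conductivity$sigma_l))
  }
  f <- conductivity$fibre(pts, elem)
  nrm <- sqrt(f[, 1L]^2 + f[, 2L]^2)
  if (any(nrm < 1e-14)) stop("zero-length fibre vector")
  f <- f / nrm
  dlt <- conductivity$sigma_l - conductivity$sigma_t
  cbind(s11 = conductivity$sigma_t + dlt * f[, 1L]^2,
        s12 = dlt * f[, 1L] * f[, 2L],
        s22 = conductivity$sigma_t + dlt * f[, 2L]^2)
}

#' Cubic polynomial fibre angle field
#'
#' Fibre direction \eqn{(\cos\theta, \sin\theta)} with the angle a
#' bivariate cubic \eqn{\theta(x, y) = \sum_k c_k m_k(x, y)} over the
#' monomials \eqn{1, x, y, x^2, xy, y^2, x^3, x^2 y, x y^2, y^3}. The
#' default coefficients emulate cardiac fibres rapidly changing
#' orientation across the unit square (angle variation well above 90
#' degrees).
#'
#' @param coefficients numeric vector of 10 monomial coefficients
#'   (radians).
#' @return fibre direction function suitable for [tensor_from_fibre()].
#' @export
cubic_angle_field <- function(coefficients = default_cubic_fibre_coefficients()) {
  cf <- rep_len(coefficients, 10L)
  function(pts, elem = NULL) {
    x <- pts[, 1L]; y <- pts[, 2L]
    th <- cf[1L] + cf[2L] * x + cf[3L] * y + cf[4L] * x^2 + cf[5L] * x * y +
      cf[6L] * y^2 + cf[7L] * x^3 + cf[8L] * x^2 * y + cf[9L] * x * y^2 +
      cf[10L] * y^3
    cbind(cos(th), sin(th))
  }
}

#' Default cubic fibre-angle coefficients
#'
#' The angle field \eqn{\theta(x,y) = (\pi/2)(2y-1)^3 + (\pi/4)(2x-1)}
#' expressed in monomial coefficients: a smooth field sweeping through
#' about 270 degrees across the unit square.
#' @export
default_cubic_fibre_coefficients <- function() {
  c(-3 * pi / 4, pi / 2, 3 * pi, 0, 0, -6 * pi, 0, 0, 0, 4 * pi)
}

# ---------------------------------------------------------------------------
# Laplace-Dirichlet rule-based fibre field

# Barycentric coordinates of physical points inside known elements.
physical_to_bary <- function(mesh, pts, elem) {
  v1 <- mesh$vertices[mesh$elements[elem, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$elements[elem, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$elements[elem, 3L], , drop = FALSE]
  d <- (v2[, 1L] - v1[, 1L]) * (v3[, 2L] - v1[, 2L]) -
    (v3[, 1L] - v1[, 1L]) * (v2[, 2L] - v1[, 2L])
  l2 <- ((pts[, 1L] - v1[, 1L]) * (v3[, 2L] - v1[, 2L]) -
           (v3[, 1L] - v1[, 1L]) * (pts[, 2L] - v1[, 2L])) / d
  l3 <- ((v2[, 1L] - v1[, 1L]) * (pts[, 2L] - v1[, 2L]) -
           (pts[, 1L] - v1[, 1L]) * (v2[, 2L] - v1[, 2L])) / d
  cbind(1 - l2 - l3, l2, l3)
}

# Gradient of a hierarchical field at points with known element ids.
hier_gradient_at <- function(mesh, dofmap, coeffs, pts, elem) {
  lam <- physical_to_bary(mesh, pts, elem)
  ev <- hbasis_eval(dofmap$basis, lam)
  geo <- element_geometry(mesh)
  n <- nrow(pts); nm <- dofmap$basis$n_modes
  cl <- matrix(coeffs[dofmap$elem_dofs[elem, , drop = FALSE]], n, nm) *
    dofmap$elem_signs[elem, , drop = FALSE]
  gx <- numeric(n); gy <- numeric(n)
  for (i in 1:3) {
    di <- rowSums(cl * matrix(ev$dlam[, , i], n, nm))
    gx <- gx + di * geo$grad_lambda[elem, i, 1L]
    gy <- gy + di * geo$grad_lambda[elem, i, 2L]
  }
  cbind(gx, gy)
}

#' Laplace-Dirichlet fibre field
#'
#' Solves Laplace's equation on the mesh with Dirichlet value +1 on the
#' inlet boundary edges, -1 on the outlet edges and natural (zero
#' Neumann) conditions elsewhere - including hole boundaries, so the
#' solution's gradient is tangent to the holes. The fibre direction is the
#' normalised gradient, which approximates how cardiac fibres negotiate
#' around blood vessels.
#'
#' @param mesh an `hp_mesh` with tagged boundary edges.
#' @param inlet_edge_tag,outlet_edge_tag boundary tags (square sides are
#'   1 = bottom, 2 = right, 3 = top, 4 = left).
#' @param p FEM degree of the potential solve (1 or 2).
#' @return list of class `laplace_fibres` with the potential coefficients,
#'   the dof map and a `fibre(pts, elem)` direction function.
#' @export
laplace_dirichlet_fibres <- function(mesh, inlet_edge_tag = 4L,
                                     outlet_edge_tag = 2L, p = 2L) {
  if (!p %in% c(1L, 2L)) stop("p must be 1 or 2")
  inlet <- which(mesh$edge_tags == inlet_edge_tag)
  outlet <- which(mesh$edge_tags == outlet_edge_tag)
  if (!length(inlet) || !length(outlet)) stop("bad tags: no such boundary edges")
  if (length(intersect(inlet, outlet))) stop("inlet and outlet tags overlap")
  dm <- dof_map(mesh, p)
  A <- assemble_stiffness(mesh, dm, 1)
  V <- mesh$n_vertices
  fix_idx <- c(unique(as.vector(mesh$edges[inlet, ])),
               unique(as.vector(mesh$edges[outlet, ])))
  fix_val <- c(rep(1, length(unique(as.vector(mesh$edges[inlet, ])))),
               rep(-1, length(unique(as.vector(mesh$edges[outlet, ])))))
  if (p >= 2L) {
    # edge-mode dofs on Dirichlet edges carry the (zero) deviation from the
    # linear trace
    emodes <- function(ed) V + (ed - 1L) * (p - 1L) + 1L
    fix_idx <- c(fix_idx, emodes(inlet), emodes(outlet))
    fix_val <- c(fix_val, rep(0, length(inlet) + length(outlet)))
  }
  free <- setdiff(seq_len(dm$n_dof), fix_idx)
  u <- numeric(dm$n_dof)
  u[fix_idx] <- fix_val
  rhs <- -as.numeric(A[free, fix_idx, drop = FALSE] %*% fix_val)
  u[free] <- as.numeric(Matrix::solve(A[free, free], rhs))
  if (any(!is.finite(u))) stop("singular system (bad tags)")
  fibre_fun <- function(pts, elem = NULL) {
    if (is.null(elem)) stop("Laplace-Dirichlet fibres need element ids")
    g <- hier_gradient_at(mesh, dm, u, pts, elem)
    nrm <- sqrt(g[, 1L]^2 + g[, 2L]^2)
    # Near stagnation points the potential gradient collapses and its
    # direction is ill-defined (the exact field is discontinuous there);
    # such points inherit the direction of the nearest well-defined point.
    thresh <- 0.2 * stats::median(nrm)
    badp <- which(nrm < thresh)
    if (length(badp) && length(badp) < length(nrm)) {
      ok <- which(nrm >= thresh)
      for (b in badp) {
        nb <- ok[which.min((pts[ok, 1L] - pts[b, 1L])^2 +
                             (pts[ok, 2L] - pts[b, 2L])^2)]
        g[b, ] <- g[nb, ]
      }
      nrm <- sqrt(g[, 1L]^2 + g[, 2L]^2)
    }
    if (any(nrm == 0)) stop("zero gradient at an evaluation point")
    g / nrm
  }
  structure(list(potential = u, dofmap = dm, mesh = mesh, fibre = fibre_fun),
            class = "laplace_fibres")
}

#' Tangency of a Laplace-Dirichlet fibre field to a hole boundary
#'
#' Evaluates the fibre direction at Gauss points on the hole's boundary
#' edges and returns the largest |f . n| against the exact circle normal.
#' Points in stagnation neighbourhoods - where the potential gradient
#' falls below `min_gradient` times the ring's median and the exact
#' direction field is singular, so the fibre direction is set by
#' continuation rather than by the potential - are excluded from the
#' maximum.
#'
#' @param fibres result of [laplace_dirichlet_fibres()].
#' @param hole_index which hole (tag `4 + hole_index`).
#' @param min_gradient relative gradient threshold defining well-posed
#'   evaluation points.
#' @return list with `max_tangency_error` (max |f . n|), `n_points` and
#'   `n_excluded`.
#' @export
hole_tangency <- function(fibres, hole_index = 1L, min_gradient = 0.3) {
  mesh <- fibres$mesh
  if (is.null(mesh$holes) || hole_index > length(mesh$holes))
    stop("no such hole")
  hole <- mesh$holes[[hole_index]]
  hedges <- which(mesh$edge_tags == 4L + hole_index)
  gl <- (1 + c(-1, 1) / sqrt(3)) / 2
  pts <- matrix(0, 2L * length(hedges), 2L)
  eid <- integer(2L * length(hedges))
  for (i in seq_along(hedges)) {
    ed <- hedges[i]
    vv <- mesh$vertices[mesh$edges[ed, ], ]
    pts[2L * i - 1L, ] <- vv[1L, ] + gl[1L] * (vv[2L, ] - vv[1L, ])
    pts[2L * i, ] <- vv[1L, ] + gl[2L] * (vv[2L, ] - vv[1L, ])
    eid[c(2L * i - 1L, 2L * i)] <-
      which(rowSums(mesh$elem_edges == ed) > 0L)[1L]
  }
  g <- hier_gradient_at(mesh, fibres$dofmap, fibres$potential, pts, eid)
  gn <- sqrt(g[, 1L]^2 + g[, 2L]^2)
  keep <- gn >= min_gradient * stats::median(gn)
  f <- g[keep, , drop = FALSE] / gn[keep]
  nhat <- cbind(pts[keep, 1L] - hole$center[1L], pts[keep, 2L] - hole$center[2L])
  nhat <- nhat / sqrt(rowSums(nhat^2))
  list(max_tangency_error = max(abs(rowSums(f * nhat))),
       n_points = length(gn), n_excluded = sum(!keep))
}
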