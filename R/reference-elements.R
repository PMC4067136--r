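# Reference-element services: hierarchical and nodal polynomial bases,
# Gauss-Lobatto point sets and quadrature rules on the reference interval
# [0, 1] and the reference triangle with vertices (0,0), (1,0), (0,1).
#
# Local edge convention on the triangle: e1 = (v1,v2), e2 = (v2,v3),
# e3 = (v3,v1). Odd-degree edge kernels change sign under edge reversal;
# global orientation is resolved by the dof map, which multiplies flipped
# edge modes by (-1)^degree.

#' Evaluate normalised Jacobi polynomials
#'
#' Returns values of the orthonormal Jacobi polynomials
#' \eqn{\tilde P_0^{(a,b)}, \dots, \tilde P_n^{(a,b)}} on \eqn{[-1, 1]}.
#'
#' @param n highest polynomial order.
#' @param a,b Jacobi weight exponents (both > -1).
#' @param x evaluation points in \eqn{[-1, 1]}.
#' @return matrix of dimension `length(x)` by `n + 1`.
#' @keywords internal
jacobi_norm <- function(n, a, b, x) {
  x <- as.numeric(x)
  PL <- matrix(0, length(x), n + 1L)
  gamma0 <- 2^(a + b + 1) / (a + b + 1) * gamma(a + 1) * gamma(b + 1) / gamma(a + b + 1)
  PL[, 1L] <- 1 / sqrt(gamma0)
  if (n == 0L) return(PL)
  gamma1 <- (a + 1) * (b + 1) / (a + b + 3) * gamma0
  PL[, 2L] <- ((a + b + 2) * x / 2 + (a - b) / 2) / sqrt(gamma1)
  if (n == 1L) return(PL)
  aold <- 2 / (2 + a + b) * sqrt((a + 1) * (b + 1) / (a + b + 3))
  for (i in seq_len(n - 1L)) {
    h1 <- 2 * i + a + b
    anew <- 2 / (h1 + 2) * sqrt((i + 1) * (i + 1 + a + b) * (i + 1 + a) * (i + 1 + b) /
                                  ((h1 + 1) * (h1 + 3)))
    bnew <- -(a^2 - b^2) / (h1 * (h1 + 2))
    PL[, i + 2L] <- ((x - bnew) * PL[, i + 1L] - aold * PL[, i]) / anew
    aold <- anew
  }
  PL
}

# Derivative of the normalised Jacobi polynomial of order n:
# d/dx P~_n^{(a,b)} = sqrt(n (n + a + b + 1)) P~_{n-1}^{(a+1,b+1)}.
jacobi_norm_deriv <- function(n, a, b, x) {
  x <- as.numeric(x)
  D <- matrix(0, length(x), n + 1L)
  if (n >= 1L) {
    P <- jacobi_norm(n - 1L, a + 1, b + 1, x)
    for (k in seq_len(n)) {
      D[, k + 1L] <- sqrt(k * (k + a + b + 1)) * P[, k]
    }
  }
  D
}

# Edge/bubble kernel K_m(t) on [-1, 1] and its derivative, m >= 0.
# K_0 = 1, K_1 = t, K_2 = (5 t^2 - 1) / 4 (a fixed, well-conditioned
# integrated-Legendre choice); K_m for m >= 3 is the Jacobi(1,1)
# polynomial of order m. Parity: K_m(-t) = (-1)^m K_m(t).
kernel_eval <- function(m, t) {
  t <- as.numeric(t)
  if (m == 0L) return(list(val = rep(1, length(t)), d = rep(0, length(t))))
  if (m == 1L) return(list(val = t, d = rep(1, length(t))))
  if (m == 2L) return(list(val = (5 * t^2 - 1) / 4, d = 5 * t / 2))
  val <- jacobi_norm(m, 1, 1, t)[, m + 1L]
  d <- jacobi_norm_deriv(m, 1, 1, t)[, m + 1L]
  list(val = val, d = d)
}

#' Gauss-Lobatto points on the unit interval
#'
#' The `np` Gauss-Lobatto points on \eqn{[0, 1]}: the endpoints plus the
#' roots of \eqn{P'_{np-1}} mapped from \eqn{[-1, 1]}. These are the
#' interpolation nodes used for the nodal representation of the cell state.
#'
#' @param np number of points (at least 2).
#' @return increasing numeric vector of length `np`.
#' @export
gauss_lobatto_points <- function(np) {
  if (np < 2L) stop("Gauss-Lobatto sets need at least 2 points")
  if (np == 2L) return(c(0, 1))
  n_int <- np - 2L
  # Interior points are the roots of the Jacobi(1,1) polynomial of order
  # n_int, found as eigenvalues of its symmetric recurrence matrix.
  if (n_int == 1L) {
    r <- 0
  } else {
    k <- seq_len(n_int - 1L)
    off <- sqrt(k * (k + 2) / ((2 * k + 1) * (2 * k + 3)))
    J <- diag(0, n_int)
    J[cbind(k, k + 1L)] <- off
    J[cbind(k + 1L, k)] <- off
    r <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  }
  c(0, (r + 1) / 2, 1)
}

#' Quadrature rule on the reference interval or triangle
#'
#' Gauss-Legendre on \eqn{[0,1]}; on the reference triangle a collapsed
#' (Duffy) tensor-product Gauss rule with positive weights. The rule
#' integrates all polynomials up to degree `exactness` exactly.
#'
#' @param dimension 1 or 2.
#' @param exactness requested polynomial exactness degree.
#' @return an object of class `quadrature_rule` with fields `points`
#'   (matrix, one row per point; reference coordinates), `weights`,
#'   `exactness` and for triangles `bary` (barycentric coordinates).
#' @export
gauss_rule <- function(dimension, exactness) {
  if (!dimension %in% c(1L, 2L)) stop("dimension must be 1 or 2")
  if (exactness < 0 || exactness > 60) stop("requested exactness unavailable")
  exactness <- as.integer(exactness)
  if (dimension == 1L) {
    n <- max(1L, as.integer(ceiling((exactness + 1) / 2)))
    g <- pracma::gaussLegendre(n, 0, 1)
    rule <- list(points = matrix(g$x, ncol = 1L), weights = g$w,
                 exactness = 2L * n - 1L, dimension = 1L)
  } else {
    n <- max(1L, as.integer(ceiling((exactness + 2) / 2)))
    g <- pracma::gaussLegendre(n, 0, 1)
    xi <- rep(g$x, times = n); wxi <- rep(g$w, times = n)
    eta <- rep(g$x, each = n); weta <- rep(g$w, each = n)
    x <- xi * (1 - eta)
    y <- eta
    w <- wxi * weta * (1 - eta)
    rule <- list(points = cbind(x, y), weights = w,
                 exactness = 2L * n - 3L, dimension = 2L)
    rule$bary <- cbind(1 - x - y, x, y)
  }
  # the constructed rule is at least as exact as requested
  rule$exactness <- max(rule$exactness, exactness)
  class(rule) <- "quadrature_rule"
  rule
}

# ---------------------------------------------------------------------------
# Hierarchical bases

#' Hierarchical basis on the reference interval
#'
#' Modes on \eqn{[0,1]} ordered by degree: the two linear hat components
#' \eqn{1-x} and \eqn{x}, then one bubble per degree:
#' \eqn{x(1-x)} (quadratic), \eqn{x(1-x)(1/2-x)} (cubic), the quartic
#' bubble \eqn{x(1-x)(5(2x-1)^2-1)/4}, and integrated-Legendre bubbles
#' beyond. The degree-p mode list is a prefix of the degree-(p+1) list.
#'
#' @param p polynomial degree; the solver uses 1 to 4, degrees up to 6 are
#'   available to carry the nodal (cell-state) degree.
#' @return object of class `hierarchical_basis`.
#' @export
hierarchical_basis_interval <- function(p) {
  p <- as.integer(p)
  if (p < 1L || p > 6L) stop("degree outside supported range (1..6)")
  modes <- data.frame(kind = c("vertex", "vertex"), entity = c(1L, 2L),
                      degree = c(1L, 1L), stringsAsFactors = FALSE)
  if (p >= 2L) {
    modes <- rbind(modes, data.frame(kind = "edge", entity = 1L,
                                     degree = 2:p, stringsAsFactors = FALSE))
  }
  structure(list(dimension = 1L, degree = p, modes = modes,
                 n_modes = nrow(modes)),
            class = "hierarchical_basis")
}

#' Hierarchical basis on the reference triangle
#'
#' In barycentric coordinates \eqn{(\lambda_1,\lambda_2,\lambda_3)}:
#' three vertex modes \eqn{\lambda_i}; per edge \eqn{(a,b)} one mode per
#' degree \eqn{d \ge 2}, \eqn{\lambda_a\lambda_b K_{d-2}(\lambda_b-\lambda_a)};
#' interior modes \eqn{\lambda_1\lambda_2\lambda_3} times a monomial basis
#' of the remaining degree. Counts are 3, 6, 10, 15 for p = 1..4. Modes are
#' listed degree-major so the degree-p list is a prefix of the degree-(p+1)
#' list. The trace of an edge mode on its edge is the 1D mode of the same
#' degree up to a fixed scale.
#'
#' @inheritParams hierarchical_basis_interval
#' @return object of class `hierarchical_basis`.
#' @export
hierarchical_basis_triangle <- function(p) {
  p <- as.integer(p)
  if (p < 1L || p > 6L) stop("degree outside supported range (1..6)")
  edges <- local_edges()
  modes <- data.frame(kind = rep("vertex", 3L), entity = 1:3,
                      degree = 1L, i1 = 0L, i2 = 0L, stringsAsFactors = FALSE)
  for (d in seq_len(p)[-1L]) {
    modes <- rbind(modes, data.frame(kind = "edge", entity = 1:3, degree = d,
                                     i1 = 0L, i2 = 0L, stringsAsFactors = FALSE))
    if (d >= 3L) {
      # interior modes of exact degree d: lambda1*lambda2*lambda3 *
      # lambda1^i lambda2^(d-3-i), i = d-3 .. 0
      ii <- (d - 3L):0L
      modes <- rbind(modes, data.frame(kind = "interior", entity = 0L,
                                       degree = d, i1 = ii, i2 = (d - 3L) - ii,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(dimension = 2L, degree = p, modes = modes,
                 n_modes = nrow(modes), edges = edges),
            class = "hierarchical_basis")
}

local_edges <- function() rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))

#' @export
print.hierarchical_basis <- function(x, ...) {
  cat(sprintf("Hierarchical basis: dimension %d, degree %d, %d modes\n",
              x$dimension, x$degree, x$n_modes))
  print(table(x$modes$kind))
  invisible(x)
}

#' Evaluate a hierarchical basis
#'
#' @param basis a `hierarchical_basis`.
#' @param x evaluation points: for dimension 1 a numeric vector in
#'   \eqn{[0,1]}; for dimension 2 a matrix of barycentric coordinates
#'   (columns \eqn{\lambda_1,\lambda_2,\lambda_3}) or of reference
#'   Cartesian coordinates (2 columns).
#' @return list with `val` (points by modes) and the gradient: `dx` in 1D;
#'   `dlam` in 2D, an array points x modes x 3 of barycentric partials.
#' @export
hbasis_eval <- function(basis, x) {
  if (basis$dimension == 1L) hbasis_eval_interval(basis, x)
  else hbasis_eval_triangle(basis, x)
}

hbasis_eval_interval <- function(basis, x) {
  x <- as.numeric(x)
  n <- length(x)
  nm <- basis$n_modes
  val <- matrix(0, n, nm)
  dx <- matrix(0, n, nm)
  val[, 1L] <- 1 - x; dx[, 1L] <- -1
  val[, 2L] <- x;     dx[, 2L] <- 1
  if (basis$degree >= 2L) {
    bub <- x * (1 - x); dbub <- 1 - 2 * x
    for (d in 2:basis$degree) {
      # the cubic is kept in its classical displayed form x(1-x)(1/2-x)
      sc <- if (d == 3L) -0.5 else 1
      k <- kernel_eval(d - 2L, 2 * x - 1)
      val[, d + 1L] <- sc * bub * k$val
      dx[, d + 1L] <- sc * (dbub * k$val + bub * 2 * k$d)
    }
  }
  list(val = val, dx = dx)
}

hbasis_eval_triangle <- function(basis, x) {
  lam <- as.matrix(x)
  if (ncol(lam) == 2L) lam <- cbind(1 - lam[, 1L] - lam[, 2L], lam[, 1L], lam[, 2L])
  if (ncol(lam) != 3L) stop("expected barycentric (3 cols) or Cartesian (2 cols) points")
  n <- nrow(lam)
  nm <- basis$n_modes
  val <- matrix(0, n, nm)
  dlam <- array(0, c(n, nm, 3L))
  modes <- basis$modes
  edges <- basis$edges
  for (k in seq_len(nm)) {
    kind <- modes$kind[k]; d <- modes$degree[k]
    if (kind == "vertex") {
      v <- modes$entity[k]
      val[, k] <- lam[, v]
      dlam[, k, v] <- 1
    } else if (kind == "edge") {
      a <- edges[modes$entity[k], 1L]; b <- edges[modes$entity[k], 2L]
      la <- lam[, a]; lb <- lam[, b]
      ke <- kernel_eval(d - 2L, lb - la)
      val[, k] <- la * lb * ke$val
      dlam[, k, a] <- lb * ke$val - la * lb * ke$d
      dlam[, k, b] <- la * ke$val + la * lb * ke$d
    } else {
      i1 <- modes$i1[k]; i2 <- modes$i2[k]
      l1 <- lam[, 1L]; l2 <- lam[, 2L]; l3 <- lam[, 3L]
      mono <- l1^i1 * l2^i2
      val[, k] <- l1 * l2 * l3 * mono
      dlam[, k, 1L] <- l2 * l3 * (i1 + 1) * safe_pow(l1, i1) * l2^i2
      dlam[, k, 2L] <- l1 * l3 * (i2 + 1) * l1^i1 * safe_pow(l2, i2)
      dlam[, k, 3L] <- l1 * l2 * mono
    }
  }
  list(val = val, dlam = dlam)
}

# x^m with the convention 0^0 = 1 kept stable for m = 0
safe_pow <- function(x, m) if (m == 0L) rep(1, length(x)) else x^m

# Signs applied to local modes when an element edge runs against the
# global (low vertex index -> high vertex index) orientation: the degree-d
# edge kernel has parity (-1)^d.
mode_orientation_signs <- function(basis, flips) {
  s <- rep(1, basis$n_modes)
  if (basis$dimension == 1L) return(s)
  modes <- basis$modes
  for (e in 1:3) {
    if (flips[e]) {
      k <- which(modes$kind == "edge" & modes$entity == e & modes$degree %% 2L == 1L)
      s[k] <- -1
    }
  }
  s
}

# ---------------------------------------------------------------------------
# Nodal (Lagrange) bases at Gauss-Lobatto-type points

#' Nodal point set and Lagrange basis
#'
#' For dimension 1, the Gauss-Lobatto points on \eqn{[0,1]}. For dimension
#' 2, a degree-\eqn{\tilde p} simplex point set built by warping the
#' principal lattice so that every edge trace is exactly the 1D
#' Gauss-Lobatto set (warp-and-blend construction). Cardinal (Lagrange)
#' functions are obtained by generalised Vandermonde inversion in an
#' orthonormal (Legendre / Proriol-Koornwinder-Dubiner) basis.
#'
#' @param dimension 1 or 2.
#' @param p nodal degree \eqn{\tilde p}, between 1 and 6.
#' @return object of class `nodal_basis` with fields `points` (reference
#'   Cartesian coordinates), `bary` (2D only), `classify` (data frame with
#'   `kind` vertex/edge/interior, `entity` local id, `index` position along
#'   the entity) and an inverse Vandermonde for cardinal evaluation.
#' @export
nodal_points <- function(dimension, p) {
  p <- as.integer(p)
  if (!dimension %in% c(1L, 2L)) stop("dimension must be 1 or 2")
  if (p < 1L || p > 6L) stop("unsupported nodal degree (1..6)")
  if (dimension == 1L) {
    pts <- gauss_lobatto_points(p + 1L)
    # order: the two endpoints (vertices) first, then interior points
    ord <- c(1L, p + 1L, setdiff(seq_len(p + 1L), c(1L, p + 1L)))
    pts <- pts[ord]
    classify <- data.frame(
      kind = c("vertex", "vertex", rep("interior", max(0L, p - 1L))),
      entity = c(1L, 2L, rep(1L, max(0L, p - 1L))),
      index = c(1L, 1L, seq_len(max(0L, p - 1L))),
      stringsAsFactors = FALSE)
    V <- jacobi_norm(p, 0, 0, 2 * pts - 1)
    nb <- list(dimension = 1L, degree = p, points = matrix(pts, ncol = 1L),
               classify = classify, Vinv = solve(V))
  } else {
    wb <- warp_blend_nodes(p)
    V <- pkd_vandermonde(p, wb$points)
    if (abs(det(V)) < 1e-12) stop("singular Vandermonde: bad nodal set")
    nb <- list(dimension = 2L, degree = p, points = wb$points, bary = wb$bary,
               classify = wb$classify, Vinv = solve(V))
  }
  class(nb) <- "nodal_basis"
  nb
}

#' @export
print.nodal_basis <- function(x, ...) {
  cat(sprintf("Nodal basis: dimension %d, degree %d, %d points\n",
              x$dimension, x$degree, nrow(x$points)))
  invisible(x)
}

# Orthonormal PKD basis on the reference triangle (0,0),(1,0),(0,1).
pkd_vandermonde <- function(p, pts) {
  r <- 2 * pts[, 1L] - 1
  s <- 2 * pts[, 2L] - 1
  a <- ifelse(abs(s - 1) > 1e-14, 2 * (1 + r) / (1 - s) - 1, -1)
  b <- s
  n <- nrow(pts)
  nm <- (p + 1L) * (p + 2L) / 2L
  V <- matrix(0, n, nm)
  Pa <- jacobi_norm(p, 0, 0, a)
  col <- 0L
  for (i in 0:p) {
    Pb <- jacobi_norm(p - i, 2 * i + 1, 0, b)
    for (j in 0:(p - i)) {
      col <- col + 1L
      V[, col] <- sqrt(2) * Pa[, i + 1L] * Pb[, j + 1L] * (1 - b)^i * 2
      # factor 2: orthonormal w.r.t. our reference triangle of area 1/2
      # (the bi-unit triangle has area 2; the Jacobian of the map is 1/4)
    }
  }
  V
}

# Warp-and-blend nodal lattice on the reference triangle.
warp_blend_nodes <- function(p) {
  alpopt <- c(0, 0, 1.4152, 0.1001, 0.2751, 0.98, 1.0999)
  alpha <- if (p <= length(alpopt)) alpopt[p] else 5 / 3
  # lattice indices (i1, i2, i3), i1 + i2 + i3 = p, for vertices v1, v2, v3
  idx <- NULL
  for (i1 in p:0) for (i2 in (p - i1):0) {
    idx <- rbind(idx, c(i1, i2, p - i1 - i2))
  }
  L1 <- idx[, 1L] / p; L2 <- idx[, 2L] / p; L3 <- idx[, 3L] / p
  # equilateral coordinates (vertex 1 on top)
  x <- -L2 + L3
  y <- (-L2 - L3 + 2 * L1) / sqrt(3)
  if (p >= 2L) {
    blend1 <- 4 * L2 * L3
    blend2 <- 4 * L1 * L3
    blend3 <- 4 * L1 * L2
    w1 <- warp_factor(p, L3 - L2)
    w2 <- warp_factor(p, L1 - L3)
    w3 <- warp_factor(p, L2 - L1)
    warp1 <- blend1 * w1 * (1 + (alpha * L1)^2)
    warp2 <- blend2 * w2 * (1 + (alpha * L2)^2)
    warp3 <- blend3 * w3 * (1 + (alpha * L3)^2)
    x <- x + 1 * warp1 + cos(2 * pi / 3) * warp2 + cos(4 * pi / 3) * warp3
    y <- y + 0 * warp1 + sin(2 * pi / 3) * warp2 + sin(4 * pi / 3) * warp3
  }
  # back to barycentric: equilateral triangle v1 = (0, 2/sqrt(3)),
  # v2 = (-1, -1/sqrt(3)), v3 = (1, -1/sqrt(3))
  lam1 <- (sqrt(3) * y + 1) / 3
  lam2 <- (2 - sqrt(3) * y - 3 * x) / 6
  lam3 <- (2 - sqrt(3) * y + 3 * x) / 6
  bary <- cbind(lam1, lam2, lam3)
  pts <- cbind(lam2, lam3)  # reference Cartesian: x = lambda2, y = lambda3
  classify <- classify_lattice(idx, p)
  list(points = pts, bary = bary, classify = classify, lattice = idx)
}

# Classify lattice points by entity; edge position counts from the first
# local vertex of the edge (local edges (1,2), (2,3), (3,1)).
classify_lattice <- function(idx, p) {
  n <- nrow(idx)
  kind <- character(n); entity <- integer(n); index <- integer(n)
  edges <- local_edges()
  for (q in seq_len(n)) {
    nz <- which(idx[q, ] > 0L)
    if (length(nz) == 1L) {
      kind[q] <- "vertex"; entity[q] <- nz; index[q] <- 1L
    } else if (length(nz) == 2L) {
      kind[q] <- "edge"
      e <- which(apply(edges, 1L, function(ed) setequal(ed, nz)))
      entity[q] <- e
      # position 1..p-1 measured from local vertex edges[e,1]
      index[q] <- idx[q, edges[e, 2L]]
    } else {
      kind[q] <- "interior"; entity[q] <- 1L; index[q] <- 0L
    }
  }
  cl <- data.frame(kind = kind, entity = entity, index = index,
                   stringsAsFactors = FALSE)
  # give interior points a stable 1..n_int numbering
  ii <- which(cl$kind == "interior")
  cl$index[ii] <- seq_along(ii)
  cl
}

# 1D warp from equidistant to Gauss-Lobatto, zero at the interval ends.
warp_factor <- function(p, r) {
  lgl <- 2 * gauss_lobatto_points(p + 1L) - 1
  req <- seq(-1, 1, length.out = p + 1L)
  Veq <- jacobi_norm(p, 0, 0, req)
  Pmat <- t(jacobi_norm(p, 0, 0, r))
  Lmat <- t(solve(t(Veq), Pmat))    # Lagrange basis at req evaluated at r
  warp <- as.numeric(Lmat %*% (lgl - req))
  zerof <- abs(r) < 1 - 1e-10
  sf <- 1 - (zerof * r)^2
  warp / sf * zerof
}

#' Evaluate nodal (cardinal) basis functions
#'
#' Evaluates the Lagrange cardinal functions of a nodal basis at arbitrary
#' reference points; at the nodal points themselves this gives the identity
#' matrix.
#'
#' @param nb a `nodal_basis`.
#' @param x evaluation points (vector in 1D; matrix with 2 Cartesian or 3
#'   barycentric columns in 2D).
#' @return matrix `length(x)` by `n_nodes`.
#' @export
nodal_eval <- function(nb, x) {
  if (nb$dimension == 1L) {
    P <- jacobi_norm(nb$degree, 0, 0, 2 * as.numeric(x) - 1)
  } else {
    pts <- as.matrix(x)
    if (ncol(pts) == 3L) pts <- pts[, 2:3, drop = FALSE]
    P <- pkd_vandermonde(nb$degree, pts)
  }
  P %*% nb$Vinv
}
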