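# Sparse operator assembly: mass M, stiffness A with conductivity tensor,
# the nested rectangular mass matrix used for matrix-based right-hand-side
# assembly, the nodal <-> hierarchical change of basis, and evaluation
# matrices. A direct Gauss-quadrature assembler is kept as an independent
# oracle for the matrix-based shortcut.

# Per-element affine geometry: barycentric gradients and areas (2D) or
# element lengths (1D).
element_geometry <- function(mesh) {
  if (mesh$dimension == 1L) {
    h <- mesh$vertices[mesh$elements[, 2L], 1L] - mesh$vertices[mesh$elements[, 1L], 1L]
    return(list(h = h))
  }
  v1 <- mesh$vertices[mesh$elements[, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$elements[, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$elements[, 3L], , drop = FALSE]
  area2 <- (v2[, 1L] - v1[, 1L]) * (v3[, 2L] - v1[, 2L]) -
    (v3[, 1L] - v1[, 1L]) * (v2[, 2L] - v1[, 2L])   # = 2 * area
  # grad lambda_i = rotated opposite edge / (2A)
  gl <- array(0, c(mesh$n_elements, 3L, 2L))
  gl[, 1L, 1L] <- (v2[, 2L] - v3[, 2L]) / area2
  gl[, 1L, 2L] <- (v3[, 1L] - v2[, 1L]) / area2
  gl[, 2L, 1L] <- (v3[, 2L] - v1[, 2L]) / area2
  gl[, 2L, 2L] <- (v1[, 1L] - v3[, 1L]) / area2
  gl[, 3L, 1L] <- (v1[, 2L] - v2[, 2L]) / area2
  gl[, 3L, 2L] <- (v2[, 1L] - v1[, 1L]) / area2
  list(area2 = area2, grad_lambda = gl, v1 = v1, v2 = v2, v3 = v3)
}

# Physical coordinates of reference points in every element:
# returns a (n_elements * n_points) x dim matrix, points fastest.
map_points_to_elements <- function(mesh, ref) {
  geo <- element_geometry(mesh)
  if (mesh$dimension == 1L) {
    x1 <- mesh$vertices[mesh$elements[, 1L], 1L]
    xq <- outer(geo$h, ref[, 1L]) + x1      # T x nq
    return(matrix(as.vector(t(xq)), ncol = 1L))
  }
  lam <- cbind(1 - ref[, 1L] - ref[, 2L], ref[, 1L], ref[, 2L])
  nq <- nrow(lam)
  xs <- geo$v1[, 1L] %o% lam[, 1L] + geo$v2[, 1L] %o% lam[, 2L] + geo$v3[, 1L] %o% lam[, 3L]
  ys <- geo$v1[, 2L] %o% lam[, 1L] + geo$v2[, 2L] %o% lam[, 2L] + geo$v3[, 2L] %o% lam[, 3L]
  cbind(as.vector(t(xs)), as.vector(t(ys)))
}

# Scatter per-element local matrices into a global sparse matrix.
# vals: n_elements x (nrow_loc * ncol_loc), column-major local layout.
scatter_sparse <- function(rows_by_elem, cols_by_elem, vals, nrow_g, ncol_g) {
  nr <- ncol(rows_by_elem); nc <- ncol(cols_by_elem)
  I <- rows_by_elem[, rep(seq_len(nr), nc)]
  J <- cols_by_elem[, rep(seq_len(nc), each = nr)]
  Matrix::sparseMatrix(i = as.vector(I), j = as.vector(J), x = as.vector(vals),
                       dims = c(nrow_g, ncol_g))
}

#' Assemble mass matrices
#'
#' Assembles the Galerkin mass matrix of the degree-p hierarchical space
#' and, when `dofmap_pt` is given, the nested rectangular mass matrix
#' pairing the degree-p test basis with the degree-p-tilde hierarchical
#' trial basis. The rectangular matrix is realised by assembling the
#' degree-p-tilde square mass and selecting the rows of the modes shared
#' with degree p (valid by hierarchical nesting).
#'
#' @param mesh an `hp_mesh`.
#' @param dofmap degree-p `hp_dofmap`.
#' @param dofmap_pt optional degree-p-tilde `hp_dofmap` on the same mesh.
#' @return list with `M` (N x N, symmetric positive definite) and, if
#'   requested, `Mtilde` (N x N-tilde) and `M_pt` (the square
#'   degree-p-tilde mass).
#' @export
assemble_mass <- function(mesh, dofmap, dofmap_pt = NULL) {
  if (!is.null(dofmap_pt) && !identical(dofmap_pt$mesh$elements, mesh$elements))
    stop("dofmaps live on inconsistent meshes")
  M <- assemble_mass_square(mesh, dofmap)
  out <- list(M = M)
  if (!is.null(dofmap_pt)) {
    if (dofmap_pt$p >= dofmap$p) {
      # S_hp is nested in S_hp-tilde: take the shared-mode rows of the
      # degree-p-tilde square mass
      M_pt <- assemble_mass_square(mesh, dofmap_pt)
      shared <- shared_mode_indices(dofmap, dofmap_pt)
      out$Mtilde <- M_pt[shared, , drop = FALSE]
      out$M_pt <- M_pt
    } else {
      # diagnostic p-tilde < p: the trial space is nested in the test
      # space, so select the shared-mode columns of the degree-p mass
      shared <- shared_mode_indices(dofmap_pt, dofmap)
      out$Mtilde <- M[, shared, drop = FALSE]
      out$M_pt <- assemble_mass_square(mesh, dofmap_pt)
    }
  }
  out
}

assemble_mass_square <- function(mesh, dofmap) {
  basis <- dofmap$basis
  quad <- gauss_rule(mesh$dimension, 2L * basis$degree)
  geo <- element_geometry(mesh)
  if (mesh$dimension == 1L) {
    B <- hbasis_eval(basis, quad$points[, 1L])$val
    Mref <- t(B) %*% (quad$weights * B)
    scale <- geo$h
  } else {
    B <- hbasis_eval(basis, quad$bary)$val
    Mref <- t(B) %*% (quad$weights * B)
    scale <- geo$area2
  }
  nm <- basis$n_modes
  s <- dofmap$elem_signs
  ss <- s[, rep(seq_len(nm), nm)] * s[, rep(seq_len(nm), each = nm)]
  vals <- ss * outer(scale, as.vector(Mref))
  Matrix::forceSymmetric(scatter_sparse(dofmap$elem_dofs, dofmap$elem_dofs, vals,
                                        dofmap$n_dof, dofmap$n_dof))
}

#' Assemble the stiffness matrix
#'
#' Galerkin stiffness \eqn{A_{ji} = (\sigma \nabla\phi_i, \nabla\phi_j)}
#' with the conductivity evaluated pointwise at every Gauss point.
#'
#' @param mesh an `hp_mesh`.
#' @param dofmap an `hp_dofmap`.
#' @param conductivity a `conductivity_field` (see [tensor_from_fibre()]),
#'   or a single number for homogeneous isotropic conductivity. Units are
#'   the caller's; the solver feeds S/m and applies its unit conversion.
#' @return sparse symmetric positive semidefinite matrix (constants are in
#'   the kernel).
#' @export
assemble_stiffness <- function(mesh, dofmap, conductivity) {
  basis <- dofmap$basis
  quad <- gauss_rule(mesh$dimension, 2L * basis$degree)
  geo <- element_geometry(mesh)
  nm <- basis$n_modes
  nt <- mesh$n_elements
  nq <- length(quad$weights)
  if (mesh$dimension == 1L) {
    dB <- hbasis_eval(basis, quad$points[, 1L])$dx      # nq x nm (reference)
    sig <- conductivity_values(conductivity, mesh,
                               map_points_to_elements(mesh, quad$points),
                               elem = rep(seq_len(nt), each = nq))
    S <- matrix(sig, nt, nq, byrow = TRUE)              # sigma at (e, q)
    W <- S * matrix(quad$weights, nt, nq, byrow = TRUE) / geo$h
    GG <- matrix(0, nq, nm * nm)
    for (q in seq_len(nq)) GG[q, ] <- as.vector(outer(dB[q, ], dB[q, ]))
    vals <- W %*% GG
  } else {
    ev <- hbasis_eval(basis, quad$bary)
    dBl <- ev$dlam                                       # nq x nm x 3
    pts <- map_points_to_elements(mesh, quad$points)
    sig <- conductivity_values(conductivity, mesh, pts,
                               elem = rep(seq_len(nt), each = nq))  # (nt*nq) x 3
    s11 <- matrix(sig[, 1L], nt, nq, byrow = TRUE)
    s12 <- matrix(sig[, 2L], nt, nq, byrow = TRUE)
    s22 <- matrix(sig[, 3L], nt, nq, byrow = TRUE)
    bad <- s11 <= 0 | s22 <= 0 | (s11 * s22 - s12^2) <= 0
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("conductivity tensor not SPD in element %d (quad point %d)",
                   w[1L], w[2L]))
    }
    gl <- geo$grad_lambda
    wq <- matrix(quad$weights, nt, nq, byrow = TRUE) * geo$area2
    vals <- matrix(0, nt, nm * nm)
    GG <- array(0, c(nq, nm * nm, 6L))  # pairs (1,1),(1,2),(1,3),(2,2),(2,3),(3,3)
    pair <- rbind(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L), c(3L, 3L))
    for (k in seq_len(6L)) {
      i <- pair[k, 1L]; j <- pair[k, 2L]
      for (q in seq_len(nq)) {
        GG[q, , k] <- as.vector(outer(dBl[q, , i], dBl[q, , j]))
      }
    }
    for (k in seq_len(6L)) {
      i <- pair[k, 1L]; j <- pair[k, 2L]
      cij <- s11 * (gl[, i, 1L] * gl[, j, 1L]) +
        s12 * (gl[, i, 1L] * gl[, j, 2L] + gl[, i, 2L] * gl[, j, 1L]) +
        s22 * (gl[, i, 2L] * gl[, j, 2L])
      vals <- vals + (wq * cij) %*% GG[, , k]
      if (i != j) {
        cji <- s11 * (gl[, j, 1L] * gl[, i, 1L]) +
          s12 * (gl[, j, 1L] * gl[, i, 2L] + gl[, j, 2L] * gl[, i, 1L]) +
          s22 * (gl[, j, 2L] * gl[, i, 2L])
        # transpose block: swap the roles of the two modes
        GGt <- GG[, , k]
        dim(GGt) <- c(nq, nm, nm)
        GGt <- aperm(GGt, c(1L, 3L, 2L))
        dim(GGt) <- c(nq, nm * nm)
        vals <- vals + (wq * cji) %*% GGt
      }
    }
  }
  s <- dofmap$elem_signs
  ss <- s[, rep(seq_len(nm), nm)] * s[, rep(seq_len(nm), each = nm)]
  A <- scatter_sparse(dofmap$elem_dofs, dofmap$elem_dofs, ss * vals,
                      dofmap$n_dof, dofmap$n_dof)
  Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
}

# ---------------------------------------------------------------------------
# Nodal <-> hierarchical change of basis

#' Element transforms between nodal values and hierarchical coefficients
#'
#' Builds the global sparse operator taking the values of a continuous
#' piecewise-degree-p-tilde function at all global nodal points to the
#' hierarchical coefficients of the same function (the interpolation
#' operator's change of basis, performed locally on each element). The
#' per-element transform is the inverse of the local hierarchical
#' generalised Vandermonde at the nodal points; exact for all polynomials
#' of degree at most p-tilde.
#'
#' @param mesh an `hp_mesh`.
#' @param dofmap_pt degree-p-tilde `hp_dofmap`.
#' @param ndmap matching `hp_nodalmap`.
#' @return sparse matrix (hierarchical DOFs x nodal points).
#' @export
nodal_to_hierarchical_matrix <- function(mesh, dofmap_pt, ndmap) {
  basis <- dofmap_pt$basis
  nb <- ndmap$nodal_basis
  if (mesh$dimension == 1L) {
    Phi <- hbasis_eval(basis, nb$points[, 1L])$val
  } else {
    Phi <- hbasis_eval(basis, nb$bary)$val
  }
  Tref <- solve(Phi)                       # coeffs = Tref %*% values
  nloc <- nrow(Tref)
  # keep exactly one owning element per global hierarchical dof
  ed <- dofmap_pt$elem_dofs
  own <- !duplicated(as.vector(ed))
  dim(own) <- dim(ed)
  nt <- mesh$n_elements
  rows <- ed[, rep(seq_len(nloc), nloc)]
  cols <- ndmap$elem_nodes[, rep(seq_len(nloc), each = nloc)]
  # local transform rows are sign-corrected: T_e = diag(s) %*% Tref
  svals <- dofmap_pt$elem_signs[, rep(seq_len(nloc), nloc)]
  vals <- svals * matrix(as.vector(Tref), nt, nloc * nloc, byrow = TRUE)
  keep <- as.vector(own[, rep(seq_len(nloc), nloc)])
  Matrix::sparseMatrix(i = as.vector(rows)[keep], j = as.vector(cols)[keep],
                       x = as.vector(vals)[keep],
                       dims = c(dofmap_pt$n_dof, ndmap$n_nodes))
}

#' Change nodal values to hierarchical coefficients
#'
#' @param transform matrix from [nodal_to_hierarchical_matrix()].
#' @param values values at the global nodal points.
#' @return hierarchical coefficient vector of the interpolant.
#' @export
nodal_to_hierarchical <- function(transform, values) {
  as.numeric(transform %*% values)
}

#' Evaluation matrix of a hierarchical space at the nodal points
#'
#' Sparse operator taking degree-p hierarchical coefficients to values at
#' the global degree-p-tilde nodal points (used every time step to feed the
#' membrane potential to the pointwise cell models).
#'
#' @param mesh an `hp_mesh`.
#' @param dofmap degree-p `hp_dofmap`.
#' @param ndmap an `hp_nodalmap`.
#' @export
nodal_evaluation_matrix <- function(mesh, dofmap, ndmap) {
  basis <- dofmap$basis
  nb <- ndmap$nodal_basis
  if (mesh$dimension == 1L) {
    B <- hbasis_eval(basis, nb$points[, 1L])$val      # nloc_nodes x nm
  } else {
    B <- hbasis_eval(basis, nb$bary)$val
  }
  nm <- ncol(B); nl <- nrow(B)
  en <- ndmap$elem_nodes
  own <- !duplicated(as.vector(en))
  dim(own) <- dim(en)
  nt <- mesh$n_elements
  rows <- en[, rep(seq_len(nl), nm)]
  cols <- dofmap$elem_dofs[, rep(seq_len(nm), each = nl)]
  svals <- dofmap$elem_signs[, rep(seq_len(nm), each = nl)]
  vals <- svals * matrix(as.vector(B), nt, nl * nm, byrow = TRUE)
  keep <- as.vector(own[, rep(seq_len(nl), nm)])
  Matrix::sparseMatrix(i = as.vector(rows)[keep], j = as.vector(cols)[keep],
                       x = as.vector(vals)[keep],
                       dims = c(ndmap$n_nodes, dofmap$n_dof))
}

# ---------------------------------------------------------------------------
# Right-hand sides

#' Matrix-based right-hand side
#'
#' Computes \eqn{I_j = (\iota I_{total}, \phi_j)} for every degree-p test
#' function as the single product of the nested rectangular mass matrix
#' with the hierarchical coefficients of the interpolated current.
#'
#' @param Mtilde rectangular mass from [assemble_mass()].
#' @param coeffs degree-p-tilde hierarchical coefficients of the current.
#' @export
rhs_matrix_based <- function(Mtilde, coeffs) {
  if (ncol(Mtilde) != length(coeffs)) stop("dimension mismatch")
  as.numeric(Mtilde %*% coeffs)
}

#' Direct quadrature right-hand side (oracle assembler)
#'
#' Integrates the interpolated current against each degree-p test function
#' element by element with Gauss quadrature: the computationally more
#' demanding alternative to matrix-based assembly, kept as an independent
#' correctness oracle.
#'
#' @param mesh an `hp_mesh`.
#' @param dofmap degree-p `hp_dofmap`.
#' @param ndmap `hp_nodalmap` carrying the current's nodal representation.
#' @param nodal_values current values at the global nodal points.
#' @export
rhs_quadrature <- function(mesh, dofmap, ndmap, nodal_values) {
  basis <- dofmap$basis
  nb <- ndmap$nodal_basis
  quad <- gauss_rule(mesh$dimension, basis$degree + nb$degree)
  geo <- element_geometry(mesh)
  if (mesh$dimension == 1L) {
    B <- hbasis_eval(basis, quad$points[, 1L])$val
    Cq <- nodal_eval(nb, quad$points[, 1L])
    scale <- geo$h
  } else {
    B <- hbasis_eval(basis, quad$bary)$val
    Cq <- nodal_eval(nb, quad$bary)
    scale <- geo$area2
  }
  Vn <- matrix(nodal_values[ndmap$elem_nodes], nrow = mesh$n_elements)
  Fq <- Vn %*% t(Cq)                                  # current at (e, q)
  wq <- matrix(quad$weights, mesh$n_elements, length(quad$weights), byrow = TRUE)
  contrib <- (Fq * wq * scale) %*% B * dofmap$elem_signs
  rhs <- numeric(dofmap$n_dof)
  agg <- rowsum(as.vector(contrib), group = as.vector(dofmap$elem_dofs))
  rhs[as.integer(rownames(agg))] <- agg
  rhs
}

# ---------------------------------------------------------------------------
# Point evaluation (1D general; 2D via provided element ids)

# Sparse evaluation/derivative matrices of a 1D hierarchical field at
# arbitrary points.
point_evaluation_matrix_1d <- function(mesh, dofmap, x, derivative = FALSE) {
  xv <- mesh$vertices[, 1L]
  brk <- xv[mesh$elements[1L, 1L]]
  lefts <- xv[mesh$elements[, 1L]]
  rights <- xv[mesh$elements[, 2L]]
  el <- findInterval(x, c(lefts, rights[length(rights)]), rightmost.closed = TRUE)
  el[el < 1L] <- 1L; el[el > mesh$n_elements] <- mesh$n_elements
  h <- rights[el] - lefts[el]
  xi <- (x - lefts[el]) / h
  ev <- hbasis_eval(dofmap$basis, xi)
  B <- if (derivative) ev$dx / h else ev$val
  nm <- ncol(B)
  Matrix::sparseMatrix(i = rep(seq_along(x), nm),
                       j = as.vector(dofmap$elem_dofs[el, ]),
                       x = as.vector(B * dofmap$elem_signs[el, , drop = FALSE]),
                       dims = c(length(x), dofmap$n_dof))
}

#' L2 projection into a hierarchical space
#'
#' Projects a function into the degree-p space by solving the mass system
#' with a quadrature right-hand side; recovers any degree-at-most-p
#' polynomial exactly (Galerkin orthogonality).
#'
#' @param mesh an `hp_mesh`.
#' @param dofmap an `hp_dofmap`.
#' @param f vectorised function of position (matrix input, one row per
#'   point).
#' @param exactness quadrature exactness used for the right-hand side.
#' @export
project_l2 <- function(mesh, dofmap, f, exactness = 2L * dofmap$basis$degree + 2L) {
  basis <- dofmap$basis
  quad <- gauss_rule(mesh$dimension, exactness)
  geo <- element_geometry(mesh)
  pts <- map_points_to_elements(mesh, quad$points)
  fq <- matrix(f(pts), mesh$n_elements, length(quad$weights), byrow = TRUE)
  if (mesh$dimension == 1L) {
    B <- hbasis_eval(basis, quad$points[, 1L])$val
    scale <- geo$h
  } else {
    B <- hbasis_eval(basis, quad$bary)$val
    scale <- geo$area2
  }
  wq <- matrix(quad$weights, mesh$n_elements, length(quad$weights), byrow = TRUE)
  contrib <- (fq * wq * scale) %*% B * dofmap$elem_signs
  rhs <- numeric(dofmap$n_dof)
  agg <- rowsum(as.vector(contrib), group = as.vector(dofmap$elem_dofs))
  rhs[as.integer(rownames(agg))] <- agg
  M <- assemble_mass_square(mesh, dofmap)
  as.numeric(Matrix::solve(M, rhs))
}
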