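# Global degree-of-freedom maps for the hierarchical spaces S_hp and the
# nodal (cell-state) spaces, plus DOF counting.
#
# Global numbering: all vertex modes first (so the linear block is a leading
# principal submatrix, which the ILU preconditioner extracts), then all edge
# modes grouped by edge and ascending degree, then interior modes grouped by
# element.

interior_mode_count <- function(p, dimension = 2L) {
  if (dimension == 1L) return(max(0L, p - 1L))
  as.integer((p - 1L) * (p - 2L) / 2L)
}

#' Hierarchical DOF count from entity counts
#'
#' Evaluates \eqn{N = V + (p-1)E + i(p)T} with \eqn{i(p) = (p-1)(p-2)/2}
#' interior modes per triangle (0, 0, 1, 3 for p = 1..4). For 1D meshes,
#' `E` is the number of elements and `T` must be 0.
#'
#' @param p basis degree.
#' @param n_vertices,n_edges,n_triangles entity counts.
#' @export
dof_count_formula <- function(p, n_vertices, n_edges, n_triangles = 0) {
  n_vertices + (p - 1) * n_edges + interior_mode_count(p) * n_triangles
}

#' Build the hierarchical degree-of-freedom map
#'
#' @param mesh an `hp_mesh`.
#' @param p basis degree (the solver supports 1..4; up to 6 is available to
#'   carry the nodal cell-state degree on the trial side).
#' @return object of class `hp_dofmap` with the global index and orientation
#'   sign of every (element, local mode) pair.
#' @export
dof_map <- function(mesh, p) {
  p <- as.integer(p)
  V <- mesh$n_vertices
  nt <- mesh$n_elements
  if (mesh$dimension == 1L) {
    basis <- hierarchical_basis_interval(p)
    nb_loc <- basis$n_modes
    n_dof <- V + (p - 1L) * nt
    elem_dofs <- matrix(0L, nt, nb_loc)
    elem_dofs[, 1:2] <- mesh$elements
    if (p >= 2L) {
      for (d in 2:p) {
        elem_dofs[, d + 1L] <- V + (seq_len(nt) - 1L) * (p - 1L) + (d - 1L)
      }
    }
    elem_signs <- matrix(1, nt, nb_loc)
  } else {
    basis <- hierarchical_basis_triangle(p)
    nb_loc <- basis$n_modes
    E <- mesh$n_edges
    ip <- interior_mode_count(p)
    n_dof <- V + (p - 1L) * E + ip * nt
    elem_dofs <- matrix(0L, nt, nb_loc)
    elem_signs <- matrix(1, nt, nb_loc)
    modes <- basis$modes
    int_seq <- cumsum(modes$kind == "interior")
    for (k in seq_len(nb_loc)) {
      kind <- modes$kind[k]; d <- modes$degree[k]
      if (kind == "vertex") {
        elem_dofs[, k] <- mesh$elements[, modes$entity[k]]
      } else if (kind == "edge") {
        e <- modes$entity[k]
        g <- mesh$elem_edges[, e]
        elem_dofs[, k] <- V + (g - 1L) * (p - 1L) + (d - 1L)
        if (d %% 2L == 1L) {
          elem_signs[mesh$elem_flip[, e], k] <- -1
        }
      } else {
        j <- int_seq[k]
        elem_dofs[, k] <- V + E * (p - 1L) + (seq_len(nt) - 1L) * ip + j
      }
    }
  }
  structure(list(mesh = mesh, p = p, basis = basis, n_dof = n_dof,
                 n_vertices = V, elem_dofs = elem_dofs, elem_signs = elem_signs),
            class = "hp_dofmap")
}

#' @export
print.hp_dofmap <- function(x, ...) {
  cat(sprintf("Hierarchical dof map: p = %d, %d DOFs (%d vertex modes)\n",
              x$p, x$n_dof, x$n_vertices))
  invisible(x)
}

#' Count hierarchical degrees of freedom on a mesh
#'
#' @inheritParams dof_map
#' @export
count_dofs <- function(mesh, p) {
  if (p < 1L || p > 4L) stop("degree outside supported range (1..4)")
  if (mesh$dimension == 1L) {
    dof_count_formula(p, mesh$n_vertices, mesh$n_elements, 0L)
  } else {
    dof_count_formula(p, mesh$n_vertices, mesh$n_edges, mesh$n_elements)
  }
}

#' Vertex-mode (linear block) global indices
#'
#' The global indices of the vertex modes; under the nested numbering these
#' are a prefix, and the corresponding principal submatrix of the system
#' matrix is the linear-basis block used to build the ILU preconditioner.
#'
#' @param dofmap an `hp_dofmap`.
#' @export
linear_block_indices <- function(dofmap) seq_len(dofmap$n_vertices)

#' Indices of degree-p modes inside a degree-p-tilde numbering
#'
#' For nested hierarchical spaces \eqn{S_{hp} \subset S_{h\tilde p}}, maps
#' every global DOF of the degree-p map to its global index in the
#' degree-p-tilde map on the same mesh (used to select the rows of the
#' nested rectangular mass matrix).
#'
#' @param dofmap_p,dofmap_pt dof maps on the same mesh, degrees `p <= pt`.
#' @export
shared_mode_indices <- function(dofmap_p, dofmap_pt) {
  p <- dofmap_p$p; pt <- dofmap_pt$p
  if (pt < p) stop("the second map must have degree >= the first")
  mesh <- dofmap_p$mesh
  V <- mesh$n_vertices
  idx <- integer(dofmap_p$n_dof)
  idx[seq_len(V)] <- seq_len(V)
  if (p >= 2L) {
    if (mesh$dimension == 1L) {
      nt <- mesh$n_elements
      for (d in 2:p) {
        idx[V + (seq_len(nt) - 1L) * (p - 1L) + (d - 1L)] <-
          V + (seq_len(nt) - 1L) * (pt - 1L) + (d - 1L)
      }
    } else {
      E <- mesh$n_edges; nt <- mesh$n_elements
      for (d in 2:p) {
        idx[V + (seq_len(E) - 1L) * (p - 1L) + (d - 1L)] <-
          V + (seq_len(E) - 1L) * (pt - 1L) + (d - 1L)
      }
      ip <- interior_mode_count(p); ipt <- interior_mode_count(pt)
      if (ip > 0L) {
        for (j in seq_len(ip)) {
          idx[V + E * (p - 1L) + (seq_len(nt) - 1L) * ip + j] <-
            V + E * (pt - 1L) + (seq_len(nt) - 1L) * ipt + j
        }
      }
    }
  }
  idx
}

# ---------------------------------------------------------------------------
# Nodal-point global numbering for the cell-state field

#' Global nodal-point map for the degree-p-tilde cell-state field
#'
#' Numbers the Gauss-Lobatto-type nodal points globally (vertices, then
#' edge points in global edge orientation, then per-element interior
#' points) and records, per element, the global id of each local nodal
#' point. Cell-state variables live at these points.
#'
#' @param mesh an `hp_mesh`.
#' @param p_tilde nodal degree.
#' @return object of class `hp_nodalmap` with `points` (global coordinates),
#'   `elem_nodes` (element-local to global ids) and the underlying
#'   `nodal_basis`.
#' @export
nodal_map <- function(mesh, p_tilde) {
  pt <- as.integer(p_tilde)
  V <- mesh$n_vertices
  nt <- mesh$n_elements
  nb <- nodal_points(mesh$dimension, pt)
  if (mesh$dimension == 1L) {
    n_nodes <- V + (pt - 1L) * nt
    nloc <- pt + 1L
    elem_nodes <- matrix(0L, nt, nloc)
    elem_nodes[, 1:2] <- mesh$elements
    if (pt >= 2L) {
      elem_nodes[, 3:nloc] <- V + outer((seq_len(nt) - 1L) * (pt - 1L),
                                        seq_len(pt - 1L), `+`)
    }
    pts <- numeric(n_nodes)
    pts[seq_len(V)] <- mesh$vertices[, 1L]
    x1 <- mesh$vertices[mesh$elements[, 1L], 1L]
    x2 <- mesh$vertices[mesh$elements[, 2L], 1L]
    ref <- nb$points[, 1L]
    for (j in seq_len(pt - 1L)) {
      pts[elem_nodes[, j + 2L]] <- x1 + (x2 - x1) * ref[j + 2L]
    }
    points <- matrix(pts, ncol = 1L)
  } else {
    E <- mesh$n_edges
    n_int <- interior_mode_count(pt)  # (pt-1)(pt-2)/2 interior points
    n_nodes <- V + (pt - 1L) * E + n_int * nt
    cl <- nb$classify
    nloc <- nrow(cl)
    elem_nodes <- matrix(0L, nt, nloc)
    edges <- local_edges()
    for (k in seq_len(nloc)) {
      if (cl$kind[k] == "vertex") {
        elem_nodes[, k] <- mesh$elements[, cl$entity[k]]
      } else if (cl$kind[k] == "edge") {
        e <- cl$entity[k]
        g <- mesh$elem_edges[, e]
        m <- cl$index[k]
        # position measured from the global low-index vertex
        mg <- ifelse(mesh$elem_flip[, e], pt - m, m)
        elem_nodes[, k] <- V + (g - 1L) * (pt - 1L) + mg
      } else {
        elem_nodes[, k] <- V + E * (pt - 1L) + (seq_len(nt) - 1L) * n_int + cl$index[k]
      }
    }
    points <- matrix(0, n_nodes, 2L)
    v1 <- mesh$vertices[mesh$elements[, 1L], , drop = FALSE]
    v2 <- mesh$vertices[mesh$elements[, 2L], , drop = FALSE]
    v3 <- mesh$vertices[mesh$elements[, 3L], , drop = FALSE]
    for (k in seq_len(nloc)) {
      lam <- nb$bary[k, ]
      points[elem_nodes[, k], ] <- lam[1L] * v1 + lam[2L] * v2 + lam[3L] * v3
    }
  }
  structure(list(mesh = mesh, p_tilde = pt, nodal_basis = nb,
                 n_nodes = n_nodes, elem_nodes = elem_nodes, points = points),
            class = "hp_nodalmap")
}

#' @export
print.hp_nodalmap <- function(x, ...) {
  cat(sprintf("Nodal map: p-tilde = %d, %d nodal points\n", x$p_tilde, x$n_nodes))
  invisible(x)
}
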