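# Linear solvers for the semi-implicit system: ILU(0)-preconditioned
# conjugate gradients with the preconditioner built from the linear-basis
# block (higher-order modes get their diagonal), and a sparse Cholesky
# alternative.

as_csr_parts <- function(K) {
  Kg <- methods::as(methods::as(K, "generalMatrix"), "CsparseMatrix")
  list(p = Kg@p, i = Kg@i, x = Kg@x, n = nrow(Kg))
}

#' Build the linear-block ILU preconditioner
#'
#' Factors the leading principal (vertex-mode) block of a symmetric system
#' matrix with ILU(0); the remaining modes are preconditioned by their
#' diagonal. Built once per (mesh, p, dt) and reused every time step.
#'
#' @param K symmetric sparse system matrix with nested numbering (vertex
#'   modes first).
#' @param nb size of the linear block (number of vertex modes).
#' @return opaque solver state for [ilu_pcg_solve()].
#' @export
ilu_pcg_setup <- function(K, nb) {
  parts <- as_csr_parts(K)
  K11 <- as_csr_parts(K[seq_len(nb), seq_len(nb), drop = FALSE])
  fac <- ilu0_factor_csr(K11$p, K11$i, K11$x, nb)
  dk <- Matrix::diag(K)
  diag_rest <- if (parts$n > nb) dk[(nb + 1L):parts$n] else numeric(0)
  list(K = parts, nb = nb, Lp = K11$p, Li = K11$i, Lx = fac$lu,
       Ldiag = fac$diag, diag_rest = diag_rest)
}

#' Solve with ILU-preconditioned conjugate gradients
#'
#' @param setup solver state from [ilu_pcg_setup()].
#' @param rhs right-hand side.
#' @param x0 initial guess.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return solution vector with attribute `"iterations"`.
#' @export
ilu_pcg_solve <- function(setup, rhs, x0 = NULL, tol = 1e-8, maxit = 1000L) {
  if (is.null(x0)) x0 <- numeric(length(rhs))
  out <- pcg_ilu_csr(setup$K$p, setup$K$i, setup$K$x, rhs, x0, tol,
                     as.integer(maxit), setup$nb, setup$Lp, setup$Li,
                     setup$Lx, setup$Ldiag, setup$diag_rest)
  structure(out$x, iterations = out$iterations, relres = out$relres)
}

#' One-shot linear-block ILU-PCG solve
#'
#' Convenience form of the solver used inside the time loop: conjugate
#' gradients on `K x = rhs` preconditioned with the ILU(0) factorisation
#' of the portion of the system matrix corresponding to the linear basis
#' functions (for p = 1 that is the whole matrix).
#'
#' @param K symmetric positive definite sparse matrix.
#' @param rhs right-hand side.
#' @param dofmap the `hp_dofmap` of the system (identifies the linear
#'   block), or an integer giving the linear-block size.
#' @param tol relative residual tolerance.
#' @param ... passed to [ilu_pcg_solve()].
#' @export
ilu_linear_block_pcg <- function(K, rhs, dofmap, tol = 1e-8, ...) {
  nb <- if (is.numeric(dofmap)) as.integer(dofmap) else dofmap$n_vertices
  setup <- ilu_pcg_setup(K, nb)
  ilu_pcg_solve(setup, rhs, tol = tol, ...)
}
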