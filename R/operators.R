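# Sparse constant-coefficient operators on tf_grid.
#
# All implicit solves use the finite-volume (flux) form: K is the symmetric
# positive-semidefinite stiffness matrix with K = -W L, where L is the
# node-centred Laplacian with zero-flux (or periodic) closures and W the
# diagonal of trapezoid cell volumes.  Discrete conservation (column sums of
# K are zero) and SPD factorizations both follow from this form.

.stiffness_1d <- function(n, h, periodic) {
  if (periodic) {
    i <- c(seq_len(n), seq_len(n), seq_len(n))
    j <- c(seq_len(n), c(2:n, 1L), c(n, 1:(n - 1L)))
    x <- c(rep(2, n), rep(-1, 2 * n)) / h
  } else {
    deg <- c(1, rep(2, n - 2L), 1)
    i <- c(seq_len(n), 1:(n - 1L), 2:n)
    j <- c(seq_len(n), 2:n, 1:(n - 1L))
    x <- c(deg, rep(-1, 2 * (n - 1L))) / h
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

.weights_1d <- function(n, h, periodic) {
  w <- rep(h, n)
  if (!periodic) w[c(1, n)] <- h / 2
  w
}

# kron chain so that axis 1 is the fastest-varying index (R column-major)
.kron_axes <- function(mats) {
  out <- mats[[1]]
  for (a in seq_along(mats)[-1]) out <- Matrix::kronecker(mats[[a]], out)
  out
}

#' Sparse stiffness matrix of a grid
#'
#' Returns `K = -W %*% L` for the node-centred Laplacian with natural
#' (zero-flux) closures on non-periodic axes and wrap-around on periodic
#' axes; `K` is symmetric positive semidefinite and has zero column sums.
#' @param g a `tf_grid`.
#' @return a `dgCMatrix` of dimension `prod(g$n)`.
#' @keywords internal
grid_stiffness <- function(g) {
  Ks <- lapply(seq_len(g$ndim), function(a) .stiffness_1d(g$n[a], g$h[a], g$periodic[a]))
  Ws <- lapply(seq_len(g$ndim), function(a)
    Matrix::Diagonal(x = .weights_1d(g$n[a], g$h[a], g$periodic[a])))
  out <- NULL
  for (a in seq_len(g$ndim)) {
    mats <- Ws
    mats[[a]] <- Ks[[a]]
    term <- .kron_axes(mats)
    out <- if (is.null(out)) term else out + term
  }
  out
}

.chol_spd <- function(M) Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)

#' Factorized Helmholtz solver `(a - b * Laplacian) u = r`
#'
#' `a` may be a scalar or a field array (e.g. `1/dt + static drag`); `b` is a
#' scalar diffusivity.  Dirichlet values are imposed on the nodes of
#' `dirichlet_mask`; all remaining non-periodic boundary nodes get the
#' natural zero-flux condition.
#'
#' @param g `tf_grid`.
#' @param a_diag scalar or array: the reaction coefficient.
#' @param b_coef scalar: the diffusion coefficient.
#' @param dirichlet_mask logical array marking strongly imposed nodes, or NULL.
#' @return a solver object with a `$solve(r, bvals)` closure returning the
#'   full-shape solution array (`bvals` supplies the Dirichlet values and
#'   defaults to zero).
#' @keywords internal
helmholtz_factor <- function(g, a_diag, b_coef, dirichlet_mask = NULL) {
  N <- prod(g$n)
  W <- as.vector(grid_weights(g))
  avec <- if (length(a_diag) == 1L) rep(a_diag, N) else as.vector(a_diag)
  M <- Matrix::Diagonal(x = W * avec) + b_coef * grid_stiffness(g)
  if (is.null(dirichlet_mask)) {
    unk <- rep(TRUE, N)
  } else {
    unk <- !as.vector(dirichlet_mask)
  }
  M_II <- M[unk, unk, drop = FALSE]
  M_IB <- if (all(unk)) NULL else M[unk, !unk, drop = FALSE]
  ch <- .chol_spd(M_II)
  gn <- g$n
  solve_fn <- function(r, bvals = NULL) {
    rhs <- (W * as.vector(r))[unk]
    out <- numeric(N)
    if (!is.null(M_IB)) {
      bv <- if (is.null(bvals)) numeric(sum(!unk)) else as.vector(bvals)[!unk]
      rhs <- rhs - as.vector(M_IB %*% bv)
      out[!unk] <- bv
    }
    out[unk] <- as.vector(Matrix::solve(ch, rhs))
    array(out, dim = gn)
  }
  list(solve = solve_fn, unknown = unk)
}

#' Factorized Poisson solver for pressure-type problems `-Laplacian psi = r`
#'
#' With a Dirichlet mask (outlet), psi is pinned there to zero; without one
#' (closed domains) the operator is singular and the solver pins one node
#' and removes the weighted mean of the right-hand side.
#' @inheritParams helmholtz_factor
#' @keywords internal
poisson_factor <- function(g, dirichlet_mask = NULL) {
  N <- prod(g$n)
  W <- as.vector(grid_weights(g))
  K <- grid_stiffness(g)
  pinned <- is.null(dirichlet_mask)
  if (pinned) {
    unk <- rep(TRUE, N); unk[1L] <- FALSE
  } else {
    unk <- !as.vector(dirichlet_mask)
  }
  K_II <- K[unk, unk, drop = FALSE]
  ch <- .chol_spd(K_II)
  gn <- g$n
  solve_fn <- function(r) {
    rv <- as.vector(r)
    if (pinned) rv <- rv - sum(W * rv) / sum(W)   # compatibility projection
    rhs <- (W * rv)[unk]
    out <- numeric(N)
    out[unk] <- as.vector(Matrix::solve(ch, rhs))
    array(out, dim = gn)
  }
  list(solve = solve_fn, unknown = unk)
}

#' Factorized semi-implicit Cahn-Hilliard operator
#'
#' The fourth-order phase update `phi/dt + tau*lam*Lap^2 phi - tau*S*Lap phi`
#' assembled in weighted symmetric form
#' `M = W/dt + tau*lam*K W^-1 K + tau*S*K` (SPD, all-natural boundaries:
#' both `n.grad(phi) = 0` and `n.grad(Lap phi) = 0` are built in through the
#' flux-form closures of `K` applied twice).
#' @param g `tf_grid`.
#' @param dt time step.
#' @param tau phase relaxation parameter.
#' @param lam mixing energy density.
#' @param S stabilization constant (splitting of the double-well term).
#' @return list with the factorization and the pieces needed to build
#'   right-hand sides (`K`, `W`).
#' @keywords internal
ch_factor <- function(g, dt, tau, lam, S) {
  W <- as.vector(grid_weights(g))
  K <- grid_stiffness(g)
  Winv <- Matrix::Diagonal(x = 1 / W)
  M <- Matrix::Diagonal(x = W / dt) + (tau * lam) * (K %*% Winv %*% K) + (tau * S) * K
  ch <- .chol_spd(M)
  gn <- g$n
  list(
    K = K, W = W, dt = dt, tau = tau, lam = lam, S = S,
    solve = function(rhs_w) array(as.vector(Matrix::solve(ch, as.vector(rhs_w))), dim = gn)
  )
}

# union of boundary-face node masks for a set of face names
.faces_mask <- function(g, faces) {
  out <- array(FALSE, dim = g$n)
  for (f in faces) {
    axis <- match(substr(f, 1, 1), c("x", "y", "z"))
    side <- substr(f, 2, 3)
    if (g$periodic[axis]) next
    out <- out | .face_mask(g, axis, side)
  }
  out
}
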