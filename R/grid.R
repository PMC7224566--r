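#' Uniform structured grids for phase-field simulations
#'
#' A grid is node-centred and axis-aligned: node `(1,1[,1])` sits at the
#' domain minimum corner.  Non-periodic axes include both end nodes
#' (spacing `L/(n-1)`); periodic axes drop the duplicate node
#' (spacing `L/n`).  Fields living on a grid are plain R arrays with
#' `dim(a) == g$n`.
#'
#' @param n integer vector of node counts, length 2 or 3.
#' @param length numeric vector of axis extents (same length as `n`).
#' @param origin numeric vector of minimum-corner coordinates.
#' @param periodic logical vector of per-axis periodicity flags.
#' @return an object of class `tf_grid` with elements `n`, `length`,
#'   `origin`, `periodic`, `h` (spacings), `ndim`, and `coords`
#'   (list of per-axis node coordinates).
#' @examples
#' g <- grid_create(c(16, 8), length = c(6, 2))
#' g$h
#' @export
grid_create <- function(n, length, origin = rep(0, base::length(n)),
                        periodic = rep(FALSE, base::length(n))) {
  n <- as.integer(n)
  nd <- base::length(n)
  stopifnot(nd %in% c(2L, 3L),
            base::length(length) == nd,
            base::length(origin) == nd,
            base::length(periodic) == nd,
            all(length > 0))
  if (any(n < 4L)) stop("grids need at least 4 nodes per axis")
  h <- ifelse(periodic, length / n, length / (n - 1L))
  coords <- lapply(seq_len(nd), function(a) origin[a] + h[a] * (seq_len(n[a]) - 1))
  structure(list(n = n, length = length, origin = origin,
                 periodic = as.logical(periodic), h = h, ndim = nd,
                 coords = coords),
            class = "tf_grid")
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf("<tf_grid> %dD  %s nodes  h = %s  periodic = %s\n",
              x$ndim, paste(x$n, collapse = "x"),
              paste(signif(x$h, 4), collapse = ", "),
              paste(x$periodic, collapse = ",")))
  invisible(x)
}

#' Coordinate arrays of a grid
#'
#' @param g a `tf_grid`.
#' @return list of `ndim` arrays, each of full grid shape, holding the
#'   x, y (and z) node coordinates.
#' @export
grid_mesh <- function(g) {
  lapply(seq_len(g$ndim), function(a) {
    perm <- seq_len(g$ndim)
    perm[1] <- a; perm[a] <- 1L
    arr <- array(g$coords[[a]], dim = g$n[perm])
    if (a == 1L) arr else aperm(arr, order(perm))
  })
}

#' Trapezoid quadrature weights (finite-volume node cells)
#'
#' Half-width cells at non-periodic ends; product over axes.  Summing
#' `field * grid_weights(g)` integrates the field over the domain.
#' @param g a `tf_grid`.
#' @return array of full grid shape.
#' @export
grid_weights <- function(g) {
  w1 <- lapply(seq_len(g$ndim), function(a) {
    w <- rep(g$h[a], g$n[a])
    if (!g$periodic[a]) w[c(1, g$n[a])] <- g$h[a] / 2
    w
  })
  out <- w1[[1]]
  for (a in seq_len(g$ndim)[-1]) out <- outer(out, w1[[a]])
  array(out, dim = g$n)
}

#' Integrate a field over the domain by trapezoid quadrature
#' @param field array on `g`.
#' @param g a `tf_grid`.
#' @return scalar integral.
#' @export
field_integral <- function(field, g) sum(field * grid_weights(g))

#' Constant field on a grid
#' @param g a `tf_grid`.
#' @param value scalar fill value.
#' @export
field_const <- function(g, value = 0) array(value, dim = g$n)

# ---- axis permutation helpers -------------------------------------------

# move `axis` to the first dimension and flatten the rest into columns
.axis_to_front <- function(a, axis) {
  d <- dim(a)
  nd <- length(d)
  if (axis != 1L) {
    perm <- seq_len(nd); perm[1] <- axis; perm[axis] <- 1L
    a <- aperm(a, perm)
    d <- d[perm]
  }
  dim(a) <- c(d[1], prod(d[-1]))
  list(m = a, d = d)
}

.axis_from_front <- function(m, d, axis) {
  dim(m) <- d
  if (axis != 1L) {
    nd <- length(d)
    perm <- seq_len(nd); perm[1] <- axis; perm[axis] <- 1L
    m <- aperm(m, perm)
  }
  m
}

# ---- finite-difference derivatives --------------------------------------

#' First derivative of a field along one axis
#'
#' Second-order centred differences in the interior.  On periodic axes the
#' stencil wraps (or, with `scheme = "spectral"`, a Fourier derivative is
#' used).  On non-periodic axes the boundary rows use one-sided
#' second-order stencils.
#'
#' @param a field array.
#' @param g `tf_grid`.
#' @param axis axis index (1-based).
#' @param scheme `"central"` or `"spectral"` (spectral only on periodic axes).
#' @return array of derivative values.
#' @export
deriv1 <- function(a, g, axis, scheme = c("central", "spectral")) {
  scheme <- match.arg(scheme)
  h <- g$h[axis]
  tf <- .axis_to_front(a, axis)
  m <- tf$m
  n <- nrow(m)
  if (g$periodic[axis] && scheme == "spectral") {
    k <- .spectral_wavenumbers(n, g$length[axis])
    out <- Re(stats::mvfft(stats::mvfft(m) * (1i * k), inverse = TRUE)) / n
  } else if (g$periodic[axis]) {
    up <- m[c(2:n, 1L), , drop = FALSE]
    dn <- m[c(n, 1:(n - 1L)), , drop = FALSE]
    out <- (up - dn) / (2 * h)
  } else {
    out <- m
    out[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]) / (2 * h)
    out[1L, ] <- (-3 * m[1L, ] + 4 * m[2L, ] - m[3L, ]) / (2 * h)
    out[n, ] <- (3 * m[n, ] - 4 * m[n - 1L, ] + m[n - 2L, ]) / (2 * h)
  }
  .axis_from_front(out, tf$d, axis)
}

.spectral_wavenumbers <- function(n, L) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0   # drop the unmatched Nyquist mode
  2 * pi * k / L
}

#' Second derivative of a field along one axis
#'
#' Flux-form stencil: on non-periodic axes the end rows use the
#' zero-normal-flux (Neumann) ghost `2*(a[2]-a[1])/h^2`, matching the
#' sparse operators used by the implicit solvers, unless
#' `bc = "onesided"` which extrapolates instead.
#' @inheritParams deriv1
#' @param bc boundary handling on non-periodic axes: `"neumann"` or `"onesided"`.
#' @export
deriv2 <- function(a, g, axis, bc = c("neumann", "onesided")) {
  bc <- match.arg(bc)
  h2 <- g$h[axis]^2
  tf <- .axis_to_front(a, axis)
  m <- tf$m
  n <- nrow(m)
  if (g$periodic[axis]) {
    up <- m[c(2:n, 1L), , drop = FALSE]
    dn <- m[c(n, 1:(n - 1L)), , drop = FALSE]
    out <- (up - 2 * m + dn) / h2
  } else {
    out <- m
    out[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] - 2 * m[2:(n - 1L), , drop = FALSE] +
                            m[1:(n - 2L), , drop = FALSE]) / h2
    if (bc == "neumann") {
      out[1L, ] <- 2 * (m[2L, ] - m[1L, ]) / h2
      out[n, ] <- 2 * (m[n - 1L, ] - m[n, ]) / h2
    } else {
      out[1L, ] <- (2 * m[1L, ] - 5 * m[2L, ] + 4 * m[3L, ] - m[4L, ]) / h2
      out[n, ] <- (2 * m[n, ] - 5 * m[n - 1L, ] + 4 * m[n - 2L, ] - m[n - 3L, ]) / h2
    }
  }
  .axis_from_front(out, tf$d, axis)
}

#' Laplacian of a field (sum of per-axis second derivatives)
#' @inheritParams deriv2
#' @export
laplacian <- function(a, g, bc = "neumann") {
  out <- deriv2(a, g, 1L, bc = bc)
  for (ax in seq_len(g$ndim)[-1]) out <- out + deriv2(a, g, ax, bc = bc)
  out
}

#' Gradient of a scalar field
#' @inheritParams deriv1
#' @return list of `ndim` arrays.
#' @export
gradient <- function(a, g, scheme = "central") {
  lapply(seq_len(g$ndim), function(ax) deriv1(a, g, ax, scheme = scheme))
}

#' Divergence of a vector field
#' @param v list of `ndim` component arrays.
#' @inheritParams deriv1
#' @export
divergence <- function(v, g, scheme = "central") {
  out <- deriv1(v[[1]], g, 1L, scheme = scheme)
  for (ax in seq_len(g$ndim)[-1]) out <- out + deriv1(v[[ax]], g, ax, scheme = scheme)
  out
}

# face index helper: logical array selecting the nodes of one boundary face
.face_mask <- function(g, axis, side) {
  idx <- array(FALSE, dim = g$n)
  tf <- .axis_to_front(idx, axis)
  m <- tf$m
  m[if (side == "lo") 1L else nrow(m), ] <- TRUE
  .axis_from_front(m, tf$d, axis)
}

# list of coordinate arrays restricted to one face (full-shape arrays sliced)
.face_coords <- function(g, axis, side) {
  mesh <- grid_mesh(g)
  mask <- .face_mask(g, axis, side)
  lapply(mesh, function(cc) cc[mask])
}
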