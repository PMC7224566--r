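# Post-processing analysis helpers: connected components of a thrombus
# mask (embolization detection) and simple trajectory summaries.

#' Connected components of a logical field
#'
#' Face-adjacency flood fill on the grid (periodic axes wrap).  Used to
#' detect detached thrombus fragments (emboli) as disconnected low-phi
#' components.
#' @param mask logical array on a `tf_grid`.
#' @param g the grid.
#' @return integer array of component labels (0 outside the mask), with
#'   attribute `sizes` (cell counts per label, sorted decreasing).
#' @export
connected_components <- function(mask, g) {
  lab <- array(0L, dim = g$n)
  nd <- g$ndim
  nvec <- g$n
  strides <- cumprod(c(1L, nvec[-nd]))
  idx_all <- which(mask)
  if (!length(idx_all)) return(structure(lab, sizes = integer(0)))
  # precompute neighbour lists lazily via index arithmetic
  coord_of <- function(i) {
    i0 <- i - 1L
    out <- matrix(0L, length(i), nd)
    for (a in seq_len(nd)) {
      out[, a] <- (i0 %/% strides[a]) %% nvec[a]
    }
    out
  }
  nextlab <- 0L
  unvisited <- logical(length(lab)); unvisited[idx_all] <- TRUE
  while (any(unvisited)) {
    nextlab <- nextlab + 1L
    seedidx <- which.max(unvisited)
    frontier <- seedidx
    unvisited[seedidx] <- FALSE
    lab[seedidx] <- nextlab
    while (length(frontier)) {
      cc <- coord_of(frontier)
      nbrs <- integer(0)
      for (a in seq_len(nd)) for (s in c(-1L, 1L)) {
        c2 <- cc
        c2[, a] <- c2[, a] + s
        if (g$periodic[a]) {
          c2[, a] <- c2[, a] %% nvec[a]
          ok <- rep(TRUE, nrow(c2))
        } else {
          ok <- c2[, a] >= 0L & c2[, a] < nvec[a]
        }
        if (!any(ok)) next
        lin <- 1L + as.integer(c2[ok, , drop = FALSE] %*% strides)
        nbrs <- c(nbrs, lin)
      }
      nbrs <- unique(nbrs)
      nbrs <- nbrs[unvisited[nbrs]]
      unvisited[nbrs] <- FALSE
      lab[nbrs] <- nextlab
      frontier <- nbrs
    }
  }
  sizes <- sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
  structure(lab, sizes = sizes)
}

#' Detect detached thrombus fragments
#'
#' Components of the thrombus mask `1 - phi > threshold` beyond the
#' largest one are counted as emboli.
#' @param state `tf_state`.
#' @param threshold thrombus-mask threshold on `1 - phi`.
#' @param min_cells ignore components smaller than this many cells.
#' @return list `n_components`, `n_emboli`, `sizes`.
#' @export
detect_emboli <- function(state, threshold = 0.5, min_cells = 2L) {
  mask <- (1 - state$phi) > threshold
  lab <- connected_components(mask, state$grid)
  sizes <- attr(lab, "sizes")
  sizes <- sizes[sizes >= min_cells]
  list(n_components = length(sizes),
       n_emboli = max(0L, length(sizes) - 1L),
       sizes = sizes)
}
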