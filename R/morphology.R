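# n-dimensional binary morphology and connected components on logical
# arrays, implemented with vectorized array shifts. Kept dimension-agnostic
# so the same code serves 2D label maps and 3D surface masks.

#' Structuring-element offsets
#'
#' Integer offset matrix (one row per cell) of a discrete ball of the given
#' radius. `"box"` is the Chebyshev ball ((2r+1)^d cube), `"diamond"` the
#' city-block ball (face-adjacent cross at r = 1), `"disc"` the Euclidean
#' ball.
#'
#' @param radius non-negative integer radius in grid cells.
#' @param ndim 2 or 3.
#' @param shape one of `"box"`, `"diamond"`, `"disc"`.
#' @return integer matrix with `ndim` columns.
#' @export
struct_offsets <- function(radius, ndim = 2, shape = c("box", "diamond", "disc")) {
  shape <- match.arg(shape)
  if (radius < 0) stop("radius must be >= 0")
  ax <- seq.int(-radius, radius)
  g <- as.matrix(expand.grid(rep(list(ax), ndim)))
  keep <- switch(shape,
    box = rep(TRUE, nrow(g)),
    diamond = rowSums(abs(g)) <= radius,
    disc = rowSums(g^2) <= radius^2
  )
  m <- g[keep, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# shift a logical array by integer offset, padding with `fill`
shift_array <- function(a, offset, fill = FALSE) {
  dims <- dim(a)
  nd <- length(dims)
  out <- array(fill, dims)
  src <- vector("list", nd)
  dst <- vector("list", nd)
  for (k in seq_len(nd)) {
    o <- offset[k]
    if (o >= 0) {
      if (o >= dims[k]) return(out)
      dst[[k]] <- seq.int(1 + o, dims[k])
      src[[k]] <- seq.int(1, dims[k] - o)
    } else {
      if (-o >= dims[k]) return(out)
      dst[[k]] <- seq.int(1, dims[k] + o)
      src[[k]] <- seq.int(1 - o, dims[k])
    }
  }
  piece <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), dst, list(piece)))
  out
}

#' Binary erosion, dilation, opening, closing
#'
#' Shift-based n-d binary morphology. Cells outside the array are treated
#' as background, so erosion shrinks at the borders and dilation never
#' wraps.
#'
#' @param mask logical/numeric array (2D or 3D).
#' @param offsets structuring element from [struct_offsets()], or an
#'   integer radius (box element of that radius).
#' @return logical array of the same shape.
#' @export
binary_erode <- function(mask, offsets) {
  offsets <- as_offsets(offsets, length(dim(mask)))
  m <- mask != 0
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offsets))) {
    out <- out & shift_array(m, -offsets[i, ], fill = FALSE)
  }
  out
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, offsets) {
  offsets <- as_offsets(offsets, length(dim(mask)))
  m <- mask != 0
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift_array(m, offsets[i, ], fill = FALSE)
  }
  out
}

#' @rdname binary_erode
#' @export
binary_open <- function(mask, offsets) {
  offsets <- as_offsets(offsets, length(dim(mask)))
  binary_dilate(binary_erode(mask, offsets), offsets)
}

#' @rdname binary_erode
#' @export
binary_close <- function(mask, offsets) {
  offsets <- as_offsets(offsets, length(dim(mask)))
  binary_erode(binary_dilate(mask, offsets), offsets)
}

as_offsets <- function(x, ndim) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == ndim)
    return(x)
  }
  struct_offsets(x, ndim, "box")
}

#' Connected-component labelling (face adjacency)
#'
#' Labels connected components of a binary array under face adjacency
#' (4-connectivity in 2D, 6-connectivity in 3D) by breadth-first search
#' with a vectorized frontier.
#'
#' @param mask logical/numeric array (2D or 3D).
#' @return integer array of component ids (0 = background), with attribute
#'   `"sizes"` giving the cell count per component.
#' @export
label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  m <- mask != 0
  lab <- array(0L, dims)
  sizes <- integer(0)
  todo <- which(m)
  # strides for linear-index neighbour arithmetic
  strides <- cumprod(c(1, dims[-nd]))
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- length(sizes) + 1L
    lab[start] <- cur
    frontier <- start
    n_cells <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      coord <- arrayInd(frontier, dims)
      for (ax in seq_len(nd)) {
        for (dlt in c(-1L, 1L)) {
          ok <- coord[, ax] + dlt >= 1L & coord[, ax] + dlt <= dims[ax]
          if (!any(ok)) next
          lin <- frontier[ok] + dlt * strides[ax]
          lin <- lin[m[lin] & lab[lin] == 0L]
          if (length(lin)) {
            lab[lin] <- cur
            nxt <- c(nxt, lin)
          }
        }
      }
      frontier <- nxt
      n_cells <- n_cells + length(frontier)
    }
    sizes[cur] <- n_cells
  }
  attr(lab, "sizes") <- sizes
  lab
}

# flood fill of `open` cells reachable from the array border (face adjacency)
flood_from_border <- function(open) {
  dims <- dim(open)
  nd <- length(dims)
  open <- open != 0
  reach <- array(FALSE, dims)
  # seed: all open border cells
  for (ax in seq_len(nd)) {
    for (side in c(1L, dims[ax])) {
      idx <- lapply(dims, seq_len)
      idx[[ax]] <- side
      reach <- do.call(`[<-`, c(list(reach), idx, list(TRUE)))
    }
  }
  reach <- reach & open
  cross <- struct_offsets(1, nd, "diamond")
  repeat {
    grown <- binary_dilate(reach, cross) & open
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  reach
}
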