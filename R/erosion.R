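# Morphological surface erosion of binary lesion maps.
#
# A lesion-altering intervention (e.g. thrombolysis) is simulated by peeling
# the lesion surface inwards until a target volume is reached. One erosion
# pass removes every lesioned voxel with at least one unlesioned neighbour
# under the chosen structuring element (6-connectivity by default, the most
# conservative 3D surface definition; 26-connectivity available). Voxels
# outside the array count as unlesioned, so lesions touching the mask edge
# erode there too. Disconnected lesions are eroded as a whole.

neighbour_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  } else stop_therinf("connectivity must be 6 or 26")
}

# Shift a 3D logical array by an offset, padding with `fill`.
shift_array <- function(arr, off, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { dst[[ax]] <- seq_len(d[ax] - o) + o; src[[ax]] <- seq_len(d[ax] - o) }
    else        { dst[[ax]] <- seq_len(d[ax] + o);      src[[ax]] <- seq_len(d[ax] + o) - o }
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Boundary voxels: lesioned with >= 1 unlesioned neighbour.
boundary_voxels <- function(vox, connectivity = 6L) {
  b <- array(FALSE, dim = dim(vox))
  for (off in neighbour_offsets(connectivity)) {
    b <- b | !shift_array(vox, off, fill = FALSE)
  }
  vox & b
}

#' Erosion depth of each lesioned voxel
#'
#' Iteratively peels the lesion surface and records, for every lesioned
#' voxel, the pass number (1 = outermost shell) at which it is removed.
#' Voxels removed at pass \code{k} form the k-th surface shell; under
#' 6-connectivity the depth equals the city-block distance to the lesion
#' exterior.
#'
#' @param map a \code{lesion_map}.
#' @param connectivity 6 or 26, the structuring element.
#' @return Integer 3D array: 0 outside the lesion, otherwise the removal
#'   pass number.
#' @export
erosion_depth <- function(map, connectivity = 6L) {
  stopifnot(inherits(map, "lesion_map"))
  vox <- map$voxels
  depth <- array(0L, dim = dim(vox))
  pass <- 0L
  while (any(vox)) {
    pass <- pass + 1L
    shell <- boundary_voxels(vox, connectivity)
    if (!any(shell)) { # cannot happen for finite arrays, guard anyway
      depth[vox] <- pass
      break
    }
    depth[shell] <- pass
    vox <- vox & !shell
  }
  depth
}

# Shells as a list of column-major linear voxel indices, ascending depth;
# indices within a shell sorted ascending (the deterministic base order on
# which seeded partial-shell sampling operates).
erosion_shells <- function(map, connectivity = 6L) {
  depth <- erosion_depth(map, connectivity)
  k <- max(depth)
  lapply(seq_len(k), function(p) which(depth == p))
}

# Shared removal rule: remove whole shells while they fit, then a seeded
# uniform random subset of the next shell. Returns linear indices removed.
removal_set <- function(shells, n_remove, seed) {
  if (n_remove <= 0L) return(integer(0))
  removed <- integer(0)
  for (sh in shells) {
    if (n_remove >= length(sh)) {
      removed <- c(removed, sh)
      n_remove <- n_remove - length(sh)
      if (n_remove == 0L) break
    } else {
      part <- withr::with_seed(seed, sample(sh, n_remove))
      removed <- c(removed, part)
      n_remove <- 0L
      break
    }
  }
  removed
}

#' Erode a lesion to a target volume fraction
#'
#' Simulates a lesion-altering intervention of effect size \code{reduction}:
#' the returned lesion is a subset of the input with volume exactly
#' \code{round((1 - reduction) * V)} (round-half-up), where \code{V} is the
#' input volume. Voxels are removed in surface-inward order: full erosion
#' passes remove entire boundary shells, and the final, partial shell is
#' removed by seeded uniform random choice among the current boundary
#' voxels, making the achieved effect size exact and the draw reproducible.
#'
#' @param map a \code{lesion_map}.
#' @param reduction fractional volume reduction in [0, 1].
#' @param seed integer seed for the partial-shell draw.
#' @param connectivity 6 (default) or 26.
#' @return The eroded \code{lesion_map}.
#' @examples
#' g <- build_brain_grid(dims = c(5, 5, 5), semiaxes = c(10, 10, 10))
#' cube <- array(FALSE, dim = c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
#' m <- lesion_map(g, cube)
#' lesion_volume(erode_to_fraction(m, 0.5, seed = 1))$voxels # 14
#' @export
erode_to_fraction <- function(map, reduction, seed = 1L, connectivity = 6L) {
  stopifnot(inherits(map, "lesion_map"))
  if (!is.numeric(reduction) || length(reduction) != 1L ||
      reduction < 0 || reduction > 1)
    stop_therinf("'reduction' must be a single value in [0, 1]")
  v0 <- sum(map$voxels)
  target <- round_half_up((1 - reduction) * v0)
  n_remove <- v0 - target
  if (n_remove <= 0L) return(map)
  shells <- erosion_shells(map, connectivity)
  removed <- removal_set(shells, n_remove, seed)
  vox <- map$voxels
  vox[removed] <- FALSE
  lesion_map(map$grid, vox)
}
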