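#' Binary lesion maps on a brain grid
#'
#' A \code{lesion_map} couples a \code{\link{build_brain_grid}} grid with a
#' logical 3D array marking damaged voxels. All lesioned voxels must lie
#' inside the grid's in-brain mask.
#'
#' @param grid a \code{brain_grid}.
#' @param voxels logical/numeric 3D array over \code{grid$dims}
#'   (nonzero = damaged).
#' @return An object of class \code{lesion_map} with fields \code{grid} and
#'   \code{voxels} (logical array).
#' @export
lesion_map <- function(grid, voxels) {
  stopifnot(inherits(grid, "brain_grid"))
  if (!identical(dim(voxels), grid$dims))
    stop_therinf("lesion array dimensions do not match the grid")
  vox <- array(voxels != 0, dim = grid$dims)
  if (any(vox & !grid$mask))
    stop_therinf("lesion contains voxels outside the in-brain mask; ",
                 "use read_lesion() to clip external input")
  structure(list(grid = grid, voxels = vox), class = "lesion_map")
}

#' Read a lesion map from a NIfTI volume
#'
#' Reads a 3D NIfTI volume, binarizes it (nonzero = damaged) and clips it to
#' the grid mask. Nonzero voxels outside the mask are discarded with a
#' warning reporting their count. A higher-resolution volume whose dimensions
#' are integer multiples of the grid's is downsampled by block reduction: a
#' grid voxel is marked damaged when at least 50\% of its constituent input
#' voxels are nonzero.
#'
#' @param path path to a \code{.nii}/\code{.nii.gz} file.
#' @param grid target \code{brain_grid}.
#' @return A \code{lesion_map}.
#' @export
read_lesion <- function(path, grid) {
  if (!file.exists(path)) stop_therinf("file not found: ", path)
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) > 3L && all(dim(vol)[-(1:3)] == 1L))
    dim(vol) <- dim(vol)[1:3]
  if (length(dim(vol)) != 3L)
    stop_therinf("expected a 3D volume: ", path)
  if (!identical(dim(vol), grid$dims)) {
    fac <- dim(vol) / grid$dims
    if (any(fac != floor(fac)) || any(fac < 1))
      stop_therinf("dimension mismatch not resolvable by integer-factor ",
                   "downsampling: input ", paste(dim(vol), collapse = "x"),
                   ", grid ", paste(grid$dims, collapse = "x"))
    vol <- block_reduce(vol != 0, as.integer(fac))
  }
  vox <- array(vol != 0, dim = grid$dims)
  n_out <- sum(vox & !grid$mask)
  if (n_out > 0L) {
    warning(sprintf("read_lesion: discarded %d nonzero voxel(s) outside the grid mask", n_out),
            call. = FALSE)
    vox <- vox & grid$mask
  }
  lesion_map(grid, vox)
}

# Block reduction by integer factors; block TRUE if >= 50% of members TRUE.
block_reduce <- function(vol, fac) {
  d <- dim(vol); out_d <- d %/% fac
  idx <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1L) %/% fac[ax] + 1L)
  sums <- array(0, dim = out_d)
  # accumulate counts per block
  blk <- cbind(idx[[1]][slice.index(vol, 1)],
               idx[[2]][slice.index(vol, 2)],
               idx[[3]][slice.index(vol, 3)])
  lin <- (blk[, 3] - 1L) * out_d[1] * out_d[2] + (blk[, 2] - 1L) * out_d[1] + blk[, 1]
  counts <- tabulate(lin[as.vector(vol)], nbins = prod(out_d))
  array(counts >= prod(fac) / 2, dim = out_d)
}

#' Write a lesion map (or any volume on a grid) as NIfTI
#'
#' @param map a \code{lesion_map}, or a numeric 3D array over the grid.
#' @param path output file path (\code{.nii} or \code{.nii.gz}).
#' @param grid required when \code{map} is a bare array.
#' @return The path, invisibly.
#' @export
write_lesion <- function(map, path, grid = NULL) {
  if (inherits(map, "lesion_map")) {
    arr <- map$voxels * 1
    grid <- map$grid
  } else {
    stopifnot(inherits(grid, "brain_grid"))
    arr <- map
  }
  img <- RNifti::asNifti(arr * 1.0)
  RNifti::pixdim(img) <- rep(grid$voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Flatten a lesion map to its in-mask binary vector
#'
#' The lesion vector is the fixed column-major linearization of the in-mask
#' voxels (see \code{\link{build_brain_grid}}); it is the high-dimensional
#' parameterization used by the recovery classifier.
#' \code{devectorize()} inverts it exactly.
#'
#' @param map a \code{lesion_map}.
#' @return Integer vector (0/1) of length \code{grid$n_in_mask}.
#' @export
vectorize <- function(map) {
  stopifnot(inherits(map, "lesion_map"))
  as.integer(map$voxels[map$grid$mask_idx])
}

#' @rdname vectorize
#' @param values vector of length \code{grid$n_in_mask} (lesion 0/1, or real
#'   values such as classifier weights).
#' @param grid the \code{brain_grid}.
#' @return \code{devectorize()}: a 3D array over the grid, zero outside the
#'   mask; logical arrays are returned as \code{lesion_map} when
#'   \code{as_map = TRUE}.
#' @param as_map return a \code{lesion_map} (binary input only).
#' @export
devectorize <- function(values, grid, as_map = FALSE) {
  stopifnot(inherits(grid, "brain_grid"))
  if (length(values) != grid$n_in_mask)
    stop_therinf("vector length ", length(values), " does not match grid n_in_mask ",
                 grid$n_in_mask)
  arr <- array(0, dim = grid$dims)
  arr[grid$mask_idx] <- values
  if (as_map) lesion_map(grid, arr != 0) else arr
}

#' Lesion volume in voxels and millilitres
#'
#' Millilitres are \code{voxels * voxel_size_mm^3 / 1000}; at the default
#' 6 mm resolution one voxel is 0.216 ml.
#'
#' @param map a \code{lesion_map}.
#' @return A list with \code{voxels} (integer count) and \code{ml}.
#' @export
lesion_volume <- function(map) {
  stopifnot(inherits(map, "lesion_map"))
  n <- sum(map$voxels)
  list(voxels = as.integer(n), ml = n * map$grid$voxel_size_mm^3 / 1000)
}

#' Right-hemisphere damage ratio
#'
#' The ratio of right-hemisphere lesioned voxels to total lesioned voxels,
#' the laterality statistic relating damage to the direction of gaze
#' deviation. For an empty lesion the ratio is undefined and \code{NA_real_}
#' is returned (never 0) with a warning.
#'
#' @param map a \code{lesion_map}.
#' @return A value in [0, 1], or \code{NA_real_} for an empty lesion.
#' @export
laterality_ratio <- function(map) {
  stopifnot(inherits(map, "lesion_map"))
  v <- map$voxels[map$grid$mask_idx]
  tot <- sum(v)
  if (tot == 0L) {
    warning("laterality_ratio: empty lesion, ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(v & map$grid$hemisphere == "right") / tot
}

#' Mirror a lesion across the midline
#'
#' Flips the lesion along the grid's midline axis; useful for symmetry
#' checks on even grids.
#' @param map a \code{lesion_map}.
#' @return The mirrored \code{lesion_map}.
#' @export
mirror_lesion <- function(map) {
  ax <- map$grid$midline_axis
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(map$grid$dims[ax]))
  flipped <- do.call(`[`, c(list(map$voxels), idx, list(drop = FALSE)))
  lesion_map(map$grid, array(flipped, dim = map$grid$dims))
}

#' @export
print.lesion_map <- function(x, ...) {
  v <- lesion_volume(x)
  cat(sprintf("lesion_map: %d voxels (%.3f ml) on %d-voxel grid\n",
              v$voxels, v$ml, x$grid$n_in_mask))
  invisible(x)
}
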