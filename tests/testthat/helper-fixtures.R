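# Shared fixtures, built in code at test time.

# Tiny all-in-mask grid for voxel-level arithmetic.
cube_grid <- function(n = 5L) {
  build_brain_grid(dims = rep(n, 3L), voxel_size_mm = 6,
                   semiaxes = rep(10 * n, 3L))
}

# Solid axis-aligned cuboid lesion.
cuboid_lesion <- function(grid, x, y, z) {
  arr <- array(FALSE, dim = grid$dims)
  arr[x, y, z] <- TRUE
  lesion_map(grid, arr)
}

# Random blob: stochastic accretion, always 6-connected and in-mask.
random_blob <- function(grid, volume, seed) {
  generate_lesion(grid, volume_voxels = volume, unilateral_p = 0, seed = seed)
}

# Brute-force city-block distance to the lesion exterior (the erosion-depth
# oracle): multi-source BFS from all non-lesion positions (array border
# counts as exterior).
cityblock_depth_oracle <- function(map) {
  d <- dim(map$voxels)
  vox <- map$voxels
  depth <- array(NA_integer_, dim = d)
  depth[!vox] <- 0L
  current <- 0L
  while (anyNA(depth)) {
    nxt <- array(FALSE, dim = d)
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      shifted <- array(FALSE, dim = d)
      src <- dst <- vector("list", 3)
      for (ax in 1:3) {
        o <- off[ax]
        if (o >= 0) { dst[[ax]] <- seq_len(d[ax]-o)+o; src[[ax]] <- seq_len(d[ax]-o) }
        else        { dst[[ax]] <- seq_len(d[ax]+o);    src[[ax]] <- seq_len(d[ax]+o)-o }
      }
      lvl <- !is.na(depth) & depth == current
      shifted[dst[[1]], dst[[2]], dst[[3]]] <- lvl[src[[1]], src[[2]], src[[3]]]
      nxt <- nxt | shifted
    }
    border_exterior <- current == 0L
    if (border_exterior) {
      # voxels on the array border adjacent to "outside"
      edge <- array(FALSE, dim = d)
      edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE
      edge[, , c(1, d[3])] <- TRUE
      nxt <- nxt | edge
    }
    sel <- nxt & is.na(depth)
    if (!any(sel)) break
    depth[sel] <- current + 1L
    current <- current + 1L
  }
  depth[!vox] <- 0L
  depth
}

# Flood fill count of 6-connected components of a lesion.
n_components_oracle <- function(map) {
  vox <- map$voxels
  d <- dim(vox)
  seen <- array(FALSE, dim = d)
  idx_all <- which(vox)
  comp <- 0L
  for (start in idx_all) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        q <- ijk + off
        if (all(q >= 1L) && all(q <= d)) {
          lin <- (q[3]-1L)*d[1]*d[2] + (q[2]-1L)*d[1] + q[1]
          if (vox[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
        }
      }
    }
  }
  comp
}

# Linearly separable lesion-vector fixture: recovery iff voxel `crit` is
# intact (0). All other voxels are noise.
separable_fixture <- function(n = 60L, p = 15L, crit = 1L, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * p, 1, 0.3), nrow = n)
    x[, crit] <- rep(c(0L, 1L), length.out = n)
    y <- x[, crit] == 0L
    rownames(x) <- sprintf("S%03d", seq_len(n))
    list(x = x, y = y, crit = crit)
  })
}

# Independent closed-form OLS oracle for the treated coefficient: normal
# equations, explicit covariance, t distribution.
ols_oracle <- function(X, y, col = 2L) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- beta[col] / se[col]
  list(coefficient = beta[col], p_value = 2 * stats::pt(-abs(tstat), df))
}

# Small cohort for engine tests (cached per session).
tiny_cohort <- local({
  cache <- NULL
  function(n = 220L, seed = 42L) {
    if (is.null(cache)) cache <<- generate_cohort(n = n, grid = desk_brain_grid(),
                                                  seed = seed)
    cache
  }
})
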