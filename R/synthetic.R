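# Synthetic cohort generation.
#
# The generator emulates the statistical structure a lesion-cohort analysis
# of gaze deviation relies on: contiguous, predominantly unilateral
# stroke-like lesions; admission gaze centred near the midline at the
# population level but strongly dependent on damage laterality (leftward
# deviation driven by right-hemisphere damage); and anatomy-dependent
# recovery that a linear classifier can learn. The functional "ground truth"
# is a pair of smooth voxel weight fields: deficit weights map damage to
# gaze deviation, recovery weights map damage to the log-odds of
# non-recovery via a logistic link — deliberately different from the linear
# models used downstream, so that high-dimensional gains are not an artefact
# of model match.

#' Ground-truth configuration for the synthetic generator
#'
#' Parameters of the smooth Gaussian-bump weight fields that stand in for
#' the (unknown) functional anatomy. Deficit weights are positive in the
#' right hemisphere (damage there pulls gaze leftward, i.e. negative) and
#' negative in the left; right-hemisphere mass exceeds left so leftward
#' deviation dominates among the severely deviated while the population
#' mean stays near the midline. Recovery foci sit near the right-hemisphere
#' deficit foci, so that among gaze-deviated patients recovery depends on
#' exactly where within the critical region the lesion falls: patients
#' whose lesion covers a recovery-critical focus persist, the rest recover.
#'
#' Spatial scales (\code{*_mm} parameters) default to \code{NULL}, meaning
#' they are derived from the grid at generation time as fixed fractions of
#' the brain width (the extent along the left-right axis), so the same
#' configuration produces equivalent structure on the full-scale and desk
#' grids.
#'
#' @param n_foci_right,n_foci_left number of deficit foci per hemisphere.
#' @param deficit_total_right,deficit_total_left total deficit weight mass
#'   per hemisphere, in degrees of gaze deviation for a lesion covering the
#'   whole field (left-hemisphere weights are negative with this magnitude).
#' @param deficit_sigma_mm spatial SD of the deficit Gaussian bumps
#'   (default: 14\% of brain width).
#' @param recovery_total total non-recovery log-odds mass across recovery
#'   foci.
#' @param focus_min_sep_frac minimum pairwise separation of focus centres,
#'   as a fraction of brain width (rejection sampling).
#' @param n_recovery_foci how many of the right-hemisphere deficit foci
#'   carry a recovery-critical focus (default 1 of the 2, so that roughly
#'   half of the gaze-deviated patients persist).
#' @param recovery_sigma_mm,recovery_offset_mm spatial SD of the recovery
#'   bumps (default 7\% of brain width) and the jitter of their centres
#'   around the corresponding deficit foci (default 6\% of brain width).
#' @param recovery_intercept baseline non-recovery log-odds for an empty
#'   lesion (negative = recovery likely).
#' @param gaze_noise_sd_deg SD of the Gaussian noise on admission gaze.
#' @param recovery_gaze_target_sd_deg SD of the second-time-point gaze draw
#'   for recovered patients (centred on the midline).
#' @param persist_sd_deg SD of the second-time-point gaze draw for
#'   non-recovered patients (centred on their admission gaze).
#' @return A list of class \code{ground_truth_config}.
#' @export
ground_truth_config <- function(n_foci_right = 2L, n_foci_left = 2L,
                                deficit_total_right = 200,
                                deficit_total_left = 170,
                                deficit_sigma_mm = NULL,
                                focus_min_sep_frac = 0.5,
                                n_recovery_foci = 1L,
                                recovery_total = 80,
                                recovery_sigma_mm = NULL,
                                recovery_offset_mm = NULL,
                                recovery_intercept = -2.5,
                                gaze_noise_sd_deg = 4,
                                recovery_gaze_target_sd_deg = 1.0,
                                persist_sd_deg = 5) {
  structure(as.list(environment()), class = "ground_truth_config")
}

# Gaussian bump over the in-mask voxels, centred at voxel coordinate ctr,
# normalized to sum to `total` over the mask.
gaussian_bump <- function(grid, ctr, sigma_mm, total) {
  coords <- arrayInd(grid$mask_idx, grid$dims)
  d2 <- colSums((t(coords) - ctr)^2) * grid$voxel_size_mm^2
  w <- exp(-d2 / (2 * sigma_mm^2))
  w * (total / sum(w))
}

#' Generate the synthetic functional ground truth
#'
#' Draws deficit and recovery weight fields as sums of Gaussian bumps
#' restricted to the grid mask (see \code{\link{ground_truth_config}}).
#' Deterministic given \code{seed}.
#'
#' @param grid a \code{brain_grid}.
#' @param config a \code{\link{ground_truth_config}}.
#' @param seed integer seed.
#' @return An object of class \code{ground_truth}: 3D arrays
#'   \code{deficit_weights} and \code{recovery_weights} (zero outside the
#'   mask), \code{recovery_intercept}, the noise SDs, and the focus centres
#'   used.
#' @export
generate_ground_truth <- function(grid, config = ground_truth_config(), seed = 1L) {
  stopifnot(inherits(grid, "brain_grid"))
  cf <- config
  brain_width <- grid$dims[grid$midline_axis] * grid$voxel_size_mm
  cf$deficit_sigma_mm <- cf$deficit_sigma_mm %||% (0.14 * brain_width)
  cf$recovery_sigma_mm <- cf$recovery_sigma_mm %||% (0.07 * brain_width)
  cf$recovery_offset_mm <- cf$recovery_offset_mm %||% (0.06 * brain_width)
  left_idx <- grid$mask_idx[grid$hemisphere == "left"]
  right_idx <- grid$mask_idx[grid$hemisphere == "right"]

  min_sep_vox <- (cf$focus_min_sep_frac %||% 0.35) * brain_width / grid$voxel_size_mm
  res <- withr::with_seed(seed, {
    # rejection-sample focus centres with a minimum pairwise separation so
    # that distinct foci occupy distinct territories, and comparable
    # distances from the hemisphere centroid so no focus dominates the
    # lesion exposure
    pick_ctr <- function(idx_pool, n) {
      centroid <- colMeans(arrayInd(idx_pool, grid$dims))
      for (try in seq_len(500L)) {
        sel <- idx_pool[sample.int(length(idx_pool), n)]
        ctr <- arrayInd(sel, grid$dims)
        if (n == 1L) return(ctr)
        d_cent <- sqrt(colSums((t(ctr) - centroid)^2))
        if (min(stats::dist(ctr)) >= min_sep_vox &&
            diff(range(d_cent)) <= 0.10 * brain_width / grid$voxel_size_mm)
          return(ctr)
      }
      ctr # fall back on the last draw if the constraints are infeasible
    }
    def_r <- if (cf$n_foci_right > 0) pick_ctr(right_idx, cf$n_foci_right) else NULL
    def_l <- if (cf$n_foci_left > 0) pick_ctr(left_idx, cf$n_foci_left) else NULL
    # recovery-critical foci: jittered copies of the first n_recovery_foci
    # right-hemisphere deficit foci
    rec_ctr <- NULL
    n_rec <- min(cf$n_recovery_foci %||% 1L, if (is.null(def_r)) 0L else nrow(def_r))
    if (n_rec > 0L && cf$recovery_total > 0) {
      off_vox <- cf$recovery_offset_mm / grid$voxel_size_mm
      rec_ctr <- def_r[seq_len(n_rec), , drop = FALSE] +
        matrix(stats::rnorm(3L * n_rec, 0, off_vox), nrow = n_rec)
      rec_ctr <- pmin(pmax(rec_ctr, 1), matrix(grid$dims, nrow(rec_ctr), 3, byrow = TRUE))
    }
    list(def_r = def_r, def_l = def_l, rec_ctr = rec_ctr)
  })

  p <- grid$n_in_mask
  deficit_v <- numeric(p)
  if (!is.null(res$def_r))
    for (i in seq_len(nrow(res$def_r)))
      deficit_v <- deficit_v + gaussian_bump(grid, res$def_r[i, ], cf$deficit_sigma_mm,
                                             cf$deficit_total_right / nrow(res$def_r))
  if (!is.null(res$def_l))
    for (i in seq_len(nrow(res$def_l)))
      deficit_v <- deficit_v - gaussian_bump(grid, res$def_l[i, ], cf$deficit_sigma_mm,
                                             cf$deficit_total_left / nrow(res$def_l))
  recovery_v <- numeric(p)
  if (!is.null(res$rec_ctr))
    for (i in seq_len(nrow(res$rec_ctr)))
      recovery_v <- recovery_v + gaussian_bump(grid, res$rec_ctr[i, ], cf$recovery_sigma_mm,
                                               cf$recovery_total / nrow(res$rec_ctr))

  structure(list(
    grid = grid,
    deficit_weights = devectorize(deficit_v, grid),
    recovery_weights = devectorize(recovery_v, grid),
    recovery_intercept = cf$recovery_intercept,
    gaze_noise_sd_deg = cf$gaze_noise_sd_deg,
    recovery_gaze_target_sd_deg = cf$recovery_gaze_target_sd_deg,
    persist_sd_deg = cf$persist_sd_deg,
    foci = res,
    config = cf
  ), class = "ground_truth")
}

#' Grow a contiguous stroke-like lesion
#'
#' Grows a single 6-connected lesion from a uniformly drawn in-mask origin
#' by stochastic boundary accretion until a target volume is reached. The
#' target is drawn from a log-normal distribution (truncated by redraw at
#' \code{max_volume_frac} of the growth region); growth is restricted to the
#' origin's hemisphere with probability \code{unilateral_p}.
#'
#' @param grid a \code{brain_grid}.
#' @param meanlog,sdlog log-normal parameters of the lesion volume in
#'   voxels. If \code{meanlog} is \code{NULL} it defaults to
#'   \code{log(volume_mean_frac * n_in_mask)}.
#' @param volume_mean_frac default median lesion volume as a fraction of the
#'   in-mask volume.
#' @param unilateral_p probability that growth is confined to one hemisphere.
#' @param max_volume_frac cap on the drawn volume, as a fraction of the
#'   growth-region capacity.
#' @param volume_voxels optional fixed target volume, overriding the draw.
#' @param seed integer seed.
#' @return A \code{lesion_map} forming one 6-connected component.
#' @export
generate_lesion <- function(grid, meanlog = NULL, sdlog = 0.6,
                            volume_mean_frac = 0.04, unilateral_p = 0.95,
                            max_volume_frac = 0.6, volume_voxels = NULL,
                            seed = 1L) {
  stopifnot(inherits(grid, "brain_grid"))
  if (is.null(meanlog)) meanlog <- log(volume_mean_frac * grid$n_in_mask)
  withr::with_seed(seed, {
    origin <- grid$mask_idx[sample.int(grid$n_in_mask, 1L)]
    unilateral <- stats::runif(1) < unilateral_p
    if (unilateral) {
      hemi <- grid$hemisphere[match(origin, grid$mask_idx)]
      region_idx <- grid$mask_idx[grid$hemisphere == hemi]
    } else region_idx <- grid$mask_idx
    capacity <- length(region_idx)
    if (is.null(volume_voxels)) {
      target <- Inf; tries <- 0L
      while (target > max_volume_frac * capacity) {
        target <- max(1, round_half_up(stats::rlnorm(1, meanlog, sdlog)))
        tries <- tries + 1L
        if (tries > 100L)
          stop_therinf("generate_lesion: volume distribution incompatible with grid capacity")
      }
    } else target <- volume_voxels
    if (target > capacity)
      stop_therinf("generate_lesion: requested volume ", target,
                   " exceeds region capacity ", capacity)

    region <- array(FALSE, dim = grid$dims); region[region_idx] <- TRUE
    lesion <- array(FALSE, dim = grid$dims)
    in_frontier <- array(FALSE, dim = grid$dims)
    d <- grid$dims
    neigh <- function(v) {
      ijk <- arrayInd(v, d)
      out <- integer(0)
      for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        q <- ijk + off
        if (all(q >= 1L) && all(q <= d))
          out <- c(out, (q[3] - 1L) * d[1] * d[2] + (q[2] - 1L) * d[1] + q[1])
      }
      out
    }
    frontier <- origin; in_frontier[origin] <- TRUE
    n_grown <- 0L
    while (n_grown < target && length(frontier) > 0L) {
      pos <- sample.int(length(frontier), 1L)
      v <- frontier[pos]
      frontier[pos] <- frontier[length(frontier)]
      frontier <- frontier[-length(frontier)]
      in_frontier[v] <- FALSE
      lesion[v] <- TRUE
      n_grown <- n_grown + 1L
      for (nb in neigh(v)) {
        if (region[nb] && !lesion[nb] && !in_frontier[nb]) {
          frontier <- c(frontier, nb)
          in_frontier[nb] <- TRUE
        }
      }
    }
    lesion_map(grid, lesion)
  })
}

#' Simulate gaze at two time points from a lesion
#'
#' Admission gaze is minus the sum of deficit weights over lesioned voxels
#' (so right-hemisphere damage, with positive weights, deviates gaze
#' leftward) plus Gaussian noise. The non-recovery log-odds are the
#' recovery-weight sum plus intercept; with the complementary probability
#' the patient recovers, in which case the second-time-point gaze is drawn
#' near the midline, otherwise it is drawn around the admission gaze. All
#' angles are wrapped to (-180, 180].
#'
#' @param lesion a \code{lesion_map} on the ground truth's grid.
#' @param gt a \code{ground_truth}.
#' @param seed integer seed.
#' @return List with \code{gaze_t1_deg}, \code{gaze_t2_deg} and
#'   \code{natural_recovered} (the latent recovery draw).
#' @export
simulate_gaze <- function(lesion, gt, seed = 1L) {
  stopifnot(inherits(lesion, "lesion_map"), inherits(gt, "ground_truth"))
  if (!same_grid(lesion$grid, gt$grid))
    stop_therinf("lesion and ground truth are on different grids")
  les <- lesion$voxels
  deficit_sum <- sum(gt$deficit_weights[les])
  nonrec_logodds <- gt$recovery_intercept + sum(gt$recovery_weights[les])
  withr::with_seed(seed, {
    gaze_t1 <- wrap_angle(-deficit_sum + stats::rnorm(1, 0, gt$gaze_noise_sd_deg))
    p_recover <- stats::plogis(-nonrec_logodds)
    natural_recovered <- stats::runif(1) < p_recover
    gaze_t2 <- if (natural_recovered) {
      wrap_angle(stats::rnorm(1, 0, gt$recovery_gaze_target_sd_deg))
    } else {
      wrap_angle(stats::rnorm(1, gaze_t1, gt$persist_sd_deg))
    }
    list(gaze_t1_deg = gaze_t1, gaze_t2_deg = gaze_t2,
         natural_recovered = natural_recovered)
  })
}

#' Generate a synthetic lesion cohort
#'
#' Generates \code{n} patients with independent lesions
#' (\code{\link{generate_lesion}}), gaze at two time points
#' (\code{\link{simulate_gaze}}), age (normal, truncated at 18) and sex
#' (Bernoulli 0.5). Age and sex have no effect on outcome: they are pure
#' confound candidates for the trial models. Eligibility (leftward gaze
#' deviation > 12 degrees at time 1) and recovery (within 3 degrees of
#' midline at time 2) labels are derived with \code{\link{classify_gaze}}.
#' Fully deterministic given \code{seed}.
#'
#' @param n number of patients (default 1172, the scale of a large clinical
#'   lesion cohort).
#' @param grid a \code{brain_grid} (default \code{\link{default_brain_grid}}).
#' @param gt optional \code{ground_truth}; generated from
#'   \code{gt_config} and \code{seed} when \code{NULL}.
#' @param gt_config a \code{\link{ground_truth_config}}.
#' @param lesion_config list of arguments passed to
#'   \code{\link{generate_lesion}} (e.g. \code{sdlog},
#'   \code{volume_mean_frac}, \code{unilateral_p}).
#' @param age_mean,age_sd age distribution (years), truncated at >= 18.
#' @param seed master integer seed.
#' @return An object of class \code{cohort}: \code{grid}, \code{covariates}
#'   (data frame with id, age_years, sex, gaze_t1_deg, gaze_t2_deg,
#'   natural_recovered, eligible, recovered), \code{lesions} (list of
#'   \code{lesion_map}) and \code{ground_truth}.
#' @export
generate_cohort <- function(n = 1172L, grid = default_brain_grid(), gt = NULL,
                            gt_config = ground_truth_config(),
                            lesion_config = list(),
                            age_mean = 68, age_sd = 14, seed = 1L) {
  stopifnot(n >= 1L)
  if (is.null(gt)) gt <- generate_ground_truth(grid, gt_config, seed = mix_seed(seed, 4L))
  if (!same_grid(grid, gt$grid)) stop_therinf("grid and ground truth disagree")

  lesions <- vector("list", n)
  gaze1 <- gaze2 <- numeric(n)
  natrec <- logical(n)
  for (i in seq_len(n)) {
    lesions[[i]] <- do.call(generate_lesion,
                            c(list(grid = grid, seed = mix_seed(seed, 1L, i)),
                              lesion_config))
    gz <- simulate_gaze(lesions[[i]], gt, seed = mix_seed(seed, 2L, i))
    gaze1[i] <- gz$gaze_t1_deg; gaze2[i] <- gz$gaze_t2_deg
    natrec[i] <- gz$natural_recovered
  }
  demo <- withr::with_seed(mix_seed(seed, 3L), {
    age <- stats::rnorm(n, age_mean, age_sd)
    while (any(age < 18)) age[age < 18] <- stats::rnorm(sum(age < 18), age_mean, age_sd)
    list(age = age, sex = stats::rbinom(n, 1, 0.5))
  })
  labels <- classify_gaze(gaze1, gaze2)
  covariates <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age_years = demo$age,
    sex = demo$sex,
    gaze_t1_deg = gaze1,
    gaze_t2_deg = gaze2,
    natural_recovered = natrec,
    eligible = labels$eligible,
    recovered = labels$recovered,
    stringsAsFactors = FALSE
  )
  names(lesions) <- covariates$id
  structure(list(grid = grid, covariates = covariates, lesions = lesions,
                 ground_truth = gt, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cv <- x$covariates
  cat(sprintf("cohort: %d patients on %d-voxel grid; %d eligible (gaze < -12), %d/%d recovered\n",
              nrow(cv), x$grid$n_in_mask, sum(cv$eligible),
              sum(cv$recovered, na.rm = TRUE), sum(cv$eligible)))
  invisible(x)
}

#' Lesion design matrix of a cohort
#'
#' Stacks the lesion vectors (\code{\link{vectorize}}) of the given patients
#' into an \code{n x n_in_mask} 0/1 matrix with patient ids as row names.
#'
#' @param cohort a \code{cohort}.
#' @param ids patient ids (default: all).
#' @return Numeric matrix.
#' @export
lesion_matrix <- function(cohort, ids = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- ids %||% cohort$covariates$id
  x <- matrix(0, nrow = length(ids), ncol = cohort$grid$n_in_mask,
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) x[i, ] <- vectorize(cohort$lesions[[ids[i]]])
  x
}

#' Write / read a cohort to a directory
#'
#' Writes one NIfTI per lesion, a tab-delimited covariates table, the grid
#' mask as NIfTI, and (when present) the ground-truth weight fields.
#' \code{read_cohort()} restores the cohort (without the generator's latent
#' ground truth unless the weight files are present).
#'
#' @param cohort a \code{cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "lesions"), showWarnings = FALSE)
  g <- cohort$grid
  write_lesion(array(g$mask * 1, dim = g$dims), file.path(dir, "mask.nii.gz"), grid = g)
  writeLines(yaml::as.yaml(list(dims = as.integer(g$dims),
                                voxel_size_mm = g$voxel_size_mm,
                                midline_axis = g$midline_axis)),
             file.path(dir, "grid.yaml"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (id in cohort$covariates$id)
    write_lesion(cohort$lesions[[id]], file.path(dir, "lesions", paste0(id, ".nii.gz")))
  if (!is.null(cohort$ground_truth)) {
    write_lesion(cohort$ground_truth$deficit_weights,
                 file.path(dir, "gt_deficit_weights.nii.gz"), grid = g)
    write_lesion(cohort$ground_truth$recovery_weights,
                 file.path(dir, "gt_recovery_weights.nii.gz"), grid = g)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  gs <- yaml::read_yaml(file.path(dir, "grid.yaml"))
  grid <- build_brain_grid(dims = gs$dims, voxel_size_mm = gs$voxel_size_mm,
                           mask = file.path(dir, "mask.nii.gz"),
                           midline_axis = gs$midline_axis)
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"),
                                  stringsAsFactors = FALSE)
  lesions <- lapply(covariates$id, function(id)
    read_lesion(file.path(dir, "lesions", paste0(id, ".nii.gz")), grid))
  names(lesions) <- covariates$id
  structure(list(grid = grid, covariates = covariates, lesions = lesions,
                 ground_truth = NULL), class = "cohort")
}
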