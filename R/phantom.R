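# Synthetic short-axis LGE phantom generator. Geometry: one LV per case as a
# per-slice annulus (blood pool inside, myocardium ring) whose radii taper
# linearly toward the apex; infarct scar as a subendocardial angular wedge
# with a drawn transmurality; an optional hypointense MVO core occupying the
# inner, angularly central part of the wedge on a central subset of the scar
# slices. Intensities are class means plus additive Gaussian noise.

# run code() under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code()
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

#' Phantom generator parameters
#'
#' Defaults emulate an all-STEMI short-axis LGE cohort: every case carries an
#' infarct scar (`scar_probability = 1`) and 15% of scarred cases carry an MVO
#' core. The grid is 12 x 128 x 128 at (8, 1.5, 1.5) mm, the typical
#' anisotropy of clinical short-axis LGE stacks.
#'
#' @param grid_shape `(n_slices, n_rows, n_cols)` voxels, all >= 1.
#' @param spacing_mm `(dz, dy, dx)` in mm.
#' @param lv_center_range List with `row` and `col` ranges (voxels) from which
#'   the LV axis position is drawn uniformly.
#' @param endo_radius_mm,epi_radius_mm Ranges (mm) for basal endo/epicardial
#'   radii; the epicardial range must lie entirely above the endocardial one.
#' @param apex_taper Radius scale factor at the most apical slice (base = 1).
#' @param scar_probability Probability a case has scar.
#' @param scar_angular_extent_deg Range (degrees) of the scar wedge.
#' @param scar_transmurality Range in (0, 1]: wedge depth from the
#'   endocardial border as a fraction of wall thickness.
#' @param mvo_probability_given_scar Probability of an MVO core given scar.
#' @param mvo_fraction_of_scar Range in (0, 1): MVO depth as a fraction of the
#'   scar depth.
#' @param intensity_means Named class means (arbitrary units); scar must be
#'   hyperintense relative to remote myocardium, MVO hypointense (<= remote).
#' @param noise_sd Additive Gaussian noise SD; a scalar or a per-class named
#'   vector.
#' @param seed Master seed for [generate_dataset()].
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(12L, 128L, 128L),
                           spacing_mm = c(8, 1.5, 1.5),
                           lv_center_range = list(row = c(52, 76), col = c(52, 76)),
                           endo_radius_mm = c(12, 18),
                           epi_radius_mm = c(22, 28),
                           apex_taper = 0.55,
                           scar_probability = 1,
                           scar_angular_extent_deg = c(40, 120),
                           scar_transmurality = c(0.4, 1),
                           mvo_probability_given_scar = 0.15,
                           mvo_fraction_of_scar = c(0.15, 0.4),
                           intensity_means = c(background = 50, blood = 320,
                                               myocardium = 200, scar = 450,
                                               mvo = 170),
                           noise_sd = 25,
                           seed = 1L) {
  p <- list(grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
            lv_center_range = lv_center_range,
            endo_radius_mm = as.numeric(endo_radius_mm),
            epi_radius_mm = as.numeric(epi_radius_mm),
            apex_taper = apex_taper,
            scar_probability = scar_probability,
            scar_angular_extent_deg = as.numeric(scar_angular_extent_deg),
            scar_transmurality = as.numeric(scar_transmurality),
            mvo_probability_given_scar = mvo_probability_given_scar,
            mvo_fraction_of_scar = as.numeric(mvo_fraction_of_scar),
            intensity_means = intensity_means,
            noise_sd = noise_sd, seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  fail <- function(field, why) stop("invalid phantom parameter '", field, "': ", why)
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 1L))
    fail("grid_shape", "all three dimensions must be >= 1")
  if (any(p$spacing_mm <= 0)) fail("spacing_mm", "spacings must be > 0")
  for (f in c("scar_probability", "mvo_probability_given_scar")) {
    if (p[[f]] < 0 || p[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  if (max(p$endo_radius_mm) >= min(p$epi_radius_mm))
    fail("epi_radius_mm", "must lie entirely above endo_radius_mm so endo < epi for every case")
  if (p$apex_taper <= 0 || p$apex_taper > 1) fail("apex_taper", "must lie in (0, 1]")
  if (any(p$scar_transmurality <= 0) || any(p$scar_transmurality > 1))
    fail("scar_transmurality", "range must lie in (0, 1]")
  if (any(p$mvo_fraction_of_scar <= 0) || any(p$mvo_fraction_of_scar >= 1))
    fail("mvo_fraction_of_scar", "range must lie in (0, 1)")
  m <- p$intensity_means
  need <- names(label_codes())
  if (!all(need %in% names(m)))
    fail("intensity_means", paste("must name all of:", paste(need, collapse = ", ")))
  if (m[["scar"]] <= m[["myocardium"]])
    fail("intensity_means", "scar mean must exceed remote myocardium mean (hyperenhancement)")
  if (m[["mvo"]] > m[["myocardium"]])
    fail("intensity_means", "mvo mean must not exceed remote myocardium mean (hypointense core)")
  if (any(expand_noise_sd(p$noise_sd) < 0)) fail("noise_sd", "must be >= 0")
  invisible(p)
}

expand_noise_sd <- function(noise_sd) {
  need <- names(label_codes())
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    return(stats::setNames(rep(as.numeric(noise_sd), 5L), need))
  if (!all(need %in% names(noise_sd)))
    stop("invalid phantom parameter 'noise_sd': scalar or named per-class vector required")
  as.numeric(noise_sd[need])
}

# circular membership: is angle a (deg) within [a0, a0 + extent] mod 360?
in_wedge <- function(a, a0, extent) ((a - a0) %% 360) <= extent

#' Generate one synthetic LGE case
#'
#' Deterministic for fixed `(params, case_seed)`; the caller's RNG state is
#' left untouched.
#'
#' @param params A [phantom_params()] object.
#' @param case_seed Integer seed for this case.
#' @return A list of class `phantom_case` with elements `image`
#'   ([image_volume()]), `labels` ([label_volume()]) and `meta` (drawn
#'   geometry: LV center, radii, scar/MVO status and wedge parameters).
#' @export
generate_case <- function(params, case_seed) {
  validate_phantom_params(params)
  with_seed(as.integer(case_seed), function() {
    d <- params$grid_shape
    cr <- runif_range(params$lv_center_range$row)
    cc <- runif_range(params$lv_center_range$col)
    endo_mm <- runif_range(params$endo_radius_mm)
    epi_mm <- runif_range(params$epi_radius_mm)
    has_scar <- stats::runif(1) < params$scar_probability
    theta0 <- stats::runif(1, 0, 360)
    extent <- runif_range(params$scar_angular_extent_deg)
    trans <- runif_range(params$scar_transmurality)
    has_mvo <- has_scar && stats::runif(1) < params$mvo_probability_given_scar
    mvo_frac <- runif_range(params$mvo_fraction_of_scar)

    # scar occupies a contiguous band of slices; MVO its central half
    n <- d[1]
    scar_len <- max(1L, as.integer(round(stats::runif(1, 0.5, 0.9) * n)))
    scar_lo <- if (n == scar_len) 1L else sample.int(n - scar_len + 1L, 1L)
    scar_slices <- scar_lo:(scar_lo + scar_len - 1L)
    mvo_len <- max(1L, as.integer(floor(scar_len / 2)))
    mvo_off <- as.integer(floor((scar_len - mvo_len) / 2))
    mvo_slices <- scar_slices[(mvo_off + 1L):(mvo_off + mvo_len)]

    dy <- params$spacing_mm[2]
    rows <- matrix(rep(seq_len(d[2]), d[3]), d[2], d[3])
    cols <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
    dist_mm <- sqrt((rows - cr)^2 + (cols - cc)^2) * dy
    ang <- (atan2(rows - cr, cols - cc) * 180 / pi) %% 360

    labels <- array(0L, d)
    for (s in seq_len(n)) {
      sc <- 1 - (1 - params$apex_taper) * (s - 1) / max(1L, n - 1L)
      endo <- endo_mm * sc
      epi <- epi_mm * sc
      sl <- matrix(0L, d[2], d[3])
      sl[dist_mm <= endo] <- 1L                       # blood pool
      ring <- dist_mm > endo & dist_mm <= epi
      sl[ring] <- 2L                                  # myocardium
      if (has_scar && s %in% scar_slices) {
        depth <- endo + trans * (epi - endo)
        wedge <- ring & dist_mm <= depth & in_wedge(ang, theta0, extent)
        sl[wedge] <- 3L                               # scar
        if (has_mvo && s %in% mvo_slices) {
          mdepth <- endo + mvo_frac * trans * (epi - endo)
          core <- wedge & dist_mm <= mdepth &
            in_wedge(ang, theta0 + 0.2 * extent, 0.6 * extent)
          sl[core] <- 4L                              # MVO core
        }
      }
      labels[s, , ] <- sl
    }

    mu <- params$intensity_means[names(label_codes())]
    sdv <- expand_noise_sd(params$noise_sd)
    img <- array(mu[labels + 1L], d) +
      array(stats::rnorm(prod(d)), d) * array(sdv[labels + 1L], d)

    meta <- list(case_seed = as.integer(case_seed), center_rc = c(cr, cc),
                 endo_radius_mm = endo_mm, epi_radius_mm = epi_mm,
                 has_scar = has_scar, has_mvo = has_mvo,
                 scar_theta0_deg = theta0, scar_extent_deg = extent,
                 scar_transmurality = trans, scar_slices = scar_slices,
                 mvo_slices = if (has_mvo) mvo_slices else integer(0))
    structure(list(image = image_volume(img, params$spacing_mm),
                   labels = label_volume(labels, params$spacing_mm),
                   meta = meta),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d, scar=%s, mvo=%s\n",
              x$meta$case_seed, x$meta$has_scar, x$meta$has_mvo))
  print(x$image)
  invisible(x)
}

#' Generate a synthetic LGE dataset
#'
#' Draws `n_cases` distinct per-case seeds from the master seed, so the
#' collection is reproducible and the MVO-positive fraction converges to
#' `scar_probability * mvo_probability_given_scar`.
#'
#' @param params A [phantom_params()] object (its `seed` is the master seed).
#' @param n_cases Number of cases, >= 1.
#' @return List of `phantom_case` objects with metadata `case_id` set.
#' @export
generate_dataset <- function(params, n_cases) {
  validate_phantom_params(params)
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) stop("n_cases must be >= 1")
  seeds <- with_seed(params$seed, function() sample.int(.Machine$integer.max - 1L, n_cases))
  lapply(seq_len(n_cases), function(i) {
    case <- generate_case(params, seeds[i])
    case$meta$case_id <- sprintf("case_%03d", i)
    case
  })
}

#' Remote-myocardium region of interest
#'
#' Returns a connected angular sector of the myocardial ring on the middle
#' slice, diametrally opposite the scar wedge centre (or at a fixed position
#' when the case has no scar); disjoint from scar and MVO by construction,
#' mirroring the small remote-segment oval drawn in the manual thresholding
#' procedure.
#'
#' @param case A `phantom_case`.
#' @param half_width_deg Angular half-width of the sector (default 25).
#' @return Logical array (full grid) marking the ROI voxels.
#' @export
remote_roi <- function(case, half_width_deg = 25) {
  labs <- case$labels$labels
  if (!any(labs == 2L)) stop("degenerate case: no myocardium voxels")
  d <- dim(labs)
  mid <- middle_slice_index(d[1])
  cand <- which(apply(labs == 2L, 1, any))
  s <- if (any(labs[mid, , ] == 2L)) mid else cand[which.min(abs(cand - mid))]

  meta <- case$meta
  opp <- if (isTRUE(meta$has_scar))
    (meta$scar_theta0_deg + meta$scar_extent_deg / 2 + 180) %% 360
  else 180
  cr <- meta$center_rc[1]; cc <- meta$center_rc[2]
  rows <- matrix(rep(seq_len(d[2]), d[3]), d[2], d[3])
  cols <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
  ang <- (atan2(rows - cr, cols - cc) * 180 / pi) %% 360
  ddeg <- pmin(abs(ang - opp), 360 - abs(ang - opp))
  sector <- labs[s, , ] == 2L & ddeg <= half_width_deg
  roi <- array(FALSE, d)
  roi[s, , ] <- sector
  if (!any(roi)) stop("degenerate case: empty remote sector")
  roi
}

#' Write a phantom dataset to disk
#'
#' Writes `<id>_image.nii.gz` and `<id>_labels.nii.gz` per case plus a
#' `manifest.csv` (case id, seed, scar/MVO status, file paths).
#'
#' @param cases List of `phantom_case` objects (from [generate_dataset()]).
#' @param dir Output directory (created if missing).
#' @return Tibble manifest, invisibly.
#' @export
write_dataset <- function(cases, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    id <- if (!is.null(case$meta$case_id)) case$meta$case_id else sprintf("case_%03d", i)
    ip <- file.path(dir, paste0(id, "_image.nii.gz"))
    lp <- file.path(dir, paste0(id, "_labels.nii.gz"))
    write_volume(case$image, ip)
    write_volume(case$labels, lp)
    tibble::tibble(case_id = id, seed = case$meta$case_seed,
                   has_scar = case$meta$has_scar, has_mvo = case$meta$has_mvo,
                   image = ip, labels = lp)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
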