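# Seeded brain-like phantom generation and forward-modeled sodium images.

#' Phantom specification
#'
#' Describes a brain-like labeled volume: an ellipsoidal brain with a gray
#' matter shell and white matter interior, ventricular CSF, three white
#' matter tract regions (SCC, PLIC, ALIC), two cylindrical agar reference
#' tubes adjacent to the head, and a configurable list of spherical lesions.
#'
#' @param grid_shape integer grid dimensions
#' @param voxel_size_mm voxel dimensions in mm (default 3.2 x 3.2 x 6.4, the
#'   density-weighted/coherent-magnetization resolution; use 4.5 x 4.5 x 9.0
#'   for the inversion recovery acquisition)
#' @param lesion_radii_mm radii of the spherical lesions placed in the WM
#' @param lesion_state tissue state of lesion regions
#' @param wm_state tissue state of the WM background and tracts ("control"
#'   for a control subject, "nawm" for a patient)
#' @param noise_sigma Rician noise sigma in agar-relative intensity units
#' @param seed integer seed fixing all randomness (lesion placement, noise)
#' @return object of class `na_phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 24L),
                         voxel_size_mm = c(3.2, 3.2, 6.4),
                         lesion_radii_mm = c(2.0, 3.2, 4.5, 6.4, 10.0),
                         lesion_state = "lesion",
                         wm_state = "control",
                         noise_sigma = 0,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            noise_sigma >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 lesion_radii_mm = lesion_radii_mm,
                 lesion_state = lesion_state, wm_state = wm_state,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "na_phantom_spec")
}

#' Label codes used in phantom volumes
#' @return named integer vector
#' @export
phantom_labels <- function() {
  c(background = 0L, wm = 1L, gm = 2L, csf = 3L, scc = 4L, plic = 5L,
    alic = 6L, agar = 7L, lesion_base = 10L)  # lesion i -> 10 + i
}

# squared ellipsoid distance of all voxel centers from a center (mm)
.ellipsoid_dist2 <- function(shape, vox, center_mm, semi_mm) {
  x <- (seq_len(shape[1]) - 0.5) * vox[1]
  y <- (seq_len(shape[2]) - 0.5) * vox[2]
  z <- (seq_len(shape[3]) - 0.5) * vox[3]
  dx2 <- ((x - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((y - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((z - center_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Build a labeled phantom volume with ground truth
#'
#' Deterministic given `spec$seed`.  Lesions are placed (seeded) inside the
#' WM at least one lesion diameter from the ventricles and from each other;
#' agar tubes are cylinders placed bilaterally outside the head.
#'
#' @param spec an [phantom_spec()]
#' @return list with `labels` (integer 3D array), `truth` (data.frame:
#'   region, label, tissue_state, n_voxels), `spec`
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "na_phantom_spec"))
  set.seed(spec$seed)
  n <- spec$grid_shape; vox <- spec$voxel_size_mm
  fov <- n * vox
  ctr <- fov / 2
  lab <- array(phantom_labels()[["background"]], n)

  brain_semi <- fov * c(0.32, 0.38, 0.40)
  d_brain <- .ellipsoid_dist2(n, vox, ctr, brain_semi)
  lab[d_brain <= 1] <- phantom_labels()[["gm"]]
  d_wm <- .ellipsoid_dist2(n, vox, ctr, brain_semi * 0.82)
  lab[d_wm <= 1] <- phantom_labels()[["wm"]]

  # two ventricles: small ellipsoids around the center
  for (sgn in c(-1, 1)) {
    dv <- .ellipsoid_dist2(n, vox, ctr + c(sgn * 0.06 * fov[1], 0, 0),
                           c(0.045, 0.16, 0.10) * fov)
    lab[dv <= 1] <- phantom_labels()[["csf"]]
  }
  # WM tracts: SCC posterior-midline, PLIC/ALIC lateral
  d <- .ellipsoid_dist2(n, vox, ctr + c(0, 0.22 * fov[2], 0),
                        c(0.10, 0.05, 0.08) * fov)
  lab[d <= 1 & lab == phantom_labels()[["wm"]]] <- phantom_labels()[["scc"]]
  for (sgn in c(-1, 1)) {
    d <- .ellipsoid_dist2(n, vox, ctr + c(sgn * 0.14 * fov[1], 0.06 * fov[2], 0),
                          c(0.04, 0.09, 0.10) * fov)
    lab[d <= 1 & lab == phantom_labels()[["wm"]]] <- phantom_labels()[["plic"]]
    d <- .ellipsoid_dist2(n, vox, ctr + c(sgn * 0.13 * fov[1], -0.12 * fov[2], 0),
                          c(0.04, 0.08, 0.10) * fov)
    lab[d <= 1 & lab == phantom_labels()[["wm"]]] <- phantom_labels()[["alic"]]
  }
  # agar tubes: cylinders (3 cm diameter) bilateral, outside the brain
  x <- (seq_len(n[1]) - 0.5) * vox[1]
  y <- (seq_len(n[2]) - 0.5) * vox[2]
  z <- (seq_len(n[3]) - 0.5) * vox[3]
  tube_r <- min(15, 0.055 * fov[1])  # 3 cm diameter, shrunk on small grids
  for (sgn in c(-1, 1)) {
    cx <- ctr[1] + sgn * 0.43 * fov[1]
    r2 <- outer(((x - cx) / tube_r)^2, ((y - ctr[2]) / tube_r)^2, `+`)
    cyl <- outer(r2 <= 1, abs(z - ctr[3]) <= 55, `&`)           # 11 cm long
    if (any(cyl & lab != 0)) stop("agar tube overlaps brain tissue")
    lab[cyl] <- phantom_labels()[["agar"]]
  }
  # lesions: seeded placement in WM, away from CSF and each other
  wm_codes <- phantom_labels()[c("wm", "scc", "plic", "alic")]
  csf_conv <- lab == phantom_labels()[["csf"]]
  placed <- list()
  for (i in seq_along(spec$lesion_radii_mm)) {
    r <- spec$lesion_radii_mm[i]
    ok <- FALSE
    for (try in 1:500) {
      cand_idx <- which(array(lab %in% wm_codes, n))
      pick <- cand_idx[sample.int(length(cand_idx), 1)]
      pos <- arrayInd(pick, n)
      cmm <- (as.numeric(pos) - 0.5) * vox
      d <- .ellipsoid_dist2(n, vox, cmm, rep(r, 3))
      inside <- d <= 1
      # lesion must lie in WM-like tissue, clear of CSF by one radius
      near <- .ellipsoid_dist2(n, vox, cmm, rep(2 * r, 3)) <= 1
      if (all(lab[inside] %in% c(wm_codes)) && !any(csf_conv & near) &&
          sum(inside) >= 1) {
        lab[inside] <- phantom_labels()[["lesion_base"]] + i
        placed[[i]] <- list(center_mm = cmm, radius_mm = r,
                            n_voxels = sum(inside))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place lesion of radius ", r, " mm")
  }

  regions <- data.frame(
    region = c("wm", "gm", "csf", "scc", "plic", "alic", "agar",
               paste0("lesion", seq_along(placed))),
    label = c(phantom_labels()[c("wm", "gm", "csf", "scc", "plic", "alic",
                                 "agar")],
              phantom_labels()[["lesion_base"]] + seq_along(placed)),
    tissue_state = c(rep(spec$wm_state, 1), "control", "csf",
                     rep(spec$wm_state, 3), "agar",
                     rep(spec$lesion_state, length(placed))),
    row.names = NULL)
  regions$n_voxels <- vapply(regions$label, function(l) sum(lab == l),
                             numeric(1))
  list(labels = lab, truth = regions, spec = spec)
}

# per-tissue-state weighted signal (mmol/L-tissue equivalent) for a sequence
.state_signal <- function(state, sq_name, rw, concs) {
  if (state == "csf") return(concs$c_csf * rw[sq_name, "csf"])
  if (state == "agar") return(concs$c_agar * rw[sq_name, "agar"])
  q <- sodium_contributions(tissue_state(state), concs)
  q$q_intra * rw[sq_name, "intra"] + q$q_extra * rw[sq_name, "extra"] +
    q$q_myelin * rw[sq_name, "myelin"] + q$q_edema * rw[sq_name, "edema"]
}

#' Full relaxation-weighting matrix including csf and agar
#'
#' The reference tissue weightings ([reference_weightings()]) extended with the
#' simulated csf and agar columns from the calibrated default environments,
#' memoized for reuse.  Pass `rw_source = "simulated"` for an entirely
#' simulated matrix.
#'
#' @param rw_source "reference" or "simulated"
#' @return matrix RW[sequence, environment] with columns intra, extra,
#'   myelin, edema, csf, agar
#' @export
full_weightings <- function(rw_source = c("reference", "simulated")) {
  rw_source <- match.arg(rw_source)
  key <- paste0("fullrw_", rw_source)
  if (!is.null(.spin32_cache[[key]])) return(.spin32_cache[[key]])
  envs <- default_environments()
  extra_cols <- relaxation_weighting_table(envs = envs[c("csf", "agar")])
  rw <- if (rw_source == "reference") {
    cbind(reference_weightings(), extra_cols)
  } else {
    relaxation_weighting_table(envs = envs)
  }
  .spin32_cache[[key]] <- rw
  rw
}

#' Render a sodium image from a labeled phantom
#'
#' Each voxel receives the relaxation-weighted sodium signal of its region's
#' tissue state, scaled relative to the agar reference (64 mM x the agar
#' weighting, or x 1 with `ideal_reference = TRUE`), then the image is
#' blurred with the sequence PSF and Rician noise is added (magnitude of a
#' complex Gaussian perturbation); all randomness is seeded.
#'
#' @param phantom result of [build_phantom()]
#' @param sequence one of "NaDW", "NaPACMAN", "NaSIRFLA"
#' @param rw weighting matrix from [full_weightings()]
#' @param psf `"saline"` (T2* = 53 ms kernel on the phantom grid),
#'   `"delta"` (no blurring), or a kernel array
#' @param noise_sigma Rician sigma in agar-relative units (overrides the
#'   spec value if given)
#' @param seed noise seed (defaults to the phantom seed)
#' @param ideal_reference if TRUE the agar reference is treated as loss-free
#'   (division by 64 mM only)
#' @param concs an [sodium_concentrations()]
#' @return 3D array of agar-relative intensities with attribute
#'   `true_intensity` (named per-region noiseless, unblurred values)
#' @export
render_sodium_image <- function(phantom, sequence,
                                rw = full_weightings(),
                                psf = c("saline", "delta"),
                                noise_sigma = NULL, seed = NULL,
                                ideal_reference = FALSE,
                                concs = sodium_concentrations()) {
  stopifnot(sequence %in% rownames(rw))
  truth <- phantom$truth
  if (!all(truth$tissue_state %in% c("control", "nawm", "lesion", "csf",
                                     "agar")))
    stop("unknown tissue state in phantom truth")
  sigma <- if (is.null(noise_sigma)) phantom$spec$noise_sigma else noise_sigma
  seed <- if (is.null(seed)) phantom$spec$seed else seed
  denom <- concs$c_agar * (if (ideal_reference) 1 else rw[sequence, "agar"])
  img <- array(0, dim(phantom$labels))
  vals <- setNames(numeric(nrow(truth)), truth$region)
  for (i in seq_len(nrow(truth))) {
    v <- .state_signal(truth$tissue_state[i], sequence, rw, concs) / denom
    vals[i] <- v
    img[phantom$labels == truth$label[i]] <- v
  }
  if (is.character(psf)) {
    psf <- match.arg(psf)
    if (psf == "saline") {
      ker <- psf_kernel(psf_params(t2star_ms = 53,
                                   voxel_size_mm = phantom$spec$voxel_size_mm,
                                   grid_shape = dim(phantom$labels)))
      img <- fft_convolve(img, ker, scale = "dc")
    }
  } else {
    img <- fft_convolve(img, psf, scale = "dc")
  }
  if (sigma > 0) {
    set.seed(seed)
    nr <- array(rnorm(length(img), 0, sigma), dim(img))
    ni <- array(rnorm(length(img), 0, sigma), dim(img))
    img <- sqrt((img + nr)^2 + ni^2)
  }
  attr(img, "true_intensity") <- vals
  img
}

#' Write a phantom and its rendered images to disk
#'
#' Label map and images as NIfTI-1, ground truth as JSON.
#'
#' @param phantom result of [build_phantom()]
#' @param dir output directory (created if needed)
#' @param sequences sequences to render
#' @param ... passed to [render_sodium_image()]
#' @return invisibly, the written file paths
#' @export
write_phantom <- function(phantom, dir,
                          sequences = c("NaDW", "NaPACMAN", "NaSIRFLA"),
                          ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pix <- phantom$spec$voxel_size_mm
  as_nifti <- function(arr) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- pix
    im
  }
  paths <- character()
  p <- file.path(dir, "labels.nii.gz")
  RNifti::writeNifti(as_nifti(phantom$labels), p); paths <- c(paths, p)
  for (sq in sequences) {
    img <- render_sodium_image(phantom, sq, ...)
    attr(img, "true_intensity") <- NULL
    p <- file.path(dir, paste0(tolower(sq), ".nii.gz"))
    RNifti::writeNifti(as_nifti(img), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(phantom$truth, p, dataframe = "rows", digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
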