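# PSF kernel construction, CSF mask expansion, ROI statistics and
# agar-referenced TSC calibration.

#' Point-spread-function parameters for a center-out sodium readout
#'
#' The k-space signal of a center-out (radial-equivalent) acquisition is
#' apodized by T2* decay during the readout: `exp(-t(k)/T2*)` with the
#' acquisition time `t(k)` linear in normalized |k| over `readout_ms`.
#' The image-domain kernel is the inverse transform of this apodization.
#'
#' @param t2star_ms T2* of the imaged medium in ms (saline default 53)
#' @param readout_ms readout duration in ms (default 10)
#' @param voxel_size_mm voxel dimensions (dx, dy, dz) in mm; anisotropic
#'   voxels are allowed (e.g. 3.2 x 3.2 x 6.4)
#' @param grid_shape integer image grid dimensions
#' @return object of class `na_psf_params`
#' @export
psf_params <- function(t2star_ms = 53, readout_ms = 10,
                       voxel_size_mm = c(3.2, 3.2, 6.4),
                       grid_shape = c(32L, 32L, 16L)) {
  if (t2star_ms <= 0) stop("t2star_ms must be > 0")
  if (readout_ms < 0) stop("readout_ms must be >= 0")
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive lengths")
  if (length(grid_shape) != 3 || any(grid_shape < 2))
    stop("grid_shape must be three dimensions >= 2")
  structure(list(t2star_ms = t2star_ms, readout_ms = readout_ms,
                 voxel_size_mm = voxel_size_mm,
                 grid_shape = as.integer(grid_shape)),
            class = "na_psf_params")
}

# FFT frequency coordinates (cycles per unit), unshifted order
.fft_freq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * d)
  k
}

#' Build the PSF kernel volume
#'
#' Returns the image-domain kernel on the requested grid, peak-normalized
#' (center value exactly 1).  The k-space apodization is radially symmetric
#' in the ellipsoid-normalized radius (per-axis Nyquist extent), so the
#' kernel reflects the anisotropic voxel footprint.  With `t2star_ms = Inf`
#' there is no apodization and the kernel is a discrete delta.
#'
#' @param p an [psf_params()]
#' @return 3D array with attribute `sum` (kernel integral, i.e. DC gain
#'   relative to the peak-normalized kernel)
#' @export
psf_kernel <- function(p) {
  stopifnot(inherits(p, "na_psf_params"))
  n <- p$grid_shape
  kx <- .fft_freq(n[1], p$voxel_size_mm[1])
  ky <- .fft_freq(n[2], p$voxel_size_mm[2])
  kz <- .fft_freq(n[3], p$voxel_size_mm[3])
  kmax <- 1 / (2 * p$voxel_size_mm)   # per-axis Nyquist extent
  r <- sqrt(outer(outer((kx / kmax[1])^2, (ky / kmax[2])^2, `+`),
                  (kz / kmax[3])^2, `+`))
  apod <- if (is.infinite(p$t2star_ms)) {
    array(1, n)
  } else {
    exp(-(p$readout_ms * r) / p$t2star_ms)
  }
  ker <- Re(fft(apod, inverse = TRUE)) / prod(n)
  # center the peak: unshifted IFFT places the peak at [1,1,1]
  ker <- .fft_shift(ker)
  ker <- ker / max(ker)
  attr(ker, "sum") <- sum(ker)
  attr(ker, "voxel_size_mm") <- p$voxel_size_mm
  ker
}

.fft_shift <- function(x) {
  # move the origin (index 1) to the grid center floor(n/2) + 1
  n <- dim(x)
  idx <- lapply(n, function(m)
    c(seq(m - floor(m / 2) + 1, m), seq_len(m - floor(m / 2))))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

# Zero-padded FFT convolution of a volume with a kernel defined on a grid of
# the same voxel size.  `scale = "dc"` normalizes the kernel to unit sum
# (DC gain 1, as used for partial-volume fractions); `scale = "none"` uses
# the kernel as given.
fft_convolve <- function(vol, kernel, scale = c("dc", "none")) {
  scale <- match.arg(scale)
  if (length(dim(vol)) != 3 || length(dim(kernel)) != 3)
    stop("vol and kernel must be 3D arrays")
  k <- kernel
  if (scale == "dc") k <- k / sum(k)
  nv <- dim(vol); nk <- dim(k)
  np <- nv + nk  # zero-padding avoids wrap-around
  vp <- array(0, np); vp[seq_len(nv[1]), seq_len(nv[2]), seq_len(nv[3])] <- vol
  kp <- array(0, np)
  # place kernel center at the origin of the padded grid (wrapped)
  ctr <- floor(nk / 2) + 1
  ix <- ((seq_len(nk[1]) - ctr[1]) %% np[1]) + 1
  iy <- ((seq_len(nk[2]) - ctr[2]) %% np[2]) + 1
  iz <- ((seq_len(nk[3]) - ctr[3]) %% np[3]) + 1
  kp[ix, iy, iz] <- k
  out <- Re(fft(fft(vp) * fft(kp), inverse = TRUE)) / prod(np)
  out[seq_len(nv[1]), seq_len(nv[2]), seq_len(nv[3])]
}

#' Expand a CSF mask by the sodium PSF
#'
#' Convolves a binary CSF mask with the (DC-gain-normalized) PSF kernel and
#' marks every voxel where the convolution exceeds `threshold` — i.e. where
#' smeared CSF contributes more than `threshold` of its full value.  The
#' result is always a superset of the input mask.
#'
#' @param csf_mask binary 3D array (or `niftiImage`)
#' @param kernel PSF kernel from [psf_kernel()]
#' @param threshold partial-volume fraction threshold (default 0.025)
#' @return logical 3D array
#' @export
expand_csf_mask <- function(csf_mask, kernel, threshold = 0.025) {
  m <- as.array(csf_mask)
  if (!all(m %in% c(0, 1))) stop("csf_mask must be binary")
  if (!identical(length(dim(m)), 3L)) stop("csf_mask must be 3D")
  conv <- fft_convolve(m, kernel, scale = "dc")
  (conv > threshold) | (m > 0)
}

#' Effective CSF signal contribution at a partial-volume threshold
#'
#' A voxel just below the mask-expansion threshold receives at most
#' `threshold` of the full CSF signal, i.e. `threshold * c_csf`
#' mmol/L-tissue worth of signal (0.025 x 150 mM = 3.75).
#'
#' @param threshold partial-volume fraction in [0, 1]
#' @param c_csf CSF sodium concentration in mM (default 150)
#' @return mmol/L-tissue
#' @export
effective_csf_contribution <- function(threshold = 0.025, c_csf = 150) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  threshold * c_csf
}

#' ROI statistics with exclusion mask
#'
#' Mean and SD of image intensity over the ROI voxels not covered by the
#' exclusion mask (e.g. the PSF-expanded CSF mask), with retained/excluded
#' voxel counts.
#'
#' @param image 3D array of intensities
#' @param roi_mask binary 3D array
#' @param exclusion_mask optional binary 3D array
#' @param label region label carried through to the output
#' @return object of class `na_roi_stats`: list with `label`, `mean`, `sd`,
#'   `n_voxels`, `n_excluded`
#' @export
roi_statistics <- function(image, roi_mask, exclusion_mask = NULL,
                           label = "roi") {
  img <- as.array(image); roi <- as.array(roi_mask) > 0
  if (!identical(dim(img), dim(roi))) stop("image/roi dimensions differ")
  excl <- if (is.null(exclusion_mask)) array(FALSE, dim(img))
          else as.array(exclusion_mask) > 0
  if (!identical(dim(img), dim(excl)))
    stop("image/exclusion dimensions differ")
  keep <- roi & !excl
  n_excl <- sum(roi & excl)
  if (!any(keep))
    stop("ROI '", label, "' retained no voxels outside the exclusion mask")
  vals <- img[keep]
  structure(list(label = label, mean = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else 0,
                 n_voxels = sum(keep), n_excluded = n_excl),
            class = "na_roi_stats")
}

#' Convert agar-relative intensity to tissue sodium concentration
#'
#' Image intensities are expressed relative to the 64 mM agar reference
#' tubes; multiplying by the reference concentration yields TSC in
#' mmol/L-tissue (0.62 -> 39.7, printed 40; 0.83 -> 53.1, printed 53).
#'
#' @param relative_intensity agar-relative intensity (>= 0)
#' @param c_agar reference concentration in mM (default 64)
#' @return TSC in mmol/L-tissue
#' @export
intensity_to_tsc <- function(relative_intensity, c_agar = 64) {
  if (any(relative_intensity < 0)) stop("relative_intensity must be >= 0")
  relative_intensity * c_agar
}
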