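# Multi-compartment tissue sodium model for white matter.
#
# Tissue is partitioned into myelin water, intracellular water, extracellular
# water, edema (free) water, and non-water solids.  Volume fractions are
# referenced to 1 L (= 1 g at unit density) of healthy tissue; demyelination
# removes myelin water plus its associated solids (atrophy) and edema adds
# free water, after which fractions are renormalized to the new volume.

#' Compartment sodium concentrations
#'
#' Defaults: intracellular 12.5 mM, extracellular 145 mM, CSF 150 mM, agar
#' reference 64 mM, edema 145 mM (extracellular-like free water).  The myelin
#' water concentration is derived as the mean of intra and extra (the intra-
#' and extracellular layers within the myelin wraps have equal thickness),
#' 78.75 mM under the defaults.
#'
#' @param c_intra,c_extra,c_edema,c_csf,c_agar concentrations in mM
#' @param c_myelin myelin water concentration in mM; default
#'   [myelin_water_concentration()] of intra and extra
#' @return object of class `na_concentrations`
#' @export
sodium_concentrations <- function(c_intra = 12.5, c_extra = 145,
                                  c_edema = 145, c_csf = 150, c_agar = 64,
                                  c_myelin = NULL) {
  vals <- c(c_intra, c_extra, c_edema, c_csf, c_agar)
  if (any(vals < 0)) stop("concentrations must be >= 0")
  if (is.null(c_myelin))
    c_myelin <- myelin_water_concentration(c_intra, c_extra)
  structure(list(c_intra = c_intra, c_extra = c_extra, c_myelin = c_myelin,
                 c_edema = c_edema, c_csf = c_csf, c_agar = c_agar),
            class = "na_concentrations")
}

#' Average sodium concentration of myelin water
#'
#' The myelin sheath consists of thin alternating intra- and extracellular
#' water layers of equal thickness, so the average myelin water sodium
#' concentration is the arithmetic mean of the two: (12.5 + 145)/2 =
#' 78.75 mM under the default concentrations.
#'
#' @param c_intra,c_extra intra-/extracellular sodium concentrations (mM)
#' @return concentration in mM
#' @export
#' @examples
#' myelin_water_concentration(12.5, 145)  # 78.75
myelin_water_concentration <- function(c_intra, c_extra) {
  if (c_intra < 0 || c_extra < 0) stop("concentrations must be >= 0")
  (c_intra + c_extra) / 2
}

.new_volumes <- function(v_myelin_water, v_intra, v_extra, v_edema, v_solids,
                         volume_scale = 1) {
  v <- c(v_myelin_water, v_intra, v_extra, v_edema, v_solids)
  if (any(v < -1e-12)) stop("volume fractions must be >= 0")
  if (abs(sum(v) - 1) > 1e-9) stop("volume fractions must sum to 1")
  structure(list(v_myelin_water = v_myelin_water, v_intra = v_intra,
                 v_extra = v_extra, v_edema = v_edema, v_solids = v_solids,
                 volume_scale = volume_scale),
            class = "na_volumes")
}

#' @export
print.na_volumes <- function(x, ...) {
  cat(sprintf(
    paste0("<na_volumes>  myelin water %.4f | intra %.4f | extra %.4f | ",
           "edema %.4f | solids %.4f  (volume scale %.4f)\n"),
    x$v_myelin_water, x$v_intra, x$v_extra, x$v_edema, x$v_solids,
    x$volume_scale))
  invisible(x)
}

#' Healthy control white matter compartment volumes
#'
#' Default fractions: myelin water 0.0865, extracellular water 0.172,
#' intracellular water 0.495, no edema, solids 0.2465.  These round to the
#' 9% / 17% / 50% water fractions of healthy white matter; the extra digits
#' are back-solved so the compartment sodium contributions reproduce
#' 6.8 / 24.9 / 6.2 mmol/L-tissue (total 37.9) exactly at the default
#' concentrations.
#'
#' @param v_myelin_water,v_extra,v_intra water volume fractions
#' @return an `na_volumes` object
#' @export
#' @examples
#' sodium_contributions(control_volumes(), sodium_concentrations())
control_volumes <- function(v_myelin_water = 0.0865, v_extra = 0.172,
                            v_intra = 0.495) {
  .new_volumes(v_myelin_water, v_intra, v_extra, 0,
               1 - v_myelin_water - v_intra - v_extra, volume_scale = 1)
}

#' Tissue water parameters (MWF and WC)
#'
#' @param MWF myelin water fraction: myelin water / total water
#' @param WC water content: total water volume fraction of tissue
#' @return object of class `na_tissue_params`
#' @export
tissue_params <- function(MWF, WC) {
  if (!(MWF >= 0 && MWF < 1)) stop("MWF must be in [0, 1)")
  if (!(WC > 0 && WC < 1)) stop("WC must be in (0, 1)")
  structure(list(MWF = MWF, WC = WC), class = "na_tissue_params")
}

#' Compartment volumes from MWF and water content
#'
#' Given a myelin water fraction and a total water content, with the
#' extracellular fraction held fixed, the myelin water volume is `MWF * WC`,
#' intracellular water takes the remaining water, and solids the remaining
#' tissue volume.
#'
#' @param params an [tissue_params()]
#' @param v_extra_fixed extracellular water volume fraction (default 0.172)
#' @return an `na_volumes` object
#' @export
#' @examples
#' volumes_from_mwf_wc(tissue_params(MWF = 0.20, WC = 0.692))
volumes_from_mwf_wc <- function(params, v_extra_fixed = 0.172) {
  stopifnot(inherits(params, "na_tissue_params"))
  if (v_extra_fixed > params$WC)
    stop("v_extra_fixed cannot exceed the water content")
  v_m <- params$MWF * params$WC
  v_i <- params$WC - v_m - v_extra_fixed
  if (v_i < 0)
    stop("inconsistent MWF/WC pair: negative intracellular volume")
  .new_volumes(v_m, v_i, v_extra_fixed, 0, 1 - params$WC)
}

#' MWF and WC implied by a set of compartment volumes
#' @param vols an `na_volumes` object
#' @return an `na_tissue_params`
#' @export
mwf_wc_of <- function(vols) {
  stopifnot(inherits(vols, "na_volumes"))
  water <- vols$v_myelin_water + vols$v_intra + vols$v_extra + vols$v_edema
  tissue_params(MWF = vols$v_myelin_water / water, WC = water)
}

#' Sodium contribution of each compartment
#'
#' Each water compartment contributes `volume fraction x concentration`
#' mmol of sodium to 1 L of tissue; the tissue sodium concentration (TSC)
#' is their sum.
#'
#' @param vols an `na_volumes` object
#' @param concs an [sodium_concentrations()]
#' @return object of class `na_contributions` with `q_myelin`, `q_intra`,
#'   `q_extra`, `q_edema` and `tsc` in mmol/L-tissue
#' @export
sodium_contributions <- function(vols, concs = sodium_concentrations()) {
  stopifnot(inherits(vols, "na_volumes"), inherits(concs, "na_concentrations"))
  q <- list(q_myelin = vols$v_myelin_water * concs$c_myelin,
            q_intra = vols$v_intra * concs$c_intra,
            q_extra = vols$v_extra * concs$c_extra,
            q_edema = vols$v_edema * concs$c_edema)
  q$tsc <- q$q_myelin + q$q_intra + q$q_extra + q$q_edema
  structure(q, class = "na_contributions")
}

#' @export
print.na_contributions <- function(x, ...) {
  cat(sprintf(
    paste0("<na_contributions mmol/L-tissue>  myelin %.2f | intra %.2f | ",
           "extra %.2f | edema %.2f | TSC %.2f\n"),
    x$q_myelin, x$q_intra, x$q_extra, x$q_edema, x$tsc))
  invisible(x)
}

#' Demyelination / edema transform parameters
#'
#' @param retention fraction of myelin water retained (1 = no demyelination)
#' @param k myelin solids volume per unit myelin water volume (default 1.5,
#'   i.e. myelin is ~40% water); lost myelin water takes `k` times its
#'   volume of solids with it (tissue atrophy)
#' @param edema_added absolute free-water volume added per original liter
#'   of tissue
#' @return object of class `na_demyelination`
#' @export
demyelination_params <- function(retention, k = 1.5, edema_added = 0) {
  if (!(retention >= 0 && retention <= 1))
    stop("retention must be in [0, 1]")
  if (k < 0 || edema_added < 0) stop("k and edema_added must be >= 0")
  structure(list(retention = retention, k = k, edema_added = edema_added),
            class = "na_demyelination")
}

#' Apply demyelination (with atrophy) and edema to a tissue state
#'
#' Removes `(1 - retention)` of the myelin water together with `k` times
#' that volume of myelin solids (atrophy), adds `edema_added` liters of free
#' water per original liter, keeps the absolute intra- and extracellular
#' volumes unchanged, and renormalizes all fractions to the new total
#' volume.  The attribute `volume_change` reports `V'/V - 1` (e.g. -0.043
#' for the default NAWM state).
#'
#' @param vols an `na_volumes` object
#' @param p an [demyelination_params()]
#' @return an `na_volumes` object with attribute `volume_change`
#' @export
#' @examples
#' nawm <- apply_demyelination(control_volumes(),
#'                             demyelination_params(retention = 0.80))
#' attr(nawm, "volume_change")  # about -0.043
apply_demyelination <- function(vols, p) {
  stopifnot(inherits(vols, "na_volumes"), inherits(p, "na_demyelination"))
  removed_water <- (1 - p$retention) * vols$v_myelin_water
  removed_solids <- p$k * removed_water
  if (removed_solids > vols$v_solids + 1e-12)
    stop("demyelination removes more solids than available")
  rel_new <- 1 - removed_water - removed_solids + p$edema_added
  out <- .new_volumes(
    v_myelin_water = p$retention * vols$v_myelin_water / rel_new,
    v_intra = vols$v_intra / rel_new,
    v_extra = vols$v_extra / rel_new,
    v_edema = (vols$v_edema + p$edema_added) / rel_new,
    v_solids = (vols$v_solids - removed_solids) / rel_new,
    volume_scale = vols$volume_scale * rel_new)
  attr(out, "volume_change") <- rel_new - 1
  out
}

#' Percent TSC difference between two tissue states
#'
#' @param state,ref `na_contributions` objects
#' @return `100 * (state$tsc / ref$tsc - 1)`
#' @export
tsc_percent_difference <- function(state, ref) {
  stopifnot(inherits(state, "na_contributions"),
            inherits(ref, "na_contributions"))
  if (ref$tsc <= 0) stop("reference TSC must be > 0")
  100 * (state$tsc / ref$tsc - 1)
}

#' Preset tissue states
#'
#' `control`: healthy white matter ([control_volumes()]).  `nawm`:
#' demyelination with atrophy (myelin retention 0.80, solids:water 1.5, no
#' edema; 4.3% volume loss).  `lesion`: stronger demyelination plus edema
#' (retention 0.45, 0.089 L free water added per original liter).
#'
#' @param state one of "control", "nawm", "lesion"
#' @param nawm_retention,lesion_retention myelin water retention per state
#' @param k myelin solids per unit myelin water
#' @param lesion_edema free water added in the lesion state (L per original L)
#' @return an `na_volumes` object
#' @export
#' @examples
#' sodium_contributions(tissue_state("lesion"))
tissue_state <- function(state = c("control", "nawm", "lesion"),
                         nawm_retention = 0.80, lesion_retention = 0.45,
                         k = 1.5, lesion_edema = 0.089) {
  state <- match.arg(state)
  ctrl <- control_volumes()
  switch(state,
    control = ctrl,
    nawm = apply_demyelination(ctrl, demyelination_params(nawm_retention, k)),
    lesion = apply_demyelination(
      ctrl, demyelination_params(lesion_retention, k, lesion_edema)))
}
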