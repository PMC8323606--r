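# Seeded cohort simulation: per-subject ROI intensity tables.

#' Simulate a control/patient cohort of ROI sodium intensities
#'
#' Generates per-subject, per-region, per-sequence mean agar-relative
#' intensities from the forward contrast model.  Controls carry the control
#' tissue state in all white matter regions; patients carry the NAWM state
#' in white matter regions plus a lesion region.  Between-subject biology is
#' a multiplicative Gaussian factor per subject, shared across that
#' subject's regions (sd `between_sd`), which also induces the intra-patient
#' correlation the paired analyses rely on; measurement noise is an
#' additive Gaussian perturbation of
#' the ROI mean (sd `noise_sd`, the ROI-averaged Rician noise in the
#' high-SNR limit).  Age and sex covariates are drawn per subject.
#'
#' @param n_controls,n_patients subjects per group (>= 2)
#' @param sequences sequences to simulate
#' @param regions white matter regions measured per subject
#' @param effect named list of multiplicative lesion effects per sequence
#'   applied on top of the modeled lesion contrast (default 1 = model only);
#'   e.g. `list(NaDW = 1.04)` inflates the NaDW lesion mean by 4%
#' @param between_sd between-subject multiplicative sd (default 0.032,
#'   which reproduces a control-WM sd of about 0.02 on the density-weighted
#'   sequence at the default contrast)
#' @param lesion_severity_sd per-patient lognormal sd of a severity factor
#'   scaling the lesion-vs-NAWM contrast of all sequences jointly; this is
#'   what spreads patients along the lesion-contrast regression lines
#' @param noise_sd additive measurement sd on ROI means (agar-relative)
#' @param age_range,p_female covariate generation settings
#' @param seed integer seed fixing all randomness
#' @param rw weighting matrix from [full_weightings()]
#' @return data.frame (tidy): subject, group, region, tissue_state,
#'   sequence, intensity, age, sex
#' @export
simulate_cohort <- function(n_controls = 9, n_patients = 30,
                            sequences = c("NaDW", "NaPACMAN", "NaSIRFLA"),
                            regions = c("scc", "plic", "alic"),
                            effect = list(),
                            between_sd = 0.032, lesion_severity_sd = 0.35,
                            noise_sd = 0.005,
                            age_range = c(21, 75), p_female = 0.64,
                            seed = 1L,
                            rw = full_weightings()) {
  stopifnot(n_controls >= 2, n_patients >= 2)
  set.seed(seed)
  concs <- sodium_concentrations()
  denom <- unname(concs$c_agar * rw[sequences, "agar"])
  names(denom) <- sequences
  base <- sapply(sequences, function(sq) c(
    control = .state_signal("control", sq, rw, concs),
    nawm = .state_signal("nawm", sq, rw, concs),
    lesion = .state_signal("lesion", sq, rw, concs)) / denom[[sq]])

  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n_controls + n_patients)),
    group = rep(c("control", "patient"), c(n_controls, n_patients)))
  subjects$age <- round(runif(nrow(subjects), age_range[1], age_range[2]))
  subjects$sex <- rbinom(nrow(subjects), 1, p_female)  # 1 = female

  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    grp <- subjects$group[i]
    bio <- exp(rnorm(1, 0, between_sd))     # subject-level biology factor
    sev <- exp(rnorm(1, 0, lesion_severity_sd))  # lesion severity factor
    meas <- c(regions, if (grp == "patient") "lesion")
    for (reg in meas) {
      state <- if (reg == "lesion") "lesion"
               else if (grp == "patient") "nawm" else "control"
      for (sq in sequences) {
        mu <- if (reg == "lesion") {
          # severity scales the lesion-vs-NAWM contrast of all sequences
          base["nawm", sq] *
            (1 + sev * (base["lesion", sq] / base["nawm", sq] - 1)) * bio
        } else {
          base[state, sq] * bio
        }
        if (reg == "lesion" && !is.null(effect[[sq]]))
          mu <- mu * effect[[sq]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjects$subject[i], group = grp, region = reg,
          tissue_state = state, sequence = sq,
          intensity = mu + rnorm(1, 0, noise_sd),
          age = subjects$age[i], sex = subjects$sex[i])
      }
    }
  }
  do.call(rbind, rows)
}

#' Lesion effect multiplier for a target percent elevation over control
#'
#' Returns the multiplicative `effect` entry for [simulate_cohort()] that
#' places the expected lesion mean at `percent` above the control white
#' matter mean for the given sequence (e.g. +35 for the density-weighted
#' lesion elevation).
#'
#' @param percent target lesion elevation over control WM, in percent
#' @param sequence sequence name
#' @param rw weighting matrix from [full_weightings()]
#' @return numeric multiplier
#' @export
lesion_effect_multiplier <- function(percent, sequence = "NaDW",
                                     rw = full_weightings()) {
  concs <- sodium_concentrations()
  ctrl <- .state_signal("control", sequence, rw, concs)
  les <- .state_signal("lesion", sequence, rw, concs)
  (1 + percent / 100) * ctrl / les
}
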