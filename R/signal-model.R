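# Relative signal contributions: compartment sodium x relaxation weighting.

#' Reference relaxation weightings of the three sequences
#'
#' The fixed per-compartment relaxation weightings (signal relative to an
#' ideal loss-free acquisition) for the three sodium sequences, as used for
#' the reference contrast predictions.  Rows: sequences; columns:
#' environments (intra, extra, myelin, edema).
#'
#' @return 3 x 4 numeric matrix
#' @export
reference_weightings <- function() {
  matrix(c(0.95, 0.95, 0.85, 0.96,
           0.35, 0.35, 0.01, 0.40,
           0.45, 0.45, 0.61, 0.10),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("NaDW", "NaPACMAN", "NaSIRFLA"),
                         c("intra", "extra", "myelin", "edema")))
}

#' Relative per-compartment signal contributions for one tissue state
#'
#' Each compartment's sodium contribution (mmol/L-tissue) is weighted by the
#' sequence's relaxation weighting for that compartment and expressed in
#' proportion to the healthy-control intracellular signal
#' `ref_intra_signal = q_intra(control) * RW[intra]`.
#'
#' @param contribs an `na_contributions` object for the tissue state
#' @param rw named numeric vector of relaxation weightings with entries
#'   `intra`, `extra`, `myelin`, `edema`
#' @param ref_intra_signal reference intracellular weighted signal (> 0)
#' @return named numeric vector (intra, extra, myelin, edema) plus `total`
#' @export
relative_contributions <- function(contribs, rw, ref_intra_signal) {
  stopifnot(inherits(contribs, "na_contributions"))
  need <- c("intra", "extra", "myelin", "edema")
  if (!all(need %in% names(rw)))
    stop("missing relaxation weighting entries: ",
         paste(setdiff(need, names(rw)), collapse = ", "))
  if (ref_intra_signal <= 0) stop("ref_intra_signal must be > 0")
  rel <- c(intra = contribs$q_intra * rw[["intra"]],
           extra = contribs$q_extra * rw[["extra"]],
           myelin = contribs$q_myelin * rw[["myelin"]],
           edema = contribs$q_edema * rw[["edema"]]) / ref_intra_signal
  c(rel, total = sum(rel))
}

#' Percent signal difference of a tissue state vs control
#'
#' @param total_state,total_control summed relative signals
#' @return `100 * (total_state / total_control - 1)`
#' @export
percent_signal_difference <- function(total_state, total_control) {
  if (total_control <= 0) stop("control total must be > 0")
  100 * (total_state / total_control - 1)
}

#' Full relative-signal table (sequences x tissue states x compartments)
#'
#' Builds the complete contrast prediction: for every sequence and tissue
#' state, the per-compartment relative signal contributions (normalized to
#' the control intracellular entry of that sequence), their total, and the
#' percent difference of the total vs the control state.
#'
#' @param tissue_states named list of `na_volumes` objects; must contain
#'   `control` (default: the three [tissue_state()] presets)
#' @param rw_source `"reference"` uses [reference_weightings()];
#'   `"simulated"` runs the spin-3/2 simulator on `envs`
#' @param concs an [sodium_concentrations()]
#' @param seqs sequences used when `rw_source = "simulated"`
#' @param envs environments used when `rw_source = "simulated"`; must be
#'   named intra, extra, myelin, edema
#' @return data.frame with columns sequence, state, intra, extra, myelin,
#'   edema, total, pct_diff plus printed-precision columns (2 dp entries,
#'   integer percent)
#' @export
#' @examples
#' build_contrast_table()
build_contrast_table <- function(tissue_states = list(control = tissue_state("control"),
                                              nawm = tissue_state("nawm"),
                                              lesion = tissue_state("lesion")),
                         rw_source = c("reference", "simulated"),
                         concs = sodium_concentrations(),
                         seqs = sequence_presets(),
                         envs = default_environments()) {
  rw_source <- match.arg(rw_source)
  if (!"control" %in% names(tissue_states))
    stop("tissue_states must include a 'control' state")
  rw <- if (rw_source == "reference") {
    reference_weightings()
  } else {
    relaxation_weighting_table(seqs, envs[c("intra", "extra", "myelin",
                                            "edema")])
  }
  contribs <- lapply(tissue_states, sodium_contributions, concs = concs)
  out <- list()
  for (sq in rownames(rw)) {
    ref <- contribs$control$q_intra * rw[sq, "intra"]
    rels <- lapply(contribs, relative_contributions, rw = rw[sq, ],
                   ref_intra_signal = ref)
    for (st in names(rels)) {
      r <- rels[[st]]
      out[[length(out) + 1L]] <- data.frame(
        sequence = sq, state = st,
        intra = r[["intra"]], extra = r[["extra"]], myelin = r[["myelin"]],
        edema = r[["edema"]], total = r[["total"]],
        pct_diff = percent_signal_difference(r[["total"]],
                                             rels$control[["total"]]))
    }
  }
  out <- do.call(rbind, out)
  for (col in c("intra", "extra", "myelin", "edema", "total"))
    out[[paste0(col, "_printed")]] <- round(out[[col]], 2)
  out$pct_diff_printed <- ifelse(
    out$state == "control", NA_real_,
    ifelse(abs(out$pct_diff) < 10, round(out$pct_diff, 1),
           round(out$pct_diff)))
  out
}
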