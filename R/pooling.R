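# Bench-side pooling arithmetic: plate normalization volumes, equimolar
# subpooling, and the sequencing-run capacity model.

#' Plate normalization volumes (6 / 3 / 1.5 ul rule)
#'
#' Per-well pooling volumes relative to the plate mean concentration:
#' 6 ul from wells below half the mean, 1.5 ul from wells above twice the
#' mean, 3 ul otherwise. The comparisons are strict, so boundary wells
#' (exactly half or twice the mean) receive 3 ul. Scale-invariant by
#' construction.
#'
#' @param concs data.frame (`well_id`, `conc` in ng/ul) or a numeric
#'   vector of concentrations.
#' @return data.frame `well_id`, `conc`, `volume_ul`, with the plate mean
#'   as attribute `mean_conc`.
#' @export
normalization_volumes <- function(concs) {
  if (is.numeric(concs))
    concs <- data.frame(well_id = sprintf("W%02d", seq_along(concs)),
                        conc = concs)
  if (any(concs$conc < 0)) stop2("concentrations must be non-negative")
  m <- mean(concs$conc)
  if (m == 0) stop2("all concentrations are zero; the volume rule is undefined")
  vol <- ifelse(concs$conc < m / 2, 6,
                ifelse(concs$conc > 2 * m, 1.5, 3))
  structure(data.frame(well_id = concs$well_id, conc = concs$conc,
                       volume_ul = vol, stringsAsFactors = FALSE),
            mean_conc = m)
}

#' Equimolar subpool volumes
#'
#' Volumes delivering `target_mass` from each subpool, so that every plate
#' contributes equal mass -- equal molarity for same-length amplicons.
#'
#' @param subpool_concs data.frame (`subpool_id`, `conc`) or numeric
#'   vector (ng/ul).
#' @param target_mass Mass per subpool (ng).
#' @return data.frame `subpool_id`, `conc`, `volume_ul`, `mass_ng`.
#' @export
equimolar_subpool_volumes <- function(subpool_concs, target_mass) {
  if (is.numeric(subpool_concs))
    subpool_concs <- data.frame(
      subpool_id = sprintf("P%02d", seq_along(subpool_concs)),
      conc = subpool_concs)
  zero <- subpool_concs$conc <= 0
  if (any(zero))
    stop2(sprintf("subpool(s) with zero concentration: %s",
                  paste(subpool_concs$subpool_id[zero], collapse = ", ")))
  if (target_mass <= 0) stop2("target mass must be positive")
  data.frame(subpool_id = subpool_concs$subpool_id,
             conc = subpool_concs$conc,
             volume_ul = target_mass / subpool_concs$conc,
             mass_ng = target_mass, stringsAsFactors = FALSE)
}

#' Sequencing-run sample capacity under coverage skew
#'
#' Expected pairs consumed per sample are the coverage target times the
#' skew expectation (with the default model, 1000 x (0.1*10 + 0.1*0.1 +
#' 0.8*1) = 1810); capacity is the floor of total pairs over that
#' expectation. Monotone in both arguments.
#'
#' @param total_read_pairs Total pairs the run yields.
#' @param coverage A [coverage_model()].
#' @return Integer number of samples.
#' @export
run_capacity <- function(total_read_pairs, coverage = coverage_model()) {
  if (total_read_pairs <= 0) stop2("total_read_pairs must be positive")
  expected <- coverage$target_pairs_per_sample *
    sum(coverage$skew$fraction * coverage$skew$multiplier)
  as.integer(floor(total_read_pairs / expected))
}
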