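# Bundled published reference tables for 15 of the world's worst invasive
# insect pests: per-species potential range areas and range-change indices
# under one current and four future (2100) scenarios, and the global areas
# of increased/decreased total habitat suitability. The four future
# scenarios combine two forcing pathways (126 = optimistic SSP1-2.6,
# 585 = pessimistic SSP5-8.5) with two general circulation models
# (F = FIO-ESM-2-0, M = MPI-ESM1-2-HR).

#' Published range-dynamics table for 15 invasive insect pests
#'
#' Potential range areas (million km^2) under the current, F126, F585, M126
#' and M585 scenarios and the corresponding range ratio (RRI) and range
#' similarity (RSI) indices, one row per species.
#'
#' @param long If `TRUE`, returns the long form used by
#'   [summarize_scenarios()]: columns `species`, `scenario`, `RRI`, `RSI`,
#'   `RFS` (future range area, million km^2) and `RCS` (current area).
#' @return A data frame (wide Table-style form, or long form).
#' @export
iip_range_dynamics <- function(long = FALSE) {
  path <- system.file("extdata", "iip_range_dynamics.csv", package = "rangedyn")
  wide <- utils::read.csv(path, check.names = FALSE)
  if (!long) return(wide)
  scen <- c("F126", "F585", "M126", "M585")
  do.call(rbind, lapply(scen, function(s) data.frame(
    species = wide$species, scenario = s,
    RRI = wide[[paste0(s, "RRI")]], RSI = wide[[paste0(s, "RSI")]],
    RFS = wide[[paste0(s, "PR")]], RCS = wide$CurPR)))
}

#' Published areas of increased/decreased total habitat suitability
#'
#' Global areas (million km^2) where the summed habitat suitability of the
#' 15 species increases or decreases between the current scenario and each
#' future scenario.
#'
#' @return A data frame with columns `scenario`, `increased_area_mkm2`,
#'   `decreased_area_mkm2`.
#' @export
iip_suitability_change <- function() {
  utils::read.csv(system.file("extdata", "iip_suitability_change.csv",
                              package = "rangedyn"))
}
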