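# Bundled reference tables for the Guizhou karst case study.

#' Guizhou terrestrial-ecosystem carbon densities
#'
#' Published four-pool carbon densities (Mg/hm^2) for the six first-level
#' ecosystem classes of Guizhou Province, compiled from regional field-survey
#' literature. Note the high soil pool of the settlement class (205.07),
#' which exceeds grassland's; it is kept as published.
#'
#' @return A [carbon_density_table()].
#' @export
guizhou_carbon_density <- function() {
  read_density_table(system.file("extdata", "guizhou_carbon_density.csv",
                                 package = "carbonscape", mustWork = TRUE))
}

#' Guizhou per-class areas for 2010/2020 (observed) and 2030/2050 (simulated)
#'
#' Published provincial area summaries in km^2. The source's forest area for
#' 2050 is internally inconsistent with its own column total (173,702 km^2)
#' and its printed forest carbon storage; it is therefore stored as missing
#' and recovered here by total-area conservation: the 2050 total equals the
#' 2030 total, so forest_2050 = 173,702 - sum of the other five classes
#' = 90,123 km^2 (which reproduces the published storage of 239,420.76
#' x 10^4 Mg).
#'
#' @return data.frame with columns `class_code`, `class_name`, `area_2010`,
#'   `area_2020`, `area_2030`, `area_2050`.
#' @export
guizhou_class_areas <- function() {
  df <- utils::read.csv(system.file("extdata", "guizhou_class_areas.csv",
                                    package = "carbonscape", mustWork = TRUE))
  i <- which(is.na(df$area_2050))
  if (length(i) == 1L)
    df$area_2050[i] <- sum(df$area_2030) - sum(df$area_2050, na.rm = TRUE)
  df
}

#' Guizhou neighbourhood (domain) weights
#'
#' Published per-class neighbourhood weights used by the cellular automaton,
#' derived by the source from each class's share of expansion area. The
#' published vector sums to 0.4258, not 1; it is stored verbatim (see
#' [expansion_share_weights()] with `basis = "given"`).
#'
#' @return Named numeric vector over the six classes.
#' @export
guizhou_domain_weights <- function() {
  df <- utils::read.csv(system.file("extdata", "guizhou_domain_weights.csv",
                                    package = "carbonscape", mustWork = TRUE))
  stats::setNames(df$weight, df$class_name)
}
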