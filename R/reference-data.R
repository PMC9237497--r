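#' Published genetic-parameter tables for the cowpea mutagenesis trial
#'
#' Returns the printed per-population summaries (mean, standard error,
#' Duncan letter string, GCV%, h2%, GA% of mean) for 10 quantitative
#' traits in the M2 and M3 generations of the cowpea varieties
#' Gomati VU-89 and Pusa-578, as transcribed from the published trial
#' report. These serve as reference inputs: treatment mean profiles for
#' the simulator defaults, plant-yield means for genetic-gain accounting,
#' and the trait-mean matrix behind the multivariate examples.
#'
#' Known typesetting defects of the source were normalized during
#' transcription (standard errors printed without a decimal point, a
#' doubled decimal point, stray spaces inside letter superscripts).
#' Letter strings are kept as printed, including one anomalous "li".
#'
#' @return A tibble with columns `variety`, `generation` ("M2"/"M3"),
#'   `trait` (codes, see [cowpea_traits()]), `treatment`, `mean`, `se`,
#'   `letters`, `gcv_pct`, `h2_pct`, `ga_pct`.
#' @export
#' @examples
#' ref <- cowpea_reference()
#' dplyr::filter(ref, trait == "PY", treatment == "G1")
cowpea_reference <- function() {
  path <- system.file("extdata", "cowpea_reference_params.csv",
                      package = "mutbreedr", mustWork = TRUE)
  readr::read_csv(
    path,
    col_types = readr::cols(
      variety = "c", generation = "c", trait = "c", treatment = "c",
      mean = "d", se = "d", letters = "c",
      gcv_pct = "d", h2_pct = "d", ga_pct = "d"
    ),
    progress = FALSE
  )
}

#' Trait codes used throughout the package
#'
#' The ten quantitative traits scored in the trial, in their canonical
#' order: plant height (PH, cm), days to flowering (DF), days to maturity
#' (DM), pods per plant (PPP), branches per plant (BPP), seeds per pod
#' (SPP), 100-seed weight (SW, g), pod length (PL, cm), plant yield
#' (PY, g) and harvest index (HI, %).
#'
#' @return Named character vector mapping code to full trait name.
#' @export
cowpea_traits <- function() {
  c(PH = "plant height", DF = "days to flowering", DM = "days to maturity",
    PPP = "pods per plant", BPP = "branches per plant",
    SPP = "seeds per pod", SW = "seed weight", PL = "pod length",
    PY = "plant yield", HI = "harvest index")
}

#' Mean matrix of the published M2 Gomati VU-89 trait means
#'
#' Convenience accessor assembling the printed treatment-by-trait mean
#' matrix (13 populations x 10 traits) for a given variety and
#' generation, in the shape [population_means()] produces.
#'
#' @param variety Variety name as printed.
#' @param generation "M2" or "M3".
#' @return A tibble with a `treatment` column followed by one column per
#'   trait code.
#' @export
reference_mean_matrix <- function(variety = "Gomati VU-89", generation = "M2") {
  ref <- cowpea_reference() |>
    filter(.data$variety == .env$variety,
           .data$generation == .env$generation)
  if (nrow(ref) == 0) {
    abort(paste0("No reference rows for variety '", variety,
                 "', generation '", generation, "'."))
  }
  ref |>
    select("treatment", "trait", "mean") |>
    pivot_wider(names_from = "trait", values_from = "mean")
}
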