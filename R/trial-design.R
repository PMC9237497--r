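#' Treatment set of the mutagenesis dose trial
#'
#' Builds the full treatment table the trial started from: an untreated
#' control, ten gamma-ray doses (100--1,000 Gy), ten sodium-azide (SA)
#' concentrations (0.01--0.1%), and the ten matched combination
#' treatments (G1+S1 ... G10+S10).
#'
#' @param n_levels Number of dose levels per mutagen series (default 10).
#' @return A tibble with columns `label`, `gamma_gy`, `sa_pct`.
#' @export
#' @examples
#' default_treatments()
default_treatments <- function(n_levels = 10) {
  k <- seq_len(n_levels)
  bind_rows(
    tibble(label = "C", gamma_gy = 0, sa_pct = 0),
    tibble(label = paste0("G", k), gamma_gy = 100 * k, sa_pct = 0),
    tibble(label = paste0("S", k), gamma_gy = 0, sa_pct = 0.01 * k),
    tibble(label = paste0("G", k, "+S", k), gamma_gy = 100 * k,
           sa_pct = 0.01 * k)
  )
}

#' Define a mutagenesis trial design
#'
#' Describes the structural layout of a replicated mutation-breeding
#' trial: varieties, mutagen treatments, seeds sown per treatment,
#' replications per line, number of lines scored per treatment, the
#' generation sequence and the traits recorded. Defaults reproduce the
#' cowpea trial layout: 2 varieties, control plus gamma/SA/combined dose
#' series, 300 seeds per treatment, 30 replications, and the ten
#' quantitative traits of [cowpea_traits()].
#'
#' @param varieties Character vector of variety labels.
#' @param treatments Tibble with columns `label`, `gamma_gy` (>= 0) and
#'   `sa_pct` (>= 0); exactly one row must be the untreated control
#'   (both doses zero).
#' @param seeds_per_treatment Seeds sown per treatment and variety.
#' @param replications Replicate plots per line (r >= 2).
#' @param lines_per_treatment Lines scored per treatment (>= 2). The
#'   default 100 leaves room for truncation selection of the 30
#'   highest-yielding lines between generations.
#' @param generations Ordered generation labels.
#' @param traits Character vector of trait codes (unique).
#' @return An object of class `trial_design` (a list).
#' @export
#' @examples
#' d <- trial_design()
#' d$replications
trial_design <- function(varieties = c("Gomati VU-89", "Pusa-578"),
                         treatments = default_treatments(),
                         seeds_per_treatment = 300,
                         replications = 30,
                         lines_per_treatment = 100,
                         generations = c("M1", "M2", "M3", "M4"),
                         traits = names(cowpea_traits())) {
  treatments <- as_tibble(treatments)
  req <- c("label", "gamma_gy", "sa_pct")
  if (!all(req %in% names(treatments))) {
    abort("`treatments` needs columns label, gamma_gy, sa_pct.")
  }
  check_positive(treatments$gamma_gy, "gamma_gy", strict = FALSE)
  check_positive(treatments$sa_pct, "sa_pct", strict = FALSE)
  if (anyDuplicated(treatments$label)) abort("treatment labels must be unique.")
  is_control <- treatments$gamma_gy == 0 & treatments$sa_pct == 0
  if (sum(is_control) != 1) {
    abort("exactly one treatment must be the untreated control (gamma_gy = 0, sa_pct = 0).")
  }
  if (length(varieties) < 1 || anyDuplicated(varieties)) {
    abort("`varieties` must be a non-empty set of unique labels.")
  }
  check_positive(seeds_per_treatment, "seeds_per_treatment")
  if (replications < 2) abort("`replications` must be >= 2.")
  if (lines_per_treatment < 2) abort("`lines_per_treatment` must be >= 2.")
  if (anyDuplicated(traits)) abort("trait names must be unique.")
  structure(
    list(
      varieties = varieties,
      treatments = treatments,
      control = treatments$label[is_control],
      seeds_per_treatment = as.integer(seeds_per_treatment),
      replications = as.integer(replications),
      lines_per_treatment = as.integer(lines_per_treatment),
      generations = generations,
      traits = traits
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  cat("  varieties:  ", paste(x$varieties, collapse = ", "), "\n")
  cat("  treatments: ", nrow(x$treatments), " (control: ", x$control, ")\n",
      sep = "")
  cat("  seeds/treatment:", x$seeds_per_treatment,
      " replications:", x$replications,
      " lines/treatment:", x$lines_per_treatment, "\n")
  cat("  generations:", paste(x$generations, collapse = " -> "), "\n")
  cat("  traits:     ", paste(x$traits, collapse = " "), "\n")
  invisible(x)
}

#' Gray-equivalent composite dose of a mutagen treatment
#'
#' Maps every treatment onto a single severity axis so germination
#' response can be modelled with one logistic curve. Gamma dose enters in
#' Gy; an SA concentration of 0.01% is equated to `sa_scale` x 100
#' Gy-equivalents. For combined treatments the two components are not
#' added outright: the composite is the larger single-mutagen equivalent
#' plus `combo_weight` times the smaller one. This saturating form keeps
#' the top retained combination (G4+S4) the most severe retained
#' treatment while all dose levels beyond the fourth -- gamma, SA or
#' combined -- fall past the germination cut-off, matching the reported
#' dose screen; a purely additive composite cannot order the series that
#' way.
#'
#' @param gamma_gy Gamma dose in Gy (vector).
#' @param sa_pct SA concentration in percent (vector).
#' @param sa_scale Gy-equivalents per (SA% x 1e4) unit; default 1 puts
#'   0.01% SA at 100 Gy-equivalents.
#' @param combo_weight Weight of the minor component in combined
#'   treatments (default 0.1).
#' @return Numeric vector of composite doses (Gy-equivalents); 0 for the
#'   control.
#' @export
#' @examples
#' composite_dose(400, 0.04)  # G4+S4 -> 440 Gy-equivalents
composite_dose <- function(gamma_gy, sa_pct, sa_scale = 1, combo_weight = 0.1) {
  check_positive(gamma_gy, "gamma_gy", strict = FALSE)
  check_positive(sa_pct, "sa_pct", strict = FALSE)
  sa_eq <- sa_pct * 1e4 * sa_scale
  hi <- pmax(gamma_gy, sa_eq)
  lo <- pmin(gamma_gy, sa_eq)
  hi + combo_weight * lo
}
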