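#' Total chlorophyll from spectrophotometer readings
#'
#' Arnon-style total chlorophyll (chlorophyll a + b) in mg per g fresh
#' leaf mass from optical densities at 645 and 663 nm:
#' `(20.2 * OD645 + 8.02 * OD663) * V / (1000 * W)`, with extract volume
#' `V` in mL and tissue mass `W` in g. The expression is linear in `V`,
#' inversely linear in `W`, and independent of the light-path length.
#'
#' @param od645,od663 Absorbances (>= 0, finite); vectorized.
#' @param v Extract volume, mL (> 0).
#' @param w Fresh tissue mass, g (> 0).
#' @return Chlorophyll content, mg per g fresh mass.
#' @export
#' @examples
#' chlorophyll_total(0.5, 0.8, v = 10, w = 0.5)  # 0.3303
chlorophyll_total <- function(od645, od663, v, w) {
  check_positive(od645, "od645", strict = FALSE)
  check_positive(od663, "od663", strict = FALSE)
  check_positive(v, "v")
  check_positive(w, "w")
  (20.2 * od645 + 8.02 * od663) * v / (1000 * w)
}

#' Carotenoids from spectrophotometer readings
#'
#' Carotenoid content in mg per g fresh leaf mass from optical densities
#' at 480 and 510 nm: `(7.6 * OD480 - 1.49 * OD510) * V / (d * 1000 * W)`
#' with light-path length `d` in cm (default 1.4). A negative bracket is
#' physically impossible and is clipped to zero with a warning.
#'
#' @inheritParams chlorophyll_total
#' @param od480,od510 Absorbances (>= 0, finite); vectorized.
#' @param d Light-path length, cm (> 0; default 1.4).
#' @return Carotenoid content, mg per g fresh mass (>= 0).
#' @export
#' @examples
#' carotenoids(0.6, 0.2, v = 10, w = 0.5)  # 0.0609
carotenoids <- function(od480, od510, v, w, d = 1.4) {
  check_positive(od480, "od480", strict = FALSE)
  check_positive(od510, "od510", strict = FALSE)
  check_positive(v, "v")
  check_positive(w, "w")
  check_positive(d, "d")
  out <- (7.6 * od480 - 1.49 * od510) * v / (d * 1000 * w)
  if (any(out < 0)) {
    warn("negative carotenoid estimate(s) clipped to 0.",
         class = "mutbreedr_negative_carotenoid")
    out <- pmax(out, 0)
  }
  out
}

#' Quantify pigments for a table of readings
#'
#' Data-frame-first wrapper: given a tibble of spectrophotometer readings
#' (columns `od645`, `od663`, `od480`, `od510`, `v`, `w`, optional `d`),
#' appends `chlorophyll_mg_g` and `carotenoids_mg_g`.
#'
#' @param readings A data frame of readings.
#' @return The input tibble with the two pigment columns appended.
#' @export
quantify_pigments <- function(readings) {
  readings <- as_tibble(readings)
  req <- c("od645", "od663", "od480", "od510", "v", "w")
  miss <- setdiff(req, names(readings))
  if (length(miss) > 0) {
    abort(paste0("missing reading columns: ", paste(miss, collapse = ", "), "."))
  }
  d <- if ("d" %in% names(readings)) readings$d else 1.4
  readings |>
    mutate(
      chlorophyll_mg_g = chlorophyll_total(.data$od645, .data$od663,
                                           .data$v, .data$w),
      carotenoids_mg_g = carotenoids(.data$od480, .data$od510,
                                     .data$v, .data$w, d = d)
    )
}
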