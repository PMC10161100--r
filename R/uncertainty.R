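#' Build an uncertainty budget
#'
#' @param label budget name.
#' @param values component values, percent at k = 1.
#' @param sources component labels.
#' @param types `"A"` (statistical) or `"B"` (systematic) per component.
#' @return an [UncertaintyBudget-class] with the quadrature-combined value.
#' @export
uncertaintyBudget <- function(label, values, sources = NULL, types = NULL) {
  if (any(values < 0)) stop("uncertainty components must be >= 0")
  if (!length(values)) stop("need at least one component")
  comp <- data.frame(
    source = sources %||% paste0("component ", seq_along(values)),
    value = as.numeric(values),
    type = types %||% rep("B", length(values)))
  new("UncertaintyBudget", label = label, components = comp,
      combined = sqrt(sum(values^2)))
}

#' Combine uncertainty components in quadrature
#'
#' GUM-style combination of type A and B components:
#' \eqn{u_c = \sqrt{\sum u_i^2}}. Display rounding is half-up to one
#' decimal (see [displayPercent()]); the raw value is returned.
#'
#' @param budget an [UncertaintyBudget-class], or a numeric vector of
#'   component values (percent, k = 1).
#' @return combined standard uncertainty, percent.
#' @examples
#' combineQuadrature(c(0.1, 0.3, 0.7, 0.5))   # 0.917 -> displays as 0.9
#' @export
combineQuadrature <- function(budget) {
  v <- if (is(budget, "UncertaintyBudget")) budget@components$value
  else as.numeric(budget)
  if (!length(v)) stop("need at least one component")
  if (any(v < 0)) stop("uncertainty components must be >= 0")
  sqrt(sum(v^2))
}

#' Half-up rounding for displayed percentages
#' @param x numeric.
#' @param digits decimals (default 1).
#' @return rounded value (0.95 -> 1.0, unlike banker's rounding).
#' @export
displayPercent <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Packaged uncertainty budgets of the verification chain
#'
#' The calibration dose-rate budget (collected charge, influence-quantity
#' corrections, chamber calibration coefficient, msr-field correction) and
#' the film dosimetry budget (calibration data, optical-density
#' reproducibility, scanner homogeneity, K_med), at k = 1.
#'
#' @return named list of [UncertaintyBudget-class] objects.
#' @export
defaultBudgets <- function() {
  list(
    gk_calibration = uncertaintyBudget(
      "GK calibration",
      values = c(0.1, 0.3, 0.7, 0.5),
      sources = c("collected charge",
                  "influence quantities (kTP, kIon, kPol)",
                  "chamber calibration coefficient NDw",
                  "msr-field correction KQmsr"),
      types = c("A", "B", "B", "B")),
    film = uncertaintyBudget(
      "Film dosimetry",
      values = c(1.9, 0.3, 0.2, 0.3),
      sources = c("calibration data", "OD measurement reproducibility",
                  "optical scanner homogeneity",
                  "dose-to-medium correction factor Kmed"),
      types = c("B", "A", "B", "B")))
}
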