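#' Construct a biomechanical component profile
#'
#' A profile holds one participant's four instability indices: force
#' variability (FV, coefficient of variation of peak vertical ground reaction
#' force), temporal asymmetry (TA, stance-time difference ratio), load
#' distribution (LD, pressure-distribution index) and bilateral asymmetry
#' (BA, kinematic/kinetic limb-comparison index). All four are dimensionless
#' non-negative ratios; values outside the plausibility bounds are rejected.
#'
#' @param fv,ta,ld,ba component values.
#' @param bounds 4 x 2 matrix of `(lo, hi)` plausibility bounds, rows FV,
#'   TA, LD, BA. Default `[0, 0.5]` for each component.
#' @return named numeric of class `component_profile`.
#' @export
component_profile <- function(fv, ta, ld, ba,
                              bounds = matrix(c(0, 0.5), 4, 2, byrow = TRUE)) {
  p <- c(fv = fv, ta = ta, ld = ld, ba = ba)
  if (!is.numeric(p) || length(p) != 4L || any(!is.finite(p)))
    stop("component values must be four finite numbers")
  if (any(p < 0)) stop("component values must be non-negative")
  if (any(p < bounds[, 1]) || any(p > bounds[, 2]))
    stop("component value outside plausibility bounds: ",
         paste(names(p)[p < bounds[, 1] | p > bounds[, 2]], collapse = ", "))
  structure(p, class = "component_profile")
}

#' Convergence factor for dynamic (windowed) risk assessment
#'
#' Computes the critical-transitions convergence factor
#' \eqn{\Omega = \sum_i w_i V_i \sigma_i^2 / (\sqrt{T}\,\Delta H)}, combining
#' the weighted product of each component's current value and its variance
#' over the observation window with the window length and the entropy shift.
#' A rising Omega signals growing instability (increasing variance, shrinking
#' window, small positive entropy shift). A negative result (entropy
#' decreasing) is clamped to 0 and flagged via the `"clamped"` attribute,
#' since the composite score is defined on `[0, 1]`.
#'
#' @param v numeric(4), current component values \eqn{V_i}.
#' @param sigma2 numeric(4), per-component variances over the window, >= 0.
#' @param t_window observation-window length T (sessions), > 0.
#' @param delta_h entropy shift; `|delta_h|` below `eps_h` is an error
#'   (division blow-up).
#' @param weights a [wase_weights] vector.
#' @param eps_h smallest admissible `|delta_h|`.
#' @return non-negative scalar with logical attribute `"clamped"`.
#' @export
compute_omega <- function(v, sigma2, t_window, delta_h,
                          weights = default_weights(), eps_h = 1e-6) {
  if (length(v) != 4L || length(sigma2) != 4L)
    stop("`v` and `sigma2` must each have four elements")
  if (any(!is.finite(v)) || any(!is.finite(sigma2)))
    stop("convergence inputs must be finite")
  if (any(sigma2 < 0)) stop("variances must be non-negative")
  if (!is.finite(t_window) || t_window <= 0)
    stop("invalid window: `t_window` must be strictly positive")
  if (!is.finite(delta_h) || abs(delta_h) <= eps_h)
    stop("undefined convergence factor: |delta_h| <= ", format(eps_h))
  omega <- sum(as.numeric(weights) * v * sigma2) / (sqrt(t_window) * delta_h)
  clamped <- omega < 0
  if (clamped) omega <- 0
  structure(omega, clamped = clamped)
}

#' Compute the WASe composite risk score
#'
#' The score is the weighted sum of the four components multiplied by the
#' convergence factor, clipped to `[0, 1]`:
#' `WASe = clip((w1*FV + w2*TA + w3*LD + w4*BA) * Omega, 0, 1)`.
#' In `cross_sectional` mode (a single observation per participant, the mode
#' used throughout the simulation study) Omega is fixed at 1; `dynamic` mode
#' accepts an Omega computed by [compute_omega()] over an observation window.
#'
#' @param profile a [component_profile] (or named numeric with fv/ta/ld/ba).
#' @param weights a [wase_weights] vector.
#' @param omega convergence factor; ignored (forced to 1) in
#'   `cross_sectional` mode, must be >= 0 in `dynamic` mode.
#' @param mode `"cross_sectional"` or `"dynamic"`.
#' @return object of class `wase_score` with fields `raw`, `omega`, `value`,
#'   `clipped`, `mode`.
#' @examples
#' p <- component_profile(0.15, 0.08, 0.12, 0.10)
#' compute_wase(p, default_weights())
#' @export
compute_wase <- function(profile, weights = default_weights(), omega = 1,
                         mode = c("cross_sectional", "dynamic")) {
  mode <- match.arg(mode)
  if (!inherits(profile, "component_profile"))
    profile <- component_profile(profile[["fv"]], profile[["ta"]],
                                 profile[["ld"]], profile[["ba"]])
  if (mode == "cross_sectional") {
    omega <- 1
  } else {
    omega <- as.numeric(omega)
    if (!is.finite(omega) || omega < 0)
      stop("negative or non-finite omega in dynamic mode")
  }
  raw <- sum(as.numeric(weights) * as.numeric(profile))
  prod <- raw * omega
  value <- min(max(prod, 0), 1)
  structure(
    list(raw = raw, omega = omega, value = value,
         clipped = !isTRUE(all.equal(value, prod)), mode = mode),
    class = "wase_score")
}

#' @export
print.wase_score <- function(x, ...) {
  cat(sprintf("WASe score: %.4f (raw %.4f x omega %.4f, %s mode%s)\n",
              x$value, x$raw, x$omega, x$mode,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Default component specification table
#'
#' Weight, normal range and risk threshold for each component, as shipped.
#' The same table is available as a CSV under `inst/extdata/`.
#'
#' @return data.frame with columns `component`, `weight`, `normal_lo`,
#'   `normal_hi`, `risk_threshold`, `label`.
#' @export
component_specs <- function() {
  data.frame(
    component = c("fv", "ta", "ld", "ba"),
    weight = c(0.35, 0.28, 0.22, 0.15),
    normal_lo = c(0.08, 0.05, 0.10, 0.06),
    normal_hi = c(0.15, 0.12, 0.18, 0.14),
    risk_threshold = c(0.18, 0.15, 0.22, 0.18),
    label = c("Ground reaction force coefficient of variation",
              "Stance time difference ratio",
              "Pressure distribution analysis",
              "Kinematic/kinetic limb comparison"),
    stringsAsFactors = FALSE)
}

#' Flag components exceeding their risk thresholds
#'
#' A component is flagged iff its value is strictly greater than its risk
#' threshold; a value exactly at the threshold is not flagged.
#'
#' @param profile a [component_profile] or named numeric (fv, ta, ld, ba).
#' @param specs specification table as returned by [component_specs()];
#'   must cover all four components.
#' @return character vector of flagged component names (possibly empty).
#' @export
flag_components <- function(profile, specs = component_specs()) {
  validate_specs(specs)
  p <- as.numeric(profile)[match(specs$component, names(profile))]
  if (anyNA(p)) {
    p <- as.numeric(profile)
    if (length(p) != 4L) stop("profile must supply fv, ta, ld, ba")
  }
  specs$component[p > specs$risk_threshold]
}

validate_specs <- function(specs) {
  need <- c("component", "weight", "normal_lo", "normal_hi", "risk_threshold")
  if (!all(need %in% names(specs)))
    stop("specs missing column(s): ",
         paste(setdiff(need, names(specs)), collapse = ", "))
  if (!setequal(specs$component, c("fv", "ta", "ld", "ba")))
    stop("missing spec for component(s): ",
         paste(setdiff(c("fv", "ta", "ld", "ba"), specs$component),
               collapse = ", "))
  if (any(specs$normal_lo >= specs$normal_hi))
    stop("each normal_lo must be < normal_hi")
  if (any(specs$risk_threshold <= specs$normal_lo))
    stop("risk_threshold must exceed normal_lo")
  invisible(specs)
}
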