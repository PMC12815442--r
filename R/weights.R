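#' Derive component weights from literature contribution ranges
#'
#' Two-step derivation of the WASe weighting coefficients: the midpoint of
#' each component's literature-reported predictive-contribution range (in
#' percent) is taken, the four midpoints are normalized to sum to 1, and the
#' result is rounded to two decimals with round-half-to-even. If rounding
#' breaks the unit sum, a single +/-0.01 adjustment is applied to the largest
#' weight; configurations that cannot be reconciled this way are an error.
#'
#' @param ranges a 4 x 2 numeric matrix (or list of length-2 vectors) of
#'   `(lo, hi)` percentage ranges, rows ordered FV, TA, LD, BA. All values
#'   must lie in (0, 100) with `lo < hi`.
#' @return a named numeric vector of class `wase_weights` with elements
#'   `fv`, `ta`, `ld`, `ba`, summing to 1 at two decimals.
#' @examples
#' derive_weights(rbind(c(30, 40), c(25, 30), c(20, 25), c(10, 20)))
#' @export
derive_weights <- function(ranges) {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- as.matrix(ranges)
  if (!is.numeric(ranges) || !all(dim(ranges) == c(4L, 2L)))
    stop("`ranges` must be four (lo, hi) pairs")
  lo <- ranges[, 1]; hi <- ranges[, 2]
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("range endpoints must be finite")
  if (any(lo >= hi)) stop("degenerate range: each lo must be < hi")
  if (any(lo <= 0) || any(hi >= 100)) stop("ranges must lie within (0, 100)")
  mid <- (lo + hi) / 2
  w <- vapply(mid / sum(mid), round2_half_even, numeric(1))
  s <- sum(w)
  if (abs(s - 1) > 1e-9) {
    adj <- round((1 - s) * 100)
    k <- which.max(w)
    cand <- w[k] + adj / 100
    if (abs(adj) == 1 && cand > 0 && cand < 1 && abs(sum(w) + adj / 100 - 1) < 1e-9) {
      w[k] <- cand
    } else {
      stop("rounded weights sum to ", format(s),
           " and cannot be reconciled to 1.00 by a single +/-0.01 adjustment")
    }
  }
  wase_weights(w[1], w[2], w[3], w[4])
}

#' Construct and validate a weight vector
#'
#' @param fv,ta,ld,ba weights for the four components, each in (0, 1).
#' @return named numeric of class `wase_weights`.
#' @export
wase_weights <- function(fv, ta, ld, ba) {
  w <- c(fv = fv, ta = ta, ld = ld, ba = ba)
  if (!is.numeric(w) || length(w) != 4L || any(!is.finite(w)))
    stop("weights must be four finite numbers")
  if (any(w <= 0) || any(w >= 1)) stop("each weight must lie in (0, 1)")
  if (abs(sum(w) - 1) > 0.005 + 1e-9)
    stop("weights must sum to 1.00 at two-decimal precision (got ",
         format(sum(w)), ")")
  structure(w, class = "wase_weights")
}

#' Default WASe weights
#'
#' The shipped weighting coefficients (0.35, 0.28, 0.22, 0.15) for FV, TA,
#' LD, BA, as derived by [derive_weights()] from the literature contribution
#' ranges 30-40%, 25-30%, 20-25%, 10-20%.
#'
#' @return a `wase_weights` vector.
#' @export
default_weights <- function() {
  wase_weights(0.35, 0.28, 0.22, 0.15)
}

#' @export
print.wase_weights <- function(x, ...) {
  cat("WASe component weights (sum = 1):\n")
  print(unclass(x))
  invisible(x)
}

# Round to two decimals with exact half-to-even, immune to binary
# misrepresentation of decimal halves (0.275 -> 0.28, 0.225 -> 0.22).
round2_half_even <- function(x) {
  r <- x * 100
  f <- floor(r)
  frac <- r - f
  if (abs(frac - 0.5) < 1e-9) {
    n <- if (f %% 2 == 0) f else f + 1
  } else {
    n <- floor(r + 0.5)
  }
  n / 100
}
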