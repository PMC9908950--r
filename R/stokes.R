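#' Stokes vector
#'
#' Constructs an (I, Q, U, V) Stokes vector describing a (partially)
#' polarized light state. The handedness convention throughout the package
#' is V = I_RCP - I_LCP from the receiver's point of view, so a pure
#' left-circular state of unit intensity is `stokes(1, 0, 0, -1)`. All
#' helicity flip/preserve logic depends only on sign *agreement* between
#' two V values and is therefore convention-invariant.
#'
#' @param I,Q,U,V Real Stokes components; `I` must be non-negative and the
#'   state physically realizable (`I >= sqrt(Q^2+U^2+V^2)` within
#'   tolerance).
#' @param tol Relative tolerance for the realizability check.
#' @return An object of class `stokes` (named numeric of length 4).
#' @examples
#' stokes_circular("left")
#' docp(stokes(1, 0, 0, 0.5))
#' @export
stokes <- function(I, Q = 0, U = 0, V = 0, tol = 1e-9) {
  vals <- c(I = I, Q = Q, U = U, V = V)
  if (!all(is.finite(vals))) stop("Stokes components must be finite")
  if (I < 0) stop("Stokes I must be non-negative")
  p <- sqrt(Q^2 + U^2 + V^2)
  if (p > I * (1 + tol) + tol) {
    stop("unphysical Stokes vector: polarized intensity exceeds I")
  }
  structure(vals, class = "stokes")
}

#' Pure circular polarization states
#'
#' @param handedness `"left"` or `"right"`; left-circular has V = -I under
#'   the package convention.
#' @param intensity Total intensity.
#' @return A `stokes` object with `|V| = I`.
#' @export
stokes_circular <- function(handedness = c("left", "right"), intensity = 1) {
  handedness <- match.arg(handedness)
  s <- if (handedness == "left") -1 else 1
  stokes(intensity, 0, 0, s * intensity)
}

#' Degree of circular polarization |V|/I
#'
#' @param s A `stokes` object.
#' @return `|V|/I`, in `[0, 1]`.
#' @export
docp <- function(s) {
  stopifnot(inherits(s, "stokes"))
  if (s[["I"]] <= 0) stop("DOCP undefined for zero intensity")
  abs(s[["V"]]) / s[["I"]]
}

is_realizable <- function(s, tol = 1e-7) {
  s[["I"]] + tol * max(1, s[["I"]]) >=
    sqrt(s[["Q"]]^2 + s[["U"]]^2 + s[["V"]]^2)
}

#' @export
print.stokes <- function(x, ...) {
  cat(sprintf("<stokes> I=%.6g Q=%.6g U=%.6g V=%.6g (DOCP %.4f)\n",
              x[["I"]], x[["Q"]], x[["U"]], x[["V"]],
              if (x[["I"]] > 0) abs(x[["V"]]) / x[["I"]] else NA_real_))
  invisible(x)
}
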