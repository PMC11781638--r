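#' Moisture thresholds from a soil-water retention curve
#'
#' Maps measured retention points (matric potential, volumetric water
#' content) to the four critical relative saturations. The hygroscopic
#' point, wilting point, stress onset and field capacity correspond to
#' matric potentials of -10, -3, -0.03 and -0.01 MPa respectively; the water
#' content at each target is interpolated linearly in `log10(|psi|)` and
#' divided by porosity. Extrapolation beyond the measured range is refused.
#'
#' @param psi_mpa Matric potentials (MPa); sign is ignored, magnitudes used.
#' @param theta Volumetric water contents at `psi_mpa`, each in `(0, n]`.
#' @param n Soil porosity.
#' @param targets_mpa Target potentials (MPa) for `(sh, sw, sstar, sfc)`;
#'   default `c(-10, -3, -0.03, -0.01)`.
#' @return A [moisture_thresholds()] object (ordering enforced).
#' @export
#' @examples
#' psi <- -c(10, 3, 1, 0.3, 0.03, 0.01, 0.003)
#' th <- 0.47 * c(0.20, 0.28, 0.45, 0.60, 0.72, 0.77, 0.90)
#' thresholds_from_retention(psi, th, n = 0.47)
thresholds_from_retention <- function(psi_mpa, theta, n,
                                      targets_mpa = c(-10, -3, -0.03, -0.01)) {
  stopifnot(length(psi_mpa) == length(theta), length(targets_mpa) == 4L)
  if (length(psi_mpa) < 4L)
    stop("need at least 4 retention points")
  if (!is.finite(n) || n <= 0 || n >= 1) stop("porosity n must lie in (0, 1)")
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta > n + 1e-12))
    stop("theta values must lie in (0, n]")
  lpsi <- log10(abs(psi_mpa))
  if (anyDuplicated(lpsi)) stop("duplicate matric potentials in retention data")
  ord <- order(lpsi)
  lpsi <- lpsi[ord]
  th <- theta[ord]
  if (any(diff(th) > 1e-12))
    stop("retention data must be monotone: theta cannot increase with |psi|")
  lt <- log10(abs(targets_mpa))
  if (any(lt < min(lpsi) - 1e-12) || any(lt > max(lpsi) + 1e-12))
    stop("target potentials outside the measured range; refusing to extrapolate")
  th_t <- approx(lpsi, th, xout = lt, ties = "ordered")$y
  s <- th_t / n
  moisture_thresholds(sh = s[1L], sw = s[2L], sstar = s[3L], sfc = s[4L])
}
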