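# Unit bookkeeping used throughout:
#   forces N, lengths mm  ->  J in N/mm == kJ/m^2, moduli in N/mm^2 == MPa,
#   K in MPa*sqrt(m) via N*mm^-1.5 * sqrt(mm/m) = N*mm^-1.5 * 0.0316228.
MM_TO_M_SQRT <- sqrt(1e-3)

#' Slope of the linear part of a load-displacement record
#'
#' Least-squares slope `m` (N/mm) through the samples whose force lies in a
#' window of the peak force; the default window, 10-50 % of peak, spans the
#' linear elastic rise while avoiding both the seating toe and the
#' near-peak nonlinearity. A valid bend test is very nearly linear there,
#' so a fit `r2 < 0.99` draws a warning.
#'
#' @param force_N,disp_mm Paired record vectors.
#' @param window_fractions Length-2 fractions of peak force delimiting the
#'   fitted window, default `c(0.1, 0.5)`.
#' @return List of class `linear_fit`: `m` (N/mm), `intercept_N`, `r2`,
#'   `window_fractions`, `n`.
#' @export
fit_linear_slope <- function(force_N, disp_mm, window_fractions = c(0.1, 0.5)) {
  stopifnot(length(force_N) == length(disp_mm))
  fmax <- max(force_N)
  if (fmax <= 0) stop("record has no positive force")
  # the post-peak softening branch re-enters the force window at large
  # displacement, so the fit is confined to the rising part
  pre <- seq_len(which.max(force_N))
  sel <- pre[force_N[pre] >= window_fractions[1] * fmax &
             force_N[pre] <= window_fractions[2] * fmax]
  if (length(sel) < 5)
    stop("too few samples in the linear-fit window (need >= 5)")
  fit <- stats::lm(force_N[sel] ~ disp_mm[sel])
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0) stop("non-positive linear slope")
  ss_tot <- sum((force_N[sel] - mean(force_N[sel]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (r2 < 0.99)
    warning(sprintf("linear fit r2 = %.4f < 0.99: check the record", r2))
  structure(list(m = m, intercept_N = unname(stats::coef(fit)[1]), r2 = r2,
                 window_fractions = window_fractions, n = length(sel)),
            class = "linear_fit")
}

#' Flexural modulus of a (notched) three-point-bend beam
#'
#' Beam-theory flexural modulus from the measured stiffness `m` (N/mm):
#' `E_f = S^3 m / (4 B (W - a0)^3)`, the standard three-point-bend relation
#' evaluated with the in-plane width reduced by the notch length. With
#' `a0 = 0` this is the familiar un-notched formula `S^3 m / (4 B W^3)`.
#' Because the stress field of a notched beam is not that of a reduced
#' rectangular section, this *apparent* value requires the finite-element
#' correction of [correct_modulus()] before use as a material modulus.
#'
#' @param m Stiffness, N/mm (scalar or [fit_linear_slope()] result).
#' @param geometry A [specimen_geometry()].
#' @return Flexural modulus, MPa (N/mm^2).
#' @export
flexural_modulus <- function(m, geometry) {
  if (inherits(m, "linear_fit")) m <- m$m
  stopifnot(inherits(geometry, "specimen_geometry"))
  w_eff <- geometry$W - geometry$a0
  geometry$S^3 * m / (4 * geometry$B * w_eff^3)
}

#' ASTM E1820 SE(B) geometry function f(a/W)
#'
#' The dimensionless stress-intensity geometry polynomial for a single-edge
#' notched bend specimen loaded in three-point bending:
#' \deqn{f(x) = \frac{3\sqrt{x}\,[1.99 - x(1-x)(2.15 - 3.93x + 2.7x^2)]}
#'             {2(1+2x)(1-x)^{3/2}}, \quad x = a/W.}
#'
#' @param a_over_W Crack length ratio(s) in (0, 1).
#' @return f(a/W), dimensionless.
#' @export
seb_geometry_factor <- function(a_over_W) {
  if (any(a_over_W <= 0 | a_over_W >= 1))
    stop("a/W must lie in (0, 1)")
  x <- a_over_W
  3 * sqrt(x) * (1.99 - x * (1 - x) * (2.15 - 3.93 * x + 2.7 * x^2)) /
    (2 * (1 + 2 * x) * (1 - x)^1.5)
}

#' Stress-intensity factor for an SE(B) specimen
#'
#' `K = F S / (B W^1.5) * f(a/W)` with the E1820 geometry function, with
#' the N/mm result converted to MPa*sqrt(m).
#'
#' @param F_N Applied force, N (vectorised).
#' @param geometry A [specimen_geometry()].
#' @param a_mm Current crack length, mm (vectorised with `F_N`).
#' @return K in MPa*sqrt(m).
#' @export
stress_intensity <- function(F_N, geometry, a_mm) {
  if (any(F_N < 0)) stop("force must be non-negative")
  f <- seb_geometry_factor(a_mm / geometry$W)
  K_nmm <- F_N * geometry$S / (geometry$B * geometry$W^1.5) * f
  K_nmm * MM_TO_M_SQRT
}

#' Cumulative plastic area under a load-displacement record
#'
#' The plastic load-line displacement per sample is
#' `d_pl = d - F / m` (elastic-compliance subtraction); `A_pl(i)` is the
#' trapezoidal area under force vs plastic displacement up to sample `i`,
#' floored at zero. For a purely linear record `A_pl` is identically zero.
#'
#' @param force_N,disp_mm Paired ordered record vectors.
#' @param m Elastic stiffness from [fit_linear_slope()], N/mm.
#' @return Numeric vector of `A_pl` at every sample, N*mm.
#' @export
plastic_area <- function(force_N, disp_mm, m) {
  if (inherits(m, "linear_fit")) m <- m$m
  if (m <= 0) stop("stiffness m must be positive")
  dpl <- disp_mm - force_N / m
  n <- length(force_N)
  if (n < 2) return(rep(0, n))
  inc <- c(0, diff(dpl) * (force_N[-n] + force_N[-1]) / 2)
  pmax(cumsum(inc), 0)
}

#' J-integral at a single load-displacement point
#'
#' Elastic part `J_el = K^2 (1 - nu^2) / E` from the stress intensity at
#' the current crack length, plastic part `J_pl = eta A_pl / (B b0)` with
#' `b0 = W - a0` the initial uncracked ligament and `eta` the SE(B)
#' plastic factor (1.9 in the E1820 basic procedure). `J = J_el + J_pl`,
#' in kJ/m^2.
#'
#' @param F_N Force at the point, N.
#' @param A_pl Plastic area up to the point, N*mm (see [plastic_area()]).
#' @param geometry A [specimen_geometry()].
#' @param a_mm Current crack length `a0 + da`, mm.
#' @param E Elastic modulus, MPa.
#' @param eta SE(B) plastic geometry factor, default 1.9.
#' @return List `J_el`, `J_pl`, `J` (kJ/m^2) and `K` (MPa*sqrt(m)).
#' @export
j_point <- function(F_N, A_pl, geometry, a_mm, E, eta = 1.9) {
  if (E <= 0) stop("E must be positive")
  b0 <- geometry$W - geometry$a0
  if (b0 <= 0) stop("non-positive initial ligament")
  K <- stress_intensity(F_N, geometry, a_mm)
  # K^2/E in MPa*m = 1000 kJ/m^2
  J_el <- K^2 * (1 - geometry$nu^2) / E * 1000
  J_pl <- eta * A_pl / (geometry$B * b0)
  list(J_el = J_el, J_pl = J_pl, J = J_el + J_pl, K = K)
}

#' Effective stress intensity from J
#'
#' `K_eff = sqrt(J E / (1 - nu^2))`, the plane-strain back-conversion, with
#' J in kJ/m^2 and E in MPa giving K_eff in MPa*sqrt(m). For an
#' elastic-only state this inverts [j_point()] exactly.
#'
#' @param J J-integral, kJ/m^2 (vectorised).
#' @param E Elastic modulus, MPa.
#' @param nu Poisson ratio.
#' @param plane `"strain"` (default, `1 - nu^2` factor) or `"stress"` (no
#'   factor).
#' @return K_eff in MPa*sqrt(m).
#' @export
k_eff <- function(J, E, nu, plane = c("strain", "stress")) {
  plane <- match.arg(plane)
  if (any(J < 0) || E < 0) stop("J and E must be non-negative")
  fac <- if (plane == "strain") 1 - nu^2 else 1
  sqrt(J * 1e-3 * E / fac)
}

#' Assemble the crack-extension resistance curve
#'
#' One R-curve point per synced frame: the monotonicised whitening-front
#' displacement is the crack extension `da`, the current crack length is
#' `a = a0 + da`, and `J_el`, `J_pl`, `J`, `K` and `K_eff` are evaluated at
#' the frame's synchronised force and the record up to that frame. Frames
#' with `a >= W` are truncated (with a warning): the effective crack tip
#' has reached the compression face and the SE(B) formulas no longer
#' apply.
#'
#' @param trajectory A `front_trajectory` data.frame (see [track_front()])
#'   or any data.frame with columns `t_s`, `force_N`, `disp_mm`,
#'   `da_mono_mm`, `synced`, `frame_idx`.
#' @param geometry A [specimen_geometry()].
#' @param E Elastic modulus, MPa (notch-corrected; see
#'   [correct_modulus()]).
#' @param eta SE(B) plastic factor, default 1.9.
#' @param m Elastic stiffness N/mm for the compliance subtraction; fitted
#'   from the trajectory's own record when `NULL`.
#' @return Object of class `rcurve`: data.frame with columns `frame_idx`,
#'   `t_s`, `force_N`, `disp_mm`, `da_mm`, `a_mm`, `Jel_kJm2`, `Jpl_kJm2`,
#'   `J_kJm2`, `K_MPa_sqrt_m`, `Keff_MPa_sqrt_m`; attributes `geometry`,
#'   `E`, `eta`, `m`.
#' @export
build_rcurve <- function(trajectory, geometry, E, eta = 1.9, m = NULL) {
  tr <- trajectory[trajectory$synced, , drop = FALSE]
  if (nrow(tr) == 0) {
    out <- data.frame(frame_idx = integer(), t_s = numeric(),
                      force_N = numeric(), disp_mm = numeric(),
                      da_mm = numeric(), a_mm = numeric(),
                      Jel_kJm2 = numeric(), Jpl_kJm2 = numeric(),
                      J_kJm2 = numeric(), K_MPa_sqrt_m = numeric(),
                      Keff_MPa_sqrt_m = numeric())
    return(structure(out, geometry = geometry, E = E, eta = eta, m = m,
                     class = c("rcurve", "data.frame")))
  }
  if (is.null(m)) m <- fit_linear_slope(tr$force_N, tr$disp_mm)$m
  da <- tr$da_mono_mm
  a <- geometry$a0 + da
  keep <- a < geometry$W
  if (any(!keep))
    warning(sprintf("truncating %d point(s) with a >= W", sum(!keep)))
  Apl <- plastic_area(tr$force_N, tr$disp_mm, m)
  sel <- which(keep & (tr$force_N > 0 | da > 0))
  pts <- lapply(sel, function(i)
    j_point(tr$force_N[i], Apl[i], geometry, a[i], E, eta))
  out <- data.frame(
    frame_idx = tr$frame_idx[sel],
    t_s = tr$t_s[sel],
    force_N = tr$force_N[sel],
    disp_mm = tr$disp_mm[sel],
    da_mm = da[sel],
    a_mm = a[sel],
    Jel_kJm2 = vapply(pts, `[[`, 0, "J_el"),
    Jpl_kJm2 = vapply(pts, `[[`, 0, "J_pl"),
    J_kJm2 = vapply(pts, `[[`, 0, "J"),
    K_MPa_sqrt_m = vapply(pts, `[[`, 0, "K"))
  out$Keff_MPa_sqrt_m <- k_eff(out$J_kJm2, E, geometry$nu)
  structure(out, geometry = geometry, E = E, eta = eta, m = m,
            class = c("rcurve", "data.frame"))
}

#' @export
print.rcurve <- function(x, ...) {
  cat(sprintf("R-curve: %d points, da %.3f-%.3f mm, J up to %.3g kJ/m^2, K_eff up to %.3g MPa*sqrt(m)\n",
              nrow(x), if (nrow(x)) min(x$da_mm) else NA,
              if (nrow(x)) max(x$da_mm) else NA,
              if (nrow(x)) max(x$J_kJm2) else NA,
              if (nrow(x)) max(x$Keff_MPa_sqrt_m) else NA))
  invisible(x)
}
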