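# Paraxial optics of the compound objective: one low-magnification dry
# objective (DO) coupled to one or more GRIN-lens miniaturized objectives
# (MOs). Lengths are millimetres, positive downward into tissue; angles
# radians.

#' GRIN miniaturized-objective specification
#'
#' Bundles the physical and optical parameters of one GRIN rod lens used as a
#' miniaturized objective. The refractive index falls parabolically from the
#' central axis, `n(r) = N0 (1 - A r^2 / 2)`, so paraxial rays oscillate
#' sinusoidally with spatial frequency `sqrt(A)`; the pitch is the lens
#' length expressed in full oscillation periods, `P = Z sqrt(A) / (2 pi)`.
#'
#' @param pitch fractional pitch `P` (dimensionless, in (0, 1)).
#' @param sqrt_a refractive-index distribution coefficient `sqrt(A)` (1/mm).
#' @param n0_axial refractive index of the material on the central axis.
#' @param front_wd_mm front working distance `L1` (mm), object plane to the
#'   front face, measured in the front medium.
#' @param n_front refractive index of the front working medium (water).
#' @param n_back refractive index of the back working medium (air).
#' @param na_mo nominal numerical aperture of the MO; must be below `n_front`.
#' @param angular_mag angular magnification factor `M_a = theta0 / theta1`
#'   of the MO (manufacturer value).
#' @param length_mm lens length `Z` (mm). Computed as `2 pi P / sqrt(A)` when
#'   omitted; when supplied it must agree with that relation within 0.2%
#'   (printed catalogue values are rounded).
#' @param label free-text version name.
#' @return an object of class `grin_lens_spec` (a named list).
#' @seealso [lens_length()], [back_working_distance()],
#'   [solve_pitch_for_depth()]
#' @examples
#' standard <- grin_lens_spec(pitch = 0.261, sqrt_a = 0.299,
#'                            label = "standard version")
#' back_working_distance(standard)
#' @export
grin_lens_spec <- function(pitch, sqrt_a, n0_axial = 1.643, front_wd_mm = 0.15,
                           n_front = 1.328, n_back = 1.000, na_mo = 0.483,
                           angular_mag = 0.1675, length_mm = NULL, label = "") {
  stopifnot(is.numeric(pitch), length(pitch) == 1,
            is.numeric(sqrt_a), length(sqrt_a) == 1)
  if (!is.finite(pitch) || pitch <= 0 || pitch >= 1)
    stop("`pitch` must lie strictly in (0, 1); got ", pitch)
  if (!is.finite(sqrt_a) || sqrt_a <= 0)
    stop("`sqrt_a` must be positive; got ", sqrt_a)
  if (n0_axial < 1 || n_front < 1 || n_back < 1)
    stop("all refractive indices must be >= 1")
  if (front_wd_mm < 0)
    stop("`front_wd_mm` must be non-negative")
  if (na_mo <= 0 || na_mo >= n_front)
    stop("`na_mo` must lie in (0, n_front); got ", na_mo)
  if (angular_mag <= 0)
    stop("`angular_mag` must be positive")
  z0 <- lens_length(pitch, sqrt_a)
  if (is.null(length_mm)) {
    length_mm <- z0
  } else if (abs(length_mm - z0) / z0 > 0.002) {
    stop(sprintf(paste0("`length_mm` (%.4f) disagrees with 2*pi*pitch/sqrt_a",
                        " (%.4f) by more than 0.2%%"), length_mm, z0))
  }
  structure(list(n0_axial = n0_axial, pitch = pitch, sqrt_a = sqrt_a,
                 length_mm = length_mm, front_wd_mm = front_wd_mm,
                 n_front = n_front, n_back = n_back, na_mo = na_mo,
                 angular_mag = angular_mag, label = label),
            class = "grin_lens_spec")
}

#' @export
print.grin_lens_spec <- function(x, ...) {
  cat("GRIN lens spec", if (nzchar(x$label)) sprintf("(%s)", x$label), "\n")
  cat(sprintf("  pitch %.4f, sqrt(A) %.3f /mm, length %.3f mm\n",
              x$pitch, x$sqrt_a, x$length_mm))
  cat(sprintf("  L1 %.3f mm, n_front %.3f, n_back %.3f, NA_MO %.3f, M_a %.4f\n",
              x$front_wd_mm, x$n_front, x$n_back, x$na_mo, x$angular_mag))
  invisible(x)
}

#' GRIN lens length from pitch
#'
#' `Z = 2 pi P / sqrt(A)`: the length containing `P` full periods of the
#' sinusoidal ray path.
#'
#' @param pitch fractional pitch (dimensionless, > 0).
#' @param sqrt_a index distribution coefficient (1/mm, > 0).
#' @return length in mm.
#' @examples
#' lens_length(0.261, 0.299)  # ~5.485 mm
#' @export
lens_length <- function(pitch, sqrt_a) {
  if (any(!is.finite(pitch)) || any(pitch <= 0))
    stop("`pitch` must be positive and finite")
  if (any(!is.finite(sqrt_a)) || any(sqrt_a <= 0))
    stop("`sqrt_a` must be positive and finite")
  2 * pi * pitch / sqrt_a
}

# Numerator/denominator of the closed-form back working distance; shared by
# back_working_distance() and the pitch solver (which needs the denominator
# to detect the afocal pole).
bwd_terms <- function(n0, sqrt_a, z, l1, n1, n2) {
  s <- sin(z * sqrt_a)
  co <- cos(z * sqrt_a)
  list(num = -(n1 * n2 / sqrt_a) * s - n2 * n0 * l1 * co,
       den = n1 * n0 * co - n0^2 * l1 * sqrt_a * s)
}

#' Back working distance of a GRIN lens
#'
#' Closed-form paraxial conjugate distance `L2` from the back face of the
#' lens to the image plane in the back medium, for an object placed `L1` in
#' front of the lens in the front medium:
#' `L2 = (-(n1 n2 / sqrt(A)) sin(Z sqrt(A)) - n2 N0 L1 cos(Z sqrt(A))) /
#'       (n1 N0 cos(Z sqrt(A)) - N0^2 L1 sqrt(A) sin(Z sqrt(A)))`.
#' Identical to propagating a paraxial ray through the translation `L1/n1`,
#' the GRIN duct ABCD matrix and solving for the axis crossing in medium
#' `n2`.
#'
#' @param spec a [grin_lens_spec()].
#' @return signed `L2` in mm; positive means the conjugate plane lies in air
#'   beyond the back face.
#' @examples
#' back_working_distance(grin_lens_spec(0.261, 0.299))  # ~16 mm
#' @export
back_working_distance <- function(spec) {
  stopifnot(inherits(spec, "grin_lens_spec"))
  tm <- bwd_terms(spec$n0_axial, spec$sqrt_a, spec$length_mm,
                  spec$front_wd_mm, spec$n_front, spec$n_back)
  if (abs(tm$den) < 1e-9)
    stop("afocal/collimated configuration: the exit beam is parallel and ",
         "no finite conjugate plane exists for these parameters")
  tm$num / tm$den
}

#' Compound numerical aperture of the DO-MO assembly
#'
#' The excitation cone leaving the dry objective (half-angle `theta0`,
#' `NA_DO = sin(theta0)`) is angularly demagnified by the MO
#' (`M_a = theta0 / theta1`), so in water the compound NA is
#' `NA_comp = n1 sin(theta1) ~= n1 sin(theta0) / M_a = (n1 / M_a) NA_DO`
#' (small-angle form; `n1 = 1.33` for water).
#'
#' @param na_do nominal NA of the dry objective, in (0, 1).
#' @param ma angular magnification factor of the MO (> 0).
#' @param n1 refractive index of the immersion medium at the specimen.
#' @return `NA_comp` (dimensionless).
#' @examples
#' na_compound(0.055, 0.1675)  # ~0.44 for a x2/0.055 DO
#' @export
na_compound <- function(na_do, ma, n1 = 1.33) {
  if (any(na_do <= 0) || any(na_do >= 1))
    stop("`na_do` must lie in (0, 1)")
  if (any(ma <= 0)) stop("`ma` must be positive")
  n1 * na_do / ma
}

#' Effective numerical aperture
#'
#' The effective excitation NA at the specimen cannot exceed the nominal NA
#' of the MO: `NA_eff = min(NA_comp, NA_MO)`.
#'
#' @param na_comp compound NA from [na_compound()].
#' @param na_mo nominal NA of the MO.
#' @return `NA_eff`.
#' @examples
#' na_effective(na_compound(0.1, 0.1675), 0.483)  # capped at 0.483
#' @export
na_effective <- function(na_comp, na_mo) {
  if (any(na_comp <= 0) || any(na_mo <= 0))
    stop("both NA values must be positive")
  pmin(na_comp, na_mo)
}

#' Lateral magnification of the miniaturized objective
#'
#' From the Lagrange invariant, lateral and angular magnification of an
#' imaging system satisfy `M_L * M_a = n1 / n2`, so
#' `M_L = n1 / (M_a * n2)`. With the manufacturer's `M_a = 0.1675` and water
#' in front this gives the ~x8 lateral magnification of the MO.
#'
#' @param ma angular magnification factor (> 0).
#' @param n1 front-medium (specimen-side) refractive index.
#' @param n2 back-medium refractive index.
#' @return `M_L` (dimensionless).
#' @examples
#' lateral_magnification(0.1675)  # ~7.93
#' @export
lateral_magnification <- function(ma, n1 = 1.328, n2 = 1.0) {
  if (any(ma <= 0)) stop("`ma` must be positive")
  n1 / (ma * n2)
}

#' Dry-objective specification
#'
#' @param magnification lateral magnification of the DO (> 0).
#' @param na_do nominal NA, in (0, 1).
#' @param model free-text model label.
#' @return an object of class `dry_objective_spec`.
#' @examples
#' dry_objective_spec(4, 0.1, "Olympus MPlan N x4")
#' @export
dry_objective_spec <- function(magnification, na_do, model = "") {
  if (!is.numeric(magnification) || magnification <= 0)
    stop("`magnification` must be positive")
  if (!is.numeric(na_do) || na_do <= 0 || na_do >= 1)
    stop("`na_do` must lie in (0, 1)")
  structure(list(magnification = magnification, na_do = na_do, model = model),
            class = "dry_objective_spec")
}

#' @export
print.dry_objective_spec <- function(x, ...) {
  cat(sprintf("Dry objective x%g / %.3f %s\n", x$magnification, x$na_do,
              x$model))
  invisible(x)
}

#' NA coupling of a DO-MO pair
#'
#' Computes the excitation-cone half-angles and the compound and effective
#' numerical apertures for one dry objective coupled to one MO.
#'
#' @param do_spec a [dry_objective_spec()].
#' @param mo_spec a [grin_lens_spec()] supplying `na_mo` and `angular_mag`.
#' @param n1 immersion index used in the NA formula (water, 1.33).
#' @return an object of class `optical_coupling` with fields `na_do`, `ma`,
#'   `theta0`, `theta1`, `na_comp`, `na_mo`, `na_eff`, `n1`.
#' @examples
#' cp <- optical_coupling(dry_objective_spec(2, 0.055, "Mitutoyo x2"),
#'                        grin_lens_spec(0.261, 0.299))
#' cp$na_eff
#' @export
optical_coupling <- function(do_spec, mo_spec, n1 = 1.33) {
  stopifnot(inherits(do_spec, "dry_objective_spec"),
            inherits(mo_spec, "grin_lens_spec"))
  theta0 <- asin(do_spec$na_do)        # in air under the DO
  theta1 <- theta0 / mo_spec$angular_mag
  na_comp <- na_compound(do_spec$na_do, mo_spec$angular_mag, n1)
  structure(list(na_do = do_spec$na_do, ma = mo_spec$angular_mag,
                 theta0 = theta0, theta1 = theta1, na_comp = na_comp,
                 na_mo = mo_spec$na_mo,
                 na_eff = na_effective(na_comp, mo_spec$na_mo), n1 = n1),
            class = "optical_coupling")
}

#' @export
print.optical_coupling <- function(x, ...) {
  cat(sprintf("NA coupling: NA_DO %.3f, M_a %.4f -> NA_comp %.3f, NA_eff %.3f\n",
              x$na_do, x$ma, x$na_comp, x$na_eff))
  invisible(x)
}
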