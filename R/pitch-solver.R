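# Depth conjugation: choosing per-MO pitch values so that object planes at
# different tissue depths all image onto one common plane under the DO.
#
# Conjugation condition, with H the common height of the DO object plane
# above the brain surface and all lengths positive downward:
#     Z(P) + L2(P) = H + (target_depth - L1)
# i.e. the optical column from the MO object plane up to the DO object plane
# has the same total height for every MO.

conjugation_length_raw <- function(pitch, template) {
  z <- lens_length(pitch, template$sqrt_a)
  tm <- bwd_terms(template$n0_axial, template$sqrt_a, z,
                  template$front_wd_mm, template$n_front, template$n_back)
  list(z = z, l2 = tm$num / tm$den, den = tm$den)
}

#' Total conjugation length of a GRIN lens
#'
#' `Z + L2`: front face of the lens to the back conjugate plane. Under the
#' planarity condition this must equal `H + (target_depth - L1)` for every
#' MO of an assembly.
#'
#' @param spec a [grin_lens_spec()].
#' @return length in mm.
#' @export
conjugation_length <- function(spec) {
  spec$length_mm + back_working_distance(spec)
}

#' Forward target depth implied by a lens under a given assembly height
#'
#' Inverse of the conjugation condition: the tissue depth whose object plane
#' a given lens conjugates onto the common DO object plane at height
#' `conjugate_height_mm` above the surface.
#'
#' @param spec a [grin_lens_spec()].
#' @param conjugate_height_mm common DO object-plane height `H` (mm).
#' @return target depth below the brain surface (mm).
#' @export
forward_target_depth <- function(spec, conjugate_height_mm) {
  conjugation_length(spec) + spec$front_wd_mm - conjugate_height_mm
}

#' Solve the GRIN pitch that conjugates a given tissue depth
#'
#' Finds the pitch `P` (and hence length `Z` and back working distance `L2`)
#' for which `Z(P) + L2(P) - (target_depth - L1) - H = 0`, by bracketed 1-D
#' root finding on the continuous branch of the conjugation function (the
#' afocal pole, where the denominator of the `L2` expression vanishes, is
#' excluded by a bounded-value filter on a scan grid before root polishing).
#' The design additionally requires a portion of the lens to protrude above
#' the brain surface so it can be held and positioned; a non-positive
#' protrusion is an infeasible design.
#'
#' @param target_depth_mm desired object-plane depth below the brain surface
#'   (mm); must be at least the template's front working distance.
#' @param conjugate_height_mm common DO object-plane height `H` above the
#'   surface (mm).
#' @param template a [grin_lens_spec()] supplying all non-pitch parameters.
#' @param bracket pitch search bracket (default `c(0.15, 0.45)`).
#' @param tol_mm tolerance on the conjugation residual (default 1e-3 mm =
#'   1 um; the root itself is polished far below this).
#' @return a `grin_lens_spec` copy of `template` with updated `pitch` and
#'   `length_mm`, plus fields `target_depth_mm`, `conjugate_height_mm`,
#'   `back_wd_mm`, `conjugation_residual_mm` and `protrusion_mm`.
#' @examples
#' std <- grin_lens_spec(0.261, 0.299, label = "standard")
#' d <- forward_target_depth(std, conjugate_height_mm = 21.4)
#' solve_pitch_for_depth(d, 21.4, std)$pitch  # recovers 0.261
#' @export
solve_pitch_for_depth <- function(target_depth_mm, conjugate_height_mm,
                                  template, bracket = c(0.15, 0.45),
                                  tol_mm = 1e-3) {
  stopifnot(inherits(template, "grin_lens_spec"))
  if (target_depth_mm < template$front_wd_mm)
    stop("infeasible design: target depth (", target_depth_mm,
         " mm) is shallower than the front working distance (",
         template$front_wd_mm, " mm)")
  need <- conjugate_height_mm + (target_depth_mm - template$front_wd_mm)
  g <- function(p) {
    cl <- conjugation_length_raw(p, template)
    cl$z + cl$l2 - need
  }
  # scan for a sign change on the continuous branch; near the afocal pole
  # |g| blows up, so require both endpoint values to be moderate
  ps <- seq(bracket[1], bracket[2], length.out = 1201L)
  gv <- vapply(ps, g, numeric(1))
  ok <- is.finite(gv) & abs(gv) < 50
  idx <- which(ok[-length(ok)] & ok[-1] &
                 gv[-length(gv)] * gv[-1] <= 0)
  if (length(idx) == 0)
    stop("infeasible design: no conjugate solution for depth ",
         target_depth_mm, " mm at height ", conjugate_height_mm,
         " mm within the pitch bracket [", bracket[1], ", ", bracket[2],
         "] (conjugation constraint cannot be met)")
  i <- idx[1]
  root <- uniroot(g, lower = ps[i], upper = ps[i + 1], tol = 1e-12)
  p_star <- root$root
  cl <- conjugation_length_raw(p_star, template)
  residual <- abs(cl$z + cl$l2 - need)
  if (residual > tol_mm)
    stop("conjugation residual ", signif(residual, 3),
         " mm exceeds tolerance ", tol_mm, " mm")
  protrusion <- cl$z - (target_depth_mm - template$front_wd_mm)
  if (protrusion <= 0)
    stop("infeasible design: the lens has no portion outside the brain ",
         "tissue (protrusion ", signif(protrusion, 4), " mm <= 0); a lens ",
         "must protrude above the surface to be positioned and fixed")
  out <- grin_lens_spec(pitch = p_star, sqrt_a = template$sqrt_a,
                        n0_axial = template$n0_axial,
                        front_wd_mm = template$front_wd_mm,
                        n_front = template$n_front, n_back = template$n_back,
                        na_mo = template$na_mo,
                        angular_mag = template$angular_mag,
                        label = template$label)
  out$target_depth_mm <- target_depth_mm
  out$conjugate_height_mm <- conjugate_height_mm
  out$back_wd_mm <- cl$l2
  out$conjugation_residual_mm <- residual
  out$protrusion_mm <- protrusion
  out
}

#' Pitch-versus-depth design curve
#'
#' Solves the conjugation condition over a sweep of target depths, giving
#' the reference curve of pitch and derived lengths against imaging depth.
#'
#' @param depths_mm vector of target depths (mm).
#' @inheritParams solve_pitch_for_depth
#' @return a data.frame with columns `target_depth_mm`, `pitch`,
#'   `length_mm`, `back_wd_mm`, `conjugation_length_mm`, `protrusion_mm`.
#' @export
pitch_depth_curve <- function(depths_mm, conjugate_height_mm, template,
                              bracket = c(0.15, 0.45)) {
  rows <- lapply(depths_mm, function(d) {
    s <- solve_pitch_for_depth(d, conjugate_height_mm, template,
                               bracket = bracket)
    data.frame(target_depth_mm = d, pitch = s$pitch,
               length_mm = s$length_mm, back_wd_mm = s$back_wd_mm,
               conjugation_length_mm = s$length_mm + s$back_wd_mm,
               protrusion_mm = s$protrusion_mm)
  })
  do.call(rbind, rows)
}

#' Compound-assembly design
#'
#' Collects one dry objective and several MO placements (lens, lateral
#' offset from the DO axis, target depth) under a common conjugate height,
#' and verifies that every MO satisfies the planarity condition.
#'
#' @param do_spec a [dry_objective_spec()].
#' @param mo_entries list of entries, each a list with fields `spec`
#'   (a [grin_lens_spec()]), `lateral_offset_mm` (length-1 or length-2
#'   offset of the MO axis from the DO axis; a scalar is placed on the x
#'   axis) and `target_depth_mm`.
#' @param conjugate_height_mm common DO object-plane height `H` (mm).
#' @param residual_tol_mm maximum tolerated conjugation residual per MO.
#' @return an object of class `assembly_design`.
#' @export
assembly_design <- function(do_spec, mo_entries, conjugate_height_mm,
                            residual_tol_mm = 1e-3) {
  stopifnot(inherits(do_spec, "dry_objective_spec"), length(mo_entries) >= 1)
  entries <- lapply(mo_entries, function(e) {
    stopifnot(inherits(e$spec, "grin_lens_spec"),
              is.numeric(e$target_depth_mm))
    off <- e$lateral_offset_mm
    if (length(off) == 1) off <- c(off, 0)
    if (length(off) != 2) stop("`lateral_offset_mm` must have length 1 or 2")
    resid <- abs(conjugation_length(e$spec) -
                   (e$target_depth_mm - e$spec$front_wd_mm) -
                   conjugate_height_mm)
    if (resid > residual_tol_mm)
      stop("MO '", e$spec$label, "' misses the conjugation condition by ",
           signif(resid, 4), " mm (tolerance ", residual_tol_mm, " mm)")
    list(spec = e$spec, lateral_offset_mm = off,
         target_depth_mm = e$target_depth_mm,
         conjugation_residual_mm = resid,
         region = if (is.null(e$region)) e$spec$label else e$region)
  })
  structure(list(do_spec = do_spec, mo_entries = entries,
                 conjugate_height_mm = conjugate_height_mm),
            class = "assembly_design")
}

#' @export
print.assembly_design <- function(x, ...) {
  cat(sprintf("Assembly design: DO x%g/%.3f, %d MO(s), H = %.3f mm\n",
              x$do_spec$magnification, x$do_spec$na_do,
              length(x$mo_entries), x$conjugate_height_mm))
  for (e in x$mo_entries)
    cat(sprintf("  %-12s offset (%.2f, %.2f) mm, depth %.3f mm, residual %.2g mm\n",
                e$region, e$lateral_offset_mm[1], e$lateral_offset_mm[2],
                e$target_depth_mm, e$conjugation_residual_mm))
  invisible(x)
}
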