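# Reporting: golden-value checks of the optics engine and machine/human
# run reports.

#' Golden-value checks of the optics engine
#'
#' Recomputes the published design quantities (lens lengths, back working
#' distance, compound and effective NA, target-zone diameters, lateral
#' magnification, scan-field arithmetic) from the primary parameters and
#' compares each against its printed value at the stated tolerance.
#'
#' @return data.frame with columns `check`, `expected`, `computed`,
#'   `tol_rel`, `pass`.
#' @examples
#' all(golden_checks()$pass)
#' @export
golden_checks <- function() {
  std <- lens_template("table1_standard")
  lng <- lens_template("table1_long_coupling")
  geom <- scan_geometry()
  px <- pixel_size(geom)
  rows <- list(
    list("length Z, standard version (mm)", 5.49,
         lens_length(std$pitch, std$sqrt_a), 0.002),
    list("length Z, long-coupling version (mm)", 5.236,
         lens_length(lng$pitch, lng$sqrt_a), 0.002),
    list("back working distance L2, standard (mm)", 16,
         back_working_distance(std), 0.02),
    list("NA_comp, x2/0.055 DO", 0.44, na_compound(0.055, 0.1675), 0.01),
    list("NA_eff, x4/0.1 DO", 0.48,
         na_effective(na_compound(0.1, 0.1675), std$na_mo), 0.01),
    list("NA_eff, x2/0.055 DO", 0.43,
         na_effective(na_compound(0.055, 0.1675), std$na_mo), 0.02),
    list("lateral magnification M_L", 8, lateral_magnification(0.1675), 0.02),
    list("target zone, x2 DO (mm)", 12, target_zone_diameter(2), 1e-9),
    list("target zone, x2.5 DO (mm)", 9.6, target_zone_diameter(2.5), 1e-9),
    list("target zone, x4 DO (mm)", 6, target_zone_diameter(4), 1e-9),
    list("target zone, x5 DO (mm)", 4.8, target_zone_diameter(5), 1e-9),
    list("effective scan field (mm)", 4.3, geom$effective_field_mm, 0.01),
    list("pixel size at DO plane (um)", 4, px[["do_plane_um"]], 0.12),
    list("per-FOV laser power, 3 FOVs (mW)", 37, per_fov_power(112, 3), 0.01)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(check = r[[1]], expected = r[[2]], computed = r[[3]],
               tol_rel = r[[4]])))
  out$pass <- abs(out$computed - out$expected) <=
    out$tol_rel * abs(out$expected)
  out
}

#' Write a machine-readable and human-readable run report
#'
#' Serializes a results list (sections `design`, `simulate`, `analyze`,
#' each optional but expected) as deterministic JSON plus a plain-text
#' summary using the `median\\25th-75th percentiles` notation, and appends
#' the golden-value check table. Missing expected sections are flagged
#' with an explicit `INCOMPLETE` marker and a non-zero status.
#'
#' @param results named list of results.
#' @param dir output directory.
#' @param expected_sections section names that must be present.
#' @return invisibly, list with `status` (0 = complete, 1 = incomplete),
#'   `complete`, and the written `files`.
#' @export
write_report <- function(results, dir,
                         expected_sections = c("design", "simulate",
                                               "analyze")) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create report directory: ", dir)
  missing_sections <- setdiff(expected_sections, names(results))
  complete <- length(missing_sections) == 0
  gold <- golden_checks()
  payload <- list(complete = complete, missing_sections = missing_sections,
                  results = results, golden_checks = gold)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("matriex run report")
  if (!complete)
    wl("STATUS: INCOMPLETE (missing: %s)",
       paste(missing_sections, collapse = ", "))
  else wl("STATUS: complete")
  for (nm in names(results)) {
    wl("")
    wl("[%s]", nm)
    sec <- results[[nm]]
    if (is.list(sec)) {
      for (k in names(sec)) {
        v <- sec[[k]]
        if (is.numeric(v) && length(v) > 1)
          wl("  %s: %s", k, format_median_iqr(v))
        else if (is.atomic(v) && length(v) == 1)
          wl("  %s: %s", k, format(v))
      }
    }
  }
  wl("")
  wl("[golden checks]")
  for (i in seq_len(nrow(gold)))
    wl("  %-42s expected %-8s computed %-10s %s", gold$check[i],
       format(gold$expected[i]), format(signif(gold$computed[i], 5)),
       if (gold$pass[i]) "PASS" else "FAIL")
  invisible(list(status = if (complete) 0L else 1L, complete = complete,
                 files = c(json = json, txt = txt)))
}
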