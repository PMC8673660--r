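# Misalignment sweeps reproducing the bench experiments: decentration
# series (0..800 um) and tilt series (0..8 deg), field and ray engines
# side by side, with figure/table rendering.

#' Run an IOL decentration sweep
#'
#' For each decentration the IOL is posed, the field-traced PSF at the
#' fixed aligned focal screen and the ray-traced pupil PSF are computed,
#' and both Strehl ratios recorded. The aligned pose is always included as
#' the baseline.
#'
#' @param bench a calibrated `model_eye_bench`; focused automatically if
#'   needed.
#' @param distances decentrations in micrometres (sorted, within the
#'   +/-2000 um envelope); default from the bench configuration.
#' @param samples field grid samples per axis.
#' @param keep_psf logical; keep the PSF rasters in the result.
#' @return a `sweep_result`.
#' @export
run_decenter_sweep <- function(bench,
                               distances = bench$config$sweeps$decenter,
                               samples = bench$grid$n, keep_psf = FALSE) {
  run_pose_sweep(bench, "decenter", distances, samples, keep_psf)
}

#' Run an IOL tilt sweep
#'
#' @param bench a calibrated `model_eye_bench`.
#' @param angles tilt angles in degrees about the y axis.
#' @inheritParams run_decenter_sweep
#' @return a `sweep_result`.
#' @export
run_tilt_sweep <- function(bench, angles = bench$config$sweeps$tilt,
                           samples = bench$grid$n, keep_psf = FALSE) {
  run_pose_sweep(bench, "tilt", angles, samples, keep_psf)
}

run_pose_sweep <- function(bench, axis, values, samples, keep_psf) {
  if (is.unsorted(values)) stop("pose values must be sorted increasing")
  if (!0 %in% values) values <- sort(c(0, values))
  if (is.null(bench$screen_z)) bench <- focus_bench(bench,
                                                    samples = min(samples, 512))
  ref <- compute_field_psf(bench, samples = samples, ideal = TRUE)
  rows <- list(); psfs <- list()
  for (v in values) {
    bp <- if (axis == "decenter") set_misalignment(bench, v, 0) else
      set_misalignment(bench, 0, v)
    psf <- tryCatch(compute_field_psf(bp, samples = samples),
                    error = function(e)
                      stop(sprintf("pose %s = %g failed: %s", axis, v,
                                   conditionMessage(e))))
    rp <- ray_psf(bp, output_pitch = psf$pitch,
                  n_out = nrow(psf$intensity))
    rows[[length(rows) + 1L]] <- data.frame(
      pose = v, strehl_field = strehl(psf, ref), strehl_ray = rp$strehl)
    if (keep_psf) psfs[[as.character(v)]] <- list(field = psf, ray = rp)
  }
  structure(list(axis = axis, values = values,
                 strehl = do.call(rbind, rows),
                 psfs = if (keep_psf) psfs,
                 bench = bench,
                 provenance = c(bench$provenance,
                                list(samples = samples))),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep, %d poses (%s)\n", x$axis,
              length(x$values), paste(x$values, collapse = ", ")))
  print(x$strehl, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render sweep figures and tables
#'
#' Writes, for each sweep: a Strehl-vs-pose curve overlaying the field and
#' ray engines (PNG) with a CSV twin, and an MTF overlay panel set for the
#' three headline cases (aligned, 200-um decentration, 8-degree tilt) with
#' CSV twins. Re-running on identical inputs reproduces identical CSVs.
#'
#' @param results a `sweep_result` or list of them.
#' @param out_dir output directory (created if missing).
#' @param mtf_panels logical; also render the MTF comparison panels.
#' @param samples field grid samples for the MTF panels.
#' @return invisibly, the paths written.
#' @export
render_report <- function(results, out_dir, mtf_panels = TRUE,
                          samples = NULL) {
  if (inherits(results, "sweep_result")) results <- list(results)
  if (!length(results)) stop("need at least one sweep result")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (res in results) {
    base <- file.path(out_dir, paste0("strehl_", res$axis))
    utils::write.csv(format(res$strehl, digits = 10),
                     paste0(base, ".csv"), row.names = FALSE, quote = FALSE)
    grDevices::png(paste0(base, ".png"), 700, 500)
    unit <- if (res$axis == "decenter") "decentration (um)" else
      "tilt (degrees)"
    plot(res$strehl$pose, res$strehl$strehl_field, type = "b", pch = 16,
         col = "red3", ylim = c(0, 1), xlab = unit, ylab = "Strehl ratio",
         main = sprintf("IOL %s: field vs ray tracing", res$axis))
    graphics::lines(res$strehl$pose, res$strehl$strehl_ray, type = "b",
                    pch = 1, col = "blue3")
    graphics::legend("topright", c("field tracing", "ray tracing"),
                     col = c("red3", "blue3"), pch = c(16, 1), lty = 1)
    grDevices::dev.off()
    paths <- c(paths, paste0(base, c(".csv", ".png")))
  }
  if (mtf_panels) {
    bench <- results[[1]]$bench
    if (is.null(samples)) samples <- min(bench$grid$n, 1024)
    cases <- list(aligned = c(0, 0), decenter_200um = c(200, 0),
                  tilt_8deg = c(0, 8))
    for (nm in names(cases)) {
      po <- cases[[nm]]
      bp <- set_misalignment(bench, po[1], po[2])
      psf <- compute_field_psf(bp, samples = samples, n_out = 256)
      rp <- ray_psf(bp, output_pitch = psf$pitch, n_out = 256)
      mf <- mtf_from_psf(psf$intensity, psf$pitch)
      mr <- mtf_from_psf(rp$psf, psf$pitch)
      sel <- mf$freq <= 200
      tab <- data.frame(frequency_cyc_mm = mf$freq[sel],
                        mtf_field_x = mf$mtf_x[sel], mtf_ray_x = mr$mtf_x[sel],
                        mtf_field_y = mf$mtf_y[sel], mtf_ray_y = mr$mtf_y[sel])
      base <- file.path(out_dir, paste0("mtf_", nm))
      utils::write.csv(format(tab, digits = 10), paste0(base, ".csv"),
                       row.names = FALSE, quote = FALSE)
      grDevices::png(paste0(base, ".png"), 700, 500)
      plot(tab$frequency_cyc_mm, tab$mtf_field_x, type = "l", col = "red3",
           lwd = 2, ylim = c(0, 1), xlab = "spatial frequency (cycles/mm)",
           ylab = "MTF", main = sprintf("MTF, %s", gsub("_", " ", nm)))
      graphics::lines(tab$frequency_cyc_mm, tab$mtf_ray_x, col = "blue3",
                      lwd = 2, lty = 2)
      graphics::legend("topright", c("field tracing", "ray tracing"),
                       col = c("red3", "blue3"), lty = c(1, 2), lwd = 2)
      grDevices::dev.off()
      paths <- c(paths, paste0(base, c(".csv", ".png")))
    }
  }
  prov <- file.path(out_dir, "provenance.txt")
  write_provenance(results[[1]]$bench, prov)
  invisible(c(paths, prov))
}

#' Replace the IOL by an ideal aberration-free phase lens
#'
#' Swaps the calibrated aspheric IOL for an ideal thin phase lens of
#' identical paraxial power at the IOL centre plane. Used to expose the
#' spherical aberration the calibrated IOL compensates.
#'
#' @param bench a `model_eye_bench`.
#' @return the modified bench.
#' @export
swap_iol_ideal <- function(bench) {
  bench$iol_ideal <- TRUE
  bench
}
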