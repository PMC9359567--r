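# The two end-to-end analysis workflows, scripted as reproducible functions
# producing machine-readable reports.

report_common <- function(workflow, inputs) {
  list(workflow = workflow, inputs = inputs)
}

spectrum_to_df <- function(s) {
  data.frame(wavelength_nm = s$wavelengths, value = s$values)
}

#' Morphology-based filtering workflow
#'
#' The classical ROI-first approach: the user outlines corresponding
#' morphological substructures in each time point's image (the images are not
#' registered, so one ROI per time point is required), and the workflow
#' reports the agglomerated ROI spectra per time point plus a spectral change
#' report (crossing wavelengths, blue/red band-shift index) of every later
#' time point against T0.
#'
#' @param ts An `hsi_timeseries`.
#' @param rois Named list, one [polygon_annotation()] (or vertex matrix) per
#'   included time point; names are time-point labels. A missing ROI for an
#'   included time point is an error.
#' @param method Aggregation operator for ROI spectra (see [agg_spectrum()]).
#' @param normalize l1-normalize each pixel spectrum before aggregation
#'   (default `TRUE`; the band-shift index assumes normalized spectra).
#' @param blue_band,red_band Band-shift bands in nm.
#' @param timepoints Time points to include (default: those named in `rois`).
#' @return Object of class `hsi_workflow_report` (workflow `"morphology"`):
#'   `inputs`, `selections`, `spectra` (per time point), `shift_reports`
#'   (per non-T0 time point, vs T0 when T0 is included).
#' @export
run_morphology_workflow <- function(ts, rois, method = "mean", normalize = TRUE,
                                    blue_band = c(400, 500), red_band = c(600, 700),
                                    timepoints = names(rois)) {
  stopifnot(inherits(ts, "hsi_timeseries"))
  timepoints <- intersect(TIMEPOINTS, timepoints)
  missing_roi <- setdiff(timepoints, names(rois))
  if (length(missing_roi) > 0) {
    stop("missing ROI for included time point(s): ",
         paste(missing_roi, collapse = ", "),
         " (images are unregistered; draw one ROI per time point)", call. = FALSE)
  }
  selections <- list(); spectra <- list()
  for (tp in timepoints) {
    sel <- select_in_image(ts, tp, rois[[tp]])
    if (length(sel) == 0) stop("ROI at ", tp, " selects no masked pixel", call. = FALSE)
    selections[[tp]] <- sel
    spectra[[tp]] <- agg_spectrum(ts$cubes[[tp]], sel, method = method,
                                  normalized = normalize)
  }
  shift_reports <- list()
  if ("T0" %in% timepoints) {
    for (tp in setdiff(timepoints, "T0")) {
      shift_reports[[tp]] <- shift_report(spectra[["T0"]], spectra[[tp]],
                                          c("T0", tp), detected = selections[[tp]],
                                          blue_band = blue_band, red_band = red_band)
    }
  }
  structure(c(report_common("morphology",
                            list(sample_id = ts$sample_id, method = method,
                                 normalize = normalize, blue_band = blue_band,
                                 red_band = red_band, timepoints = timepoints)),
              list(selections = selections, spectra = spectra,
                   shift_reports = shift_reports)),
            class = "hsi_workflow_report")
}

#' Embedding-driven response analysis workflow
#'
#' Detects areas of spectral change without a spatial hypothesis: compute (or
#' reuse) the pooled embedding, hide all but two time points, detect
#' embedding regions exclusively populated by one of them (k-NN time-purity),
#' project the detection back to image masks and spectra, and quantify the
#' change (crossing wavelengths, band-shift index) between the region's
#' spectra at the two time points. The manual step of re-selecting "the same"
#' region at the other time point is automated by transferring the detected
#' pixel coordinates directly to the other cube; this assumes near-aligned
#' acquisitions and is flagged as approximate in the report.
#'
#' If the detected region is no larger than `min_region_fraction` of the tB
#' pixels it is treated as noise and the report carries
#' `no_exclusive_regions = TRUE` with an empty change report.
#'
#' @param ts An `hsi_timeseries`.
#' @param tA,tB The two time points to compare (tA earlier, typically "T0").
#' @param embedding Optional precomputed `hsi_embedding` (else computed here).
#' @param method,metric,seed,params Embedding settings when computing (see
#'   [compute_embedding()]).
#' @param k,purity Detection parameters (see
#'   [detect_timepoint_exclusive_regions()]).
#' @param min_region_fraction Detected-fraction threshold below which the
#'   "no exclusive regions" flag is raised (default 0.05).
#' @param agg Aggregation operator for the region spectra.
#' @param blue_band,red_band Band-shift bands in nm.
#' @return Object of class `hsi_workflow_report` (workflow
#'   `"embedding_driven"`): `inputs`, `detected` (selection),
#'   `detected_tB_pixels` (data frame), `no_exclusive_regions` (flag),
#'   `coordinate_transfer_approximate = TRUE`, `spectra` (region spectra at
#'   tA and tB, or `NULL`), `shift` (a `shift_report`, or `NULL`), `masks`.
#' @export
run_embedding_workflow <- function(ts, tA = "T0", tB = "T2", embedding = NULL,
                                   method = "umap", metric = "cosine",
                                   seed = 42, params = list(),
                                   k = 15, purity = 0.9,
                                   min_region_fraction = 0.05, agg = "mean",
                                   blue_band = c(400, 500), red_band = c(600, 700)) {
  stopifnot(inherits(ts, "hsi_timeseries"))
  tA <- match.arg(tA, TIMEPOINTS); tB <- match.arg(tB, TIMEPOINTS)
  if (tA == tB) stop("tA and tB must differ", call. = FALSE)
  e <- embedding %||% compute_embedding(ts, method = method, metric = metric,
                                        seed = seed, params = params)
  det <- detect_timepoint_exclusive_regions(e, tA, tB, k = k, purity = purity)
  n_tB <- sum(as.character(e$index$time_point) == tB)
  det_tB <- det$pixels[as.character(det$pixels$time_point) == tB, c("x", "y"),
                       drop = FALSE]
  frac <- nrow(det_tB) / n_tB
  inputs <- list(sample_id = ts$sample_id, tA = tA, tB = tB,
                 method = e$method, metric = e$metric, seed = e$seed,
                 params = e$params, k = k, purity = purity,
                 min_region_fraction = min_region_fraction, agg = agg,
                 blue_band = blue_band, red_band = red_band)
  base <- report_common("embedding_driven", inputs)
  if (frac <= min_region_fraction) {
    return(structure(c(base, list(
      detected = det, detected_tB_pixels = det_tB, detected_tB_fraction = frac,
      no_exclusive_regions = TRUE, coordinate_transfer_approximate = TRUE,
      spectra = NULL, shift = NULL, masks = NULL)),
      class = "hsi_workflow_report"))
  }
  # coordinate transfer: apply the detected tB pixel set to both cubes
  spec_a <- agg_spectrum(ts$cubes[[tA]], det_tB, method = agg, normalized = TRUE)
  spec_b <- agg_spectrum(ts$cubes[[tB]], det_tB, method = agg, normalized = TRUE)
  sel_both <- selection(rbind(data.frame(time_point = tA, det_tB),
                              data.frame(time_point = tB, det_tB)),
                        provenance = "composite",
                        visible_timepoints = c(tA, tB))
  proj <- project(sel_both, ts, e, method = agg, normalized = TRUE)
  structure(c(base, list(
    detected = det, detected_tB_pixels = det_tB, detected_tB_fraction = frac,
    no_exclusive_regions = FALSE, coordinate_transfer_approximate = TRUE,
    spectra = stats::setNames(list(spec_a, spec_b), c(tA, tB)),
    shift = shift_report(spec_a, spec_b, c(tA, tB), detected = det,
                         blue_band = blue_band, red_band = red_band),
    masks = proj$masks)),
    class = "hsi_workflow_report")
}

#' @export
print.hsi_workflow_report <- function(x, ...) {
  cat(sprintf("<hsi_workflow_report> %s workflow, sample '%s'\n",
              x$workflow, x$inputs$sample_id))
  if (x$workflow == "embedding_driven") {
    if (isTRUE(x$no_exclusive_regions)) {
      cat(sprintf("  no exclusive regions (detected fraction %.3f)\n",
                  x$detected_tB_fraction))
    } else {
      cat(sprintf("  detected %d %s pixels (fraction %.3f)\n",
                  nrow(x$detected_tB_pixels), x$inputs$tB, x$detected_tB_fraction))
      print(x$shift)
    }
  } else {
    for (tp in names(x$shift_reports)) print(x$shift_reports[[tp]])
  }
  invisible(x)
}

#' Write a workflow report to disk
#'
#' Serializes a report as `report.json` plus one spectrum CSV per time point
#' (columns `wavelength_nm`, `value`) and, optionally, pseudo-image PNGs with
#' the selection highlighted. Reports are pure functions of their inputs and
#' seeds, so re-running a workflow writes byte-identical JSON.
#'
#' @param report An `hsi_workflow_report`.
#' @param dir Output directory (created).
#' @param render Also write pseudo-image PNGs per time point (default FALSE).
#' @param ts Time series, required when `render = TRUE`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, render = FALSE, ts = NULL) {
  stopifnot(inherits(report, "hsi_workflow_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- report$spectra
  for (tp in names(spectra)) {
    utils::write.csv(spectrum_to_df(spectra[[tp]]),
                     file.path(dir, paste0("spectrum_", gsub(".", "p", tp, fixed = TRUE), ".csv")),
                     row.names = FALSE)
  }
  js <- list(workflow = report$workflow, inputs = report$inputs)
  if (report$workflow == "embedding_driven") {
    js$no_exclusive_regions <- isTRUE(report$no_exclusive_regions)
    js$detected_tB_fraction <- report$detected_tB_fraction
    js$detected_tB_pixels <- report$detected_tB_pixels
    js$coordinate_transfer_approximate <- TRUE
    if (!is.null(report$shift)) {
      js$shift <- list(time_pair = report$shift$time_pair,
                       crossings_nm = report$shift$crossings,
                       band_shift = report$shift$band_shift)
    }
  } else {
    js$shift_reports <- lapply(report$shift_reports, function(s) {
      list(time_pair = s$time_pair, crossings_nm = s$crossings,
           band_shift = s$band_shift)
    })
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (render) {
    stopifnot(inherits(ts, "hsi_timeseries"))
    for (tp in TIMEPOINTS) {
      img <- scale_to_uint8(render_pseudo(ts$cubes[[tp]], "mean"))
      write_pseudo_png(img, file.path(dir, paste0("pseudo_", gsub(".", "p", tp, fixed = TRUE), ".png")))
    }
  }
  invisible(dir)
}
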