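#' Write a cell to a sweep bundle
#'
#' A sweep bundle is one directory per cell holding `metadata.json` and
#' one `sweep_<k>.csv` per sweep with header `time_ms,value` (value in mV
#' for current clamp, pA for voltage clamp). All numbers are written with
#' fixed six-decimal formatting so that save -> load -> save is
#' byte-identical, which keeps bundles diffable across machines.
#'
#' @param cell A [cell_recording()].
#' @param bundle_path Directory to create (named after the cell id if the
#'   path's last component differs).
#' @return The bundle path, invisibly.
#' @seealso [load_cell()]
#' @export
save_cell <- function(cell, bundle_path) {
  stopifnot(inherits(cell, "cell_recording"))
  if (length(cell$sweeps) == 0L) stop("refusing to write an empty bundle")
  dir.create(bundle_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(bundle_path))
    stop("cannot create bundle directory ", bundle_path)

  sweep_meta <- lapply(cell$sweeps, function(sw) {
    m <- list(sweep_id = sw$sweep_id, modality = sw$modality,
              dt_ms = sw$dt_ms, units = sweep_units(sw),
              n_samples = length(sw$samples))
    if (!is.null(sw$stimulus)) m$stimulus <- unclass(sw$stimulus)
    m
  })
  meta <- list(format = "fsephys-sweep-bundle-v1",
               cell_id = cell$cell_id, genotype = cell$genotype,
               region = cell$region,
               holding_condition = cell$holding_condition,
               sweeps = unname(sweep_meta))
  if (!is.null(cell$passive)) meta$passive <- unclass(cell$passive)
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, file.path(bundle_path, "metadata.json"))

  for (k in seq_along(cell$sweeps)) {
    sw <- cell$sweeps[[k]]
    t_ms <- sweep_times(sw)
    con <- file(file.path(bundle_path, sprintf("sweep_%d.csv", k)), "w")
    writeLines("time_ms,value", con)
    writeLines(sprintf("%.6f,%.6f", t_ms, sw$samples), con)
    close(con)
  }
  invisible(bundle_path)
}

#' Read a cell from a sweep bundle
#'
#' Validates units, sampling interval and stimulus metadata while
#' loading; loading is a lossless round trip with [save_cell()] up to the
#' bundle's six-decimal number formatting.
#'
#' @param bundle_path Directory written by [save_cell()].
#' @return A [cell_recording()].
#' @export
load_cell <- function(bundle_path) {
  meta_file <- file.path(bundle_path, "metadata.json")
  if (!file.exists(meta_file))
    stop("bundle format error: missing metadata.json in ", bundle_path)
  meta <- jsonlite::fromJSON(meta_file, simplifyVector = FALSE)
  for (fld in c("cell_id", "genotype", "sweeps"))
    if (is.null(meta[[fld]]))
      stop("bundle format error: metadata field '", fld, "' missing")
  if (length(meta$sweeps) < 1L)
    stop("bundle format error: bundle lists no sweeps")

  sweeps <- vector("list", length(meta$sweeps))
  for (k in seq_along(meta$sweeps)) {
    sm <- meta$sweeps[[k]]
    for (fld in c("sweep_id", "modality", "dt_ms", "units"))
      if (is.null(sm[[fld]]))
        stop("bundle format error: sweep ", k, " metadata field '", fld,
             "' missing")
    expected_units <- switch(sm$modality, current_clamp = "mV",
                             voltage_clamp = "pA",
                             stop("bundle format error: sweep ", k,
                                  " has unknown modality '", sm$modality, "'"))
    if (!identical(sm$units, expected_units))
      stop("bundle format error: sweep ", k, " units '", sm$units,
           "' do not match modality ", sm$modality,
           " (expected ", expected_units, ")")
    csv <- file.path(bundle_path, sprintf("sweep_%d.csv", k))
    if (!file.exists(csv))
      stop("bundle format error: missing sweep file ", csv)
    d <- read.csv(csv, colClasses = "numeric")
    if (!identical(names(d), c("time_ms", "value")))
      stop("bundle format error: ", csv, " must have header time_ms,value")
    dts <- diff(d$time_ms)
    if (any(dts <= 0))
      stop("bundle format error: non-monotone time column in ", csv)
    if (max(abs(dts - sm$dt_ms)) > 1e-4)
      stop("bundle format error: time column of ", csv,
           " disagrees with metadata dt_ms = ", sm$dt_ms)
    stim <- restore_stimulus(sm$stimulus)
    sweeps[[k]] <- sweep_trace(d$value, dt_ms = sm$dt_ms,
                               modality = sm$modality, stimulus = stim,
                               sweep_id = sm$sweep_id)
  }

  passive <- if (!is.null(meta$passive)) {
    pp <- lapply(meta$passive, function(v) if (is.null(v)) NA_real_ else v)
    do.call(passive_props, pp)
  }
  cell_recording(cell_id = meta$cell_id, genotype = meta$genotype,
                 sweeps = sweeps,
                 region = if (is.null(meta$region)) "" else meta$region,
                 holding_condition = meta$holding_condition,
                 passive = passive)
}

restore_stimulus <- function(sm) {
  if (is.null(sm)) return(NULL)
  switch(sm$type,
         step  = step_protocol(sm$amplitude_pA, sm$onset_ms, sm$duration_ms),
         train = stim_train(unlist(sm$pulse_times_ms), sm$pulse_amplitude_nA,
                            sm$pulse_width_ms),
         stop("bundle format error: unknown stimulus type '", sm$type, "'"))
}
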