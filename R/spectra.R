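#' Construct a spectrum
#'
#' @param wavelengths strictly increasing grid in nm.
#' @param intensities detector units (raw/dark/white) or dimensionless
#'   reflectance.
#' @param role one of `"raw"`, `"dark"`, `"white"`, `"reflectance"`.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, intensities,
                     role = c("raw", "dark", "white", "reflectance")) {
  role <- match.arg(role)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have equal length")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  structure(
    list(wavelengths = wavelengths, intensities = intensities, role = role),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum role=%s, %d points, %.1f-%.1f nm>\n",
    x$role, length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)
  ))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    max(abs(a$wavelengths - b$wavelengths)) < 1e-9
}

#' Reference-normalize a raw spectrum
#'
#' Converts raw detector counts to reflectance using dark-field and
#' white-standard references: `(raw - dark) / (white - dark)` elementwise.
#'
#' @param raw,dark,white [spectrum()] objects on one common grid.
#' @return reflectance [spectrum()].
#' @export
normalize_spectrum <- function(raw, dark, white) {
  if (!same_grid(raw, dark) || !same_grid(raw, white)) {
    stop("raw, dark and white spectra must share one wavelength grid")
  }
  denom <- white$intensities - dark$intensities
  bad <- which(denom == 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "degenerate reference: white equals dark at %.1f nm",
      raw$wavelengths[bad[1]]
    ))
  }
  spectrum(
    raw$wavelengths,
    (raw$intensities - dark$intensities) / denom,
    role = "reflectance"
  )
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; reproduces polynomials up to
#' `polyorder` exactly, including at the edges, where the fit is carried by
#' the filter's transient rows.
#'
#' @param spec a [spectrum()].
#' @param window odd window length (default 11 points).
#' @param polyorder polynomial order, `< window` (default 3).
#' @return smoothed [spectrum()] with the same role and grid.
#' @export
smooth_spectrum <- function(spec, window = 11, polyorder = 3) {
  stopifnot(window %% 2 == 1, polyorder < window)
  if (window > length(spec$wavelengths)) {
    stop("smoothing window longer than the spectrum")
  }
  y <- signal::sgolayfilt(spec$intensities, p = polyorder, n = window)
  spectrum(spec$wavelengths, y, role = spec$role)
}

#' Trim and resample a spectrum onto a regular grid
#'
#' Linear interpolation onto the inclusive grid `seq(start, stop, step)`.
#' The canonical analysis grid of 468 to 720 nm at 0.5 nm yields 505 points.
#'
#' @param spec a [spectrum()].
#' @param start_nm,stop_nm,step_nm target grid in nm.
#' @return resampled [spectrum()].
#' @export
trim_resample <- function(spec, start_nm = 468, stop_nm = 720, step_nm = 0.5) {
  stopifnot(stop_nm > start_nm, step_nm > 0)
  if (start_nm < min(spec$wavelengths) || stop_nm > max(spec$wavelengths)) {
    stop("requested range lies outside the source spectrum coverage")
  }
  grid <- seq(start_nm, stop_nm, by = step_nm)
  y <- stats::approx(spec$wavelengths, spec$intensities, xout = grid)$y
  spectrum(grid, y, role = spec$role)
}

#' Average replicate spectra of one site
#'
#' @param replicates list of [spectrum()] objects on one common grid.
#' @return pointwise mean [spectrum()].
#' @export
average_site <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  ref <- replicates[[1]]
  for (s in replicates) {
    if (!same_grid(ref, s)) stop("replicates are on mixed wavelength grids")
  }
  m <- rowMeans(vapply(
    replicates, function(s) s$intensities, numeric(length(ref$intensities))
  ))
  spectrum(ref$wavelengths, m, role = ref$role)
}

#' Flag outlier spectra with a robust MAD rule
#'
#' Residuals are taken against the cohort median spectrum.  A value is an
#' outlier when it lies more than `times_mad` median absolute deviations from
#' the median of the residuals (both computed over all residuals, raw MAD
#' without a consistency constant); a row (spectrum) is flagged when more than
#' `row_fraction` of its values are outliers.  A cohort of identical rows has
#' zero MAD and flags nothing.  Typical no-contact "air" spectra sit near
#' unit reflectance across the whole band and are flagged at almost every
#' wavelength.
#'
#' @param x matrix of spectra, one row per spectrum, or a list of
#'   [spectrum()] objects on a common grid.
#' @param times_mad threshold in MAD units (default 1.5).
#' @param row_fraction fraction of flagged values needed to flag a row
#'   (default 0.75: a no-contact spectrum is outlying across the bulk of the
#'   band, whereas a merely offset tissue spectrum is not).
#' @return logical vector, one element per row; attributes `value_fraction`
#'   (per-row fraction of outlying values), `threshold` and `rule` document
#'   the decision.
#' @export
flag_outliers <- function(x, times_mad = 1.5, row_fraction = 0.75) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(s) s$intensities))
  }
  x <- as.matrix(x)
  if (nrow(x) < 5) stop("outlier flagging needs at least 5 spectra")
  med_spec <- apply(x, 2, stats::median)
  resid <- sweep(x, 2, med_spec)
  med_r <- stats::median(resid)
  mad_r <- stats::median(abs(resid - med_r))
  thr <- times_mad * mad_r
  out_vals <- abs(resid - med_r) > thr
  frac <- rowMeans(out_vals)
  flags <- frac > row_fraction
  attr(flags, "value_fraction") <- frac
  attr(flags, "threshold") <- thr
  attr(flags, "rule") <- sprintf(
    "value-level |resid - median| > %g * MAD (raw), row flagged when > %g of values outlying",
    times_mad, row_fraction
  )
  flags
}

#' Process a replicate acquisition into a classifier-ready dataset
#'
#' Fixed order, logged in the result metadata: normalize each replicate
#' against the references, Savitzky-Golay smooth, trim/resample to the
#' analysis grid, flag and drop outlier replicates, then average the
#' surviving replicates of every site.
#'
#' @param sim acquisition in the format of [simulate_spectra()] /
#'   [read_spectra_csv()].
#' @param tissue free-text tissue tag stored with the dataset.
#' @param start_nm,stop_nm,step_nm analysis grid (defaults 468-720 nm,
#'   0.5 nm).
#' @param window,polyorder Savitzky-Golay parameters.
#' @param times_mad,row_fraction outlier rule parameters, see
#'   [flag_outliers()].
#' @param outlier_scope `"cohort"` (default) applies the outlier rule across
#'   all replicates at once; `"site"` applies it within each site's
#'   replicate cohort (sites with fewer than 5 replicates fall back to the
#'   full cohort).
#' @return object of class `spectra_dataset`: list with `features` (site x
#'   wavelength matrix), `grid`, `labels` (factor, levels normal/tumor),
#'   `patient_id`, `site_id`, `tissue`, `replicate_flags` (logical per input
#'   replicate) and `meta` (processing log).
#' @export
process_spectra <- function(sim, tissue = "synthetic",
                            start_nm = 468, stop_nm = 720, step_nm = 0.5,
                            window = 11, polyorder = 3,
                            times_mad = 1.5, row_fraction = 0.75,
                            outlier_scope = c("cohort", "site")) {
  outlier_scope <- match.arg(outlier_scope)
  wl <- sim$wavelengths
  n <- ncol(sim$raw)
  grid <- seq(start_nm, stop_nm, by = step_nm)
  proc <- matrix(0, n, length(grid))
  for (j in seq_len(n)) {
    s <- spectrum(wl, sim$raw[, j], role = "raw")
    s <- normalize_spectrum(s, sim$dark, sim$white)
    s <- smooth_spectrum(s, window = window, polyorder = polyorder)
    s <- trim_resample(s, start_nm, stop_nm, step_nm)
    proc[j, ] <- s$intensities
  }
  site_ids <- unique(sim$labels$site_id)
  flags <- logical(n)
  if (outlier_scope == "site") {
    small <- logical(0)
    for (sid in site_ids) {
      rows <- which(sim$labels$site_id == sid)
      if (length(rows) >= 5) {
        flags[rows] <- flag_outliers(
          proc[rows, , drop = FALSE],
          times_mad = times_mad, row_fraction = row_fraction
        )
      } else {
        small <- c(small, rows)
      }
    }
    if (length(small) > 0) {
      flags[small] <- flag_outliers(
        proc, times_mad = times_mad, row_fraction = row_fraction
      )[small]
    }
  } else {
    flags <- as.logical(flag_outliers(
      proc, times_mad = times_mad, row_fraction = row_fraction
    ))
  }
  keep <- !flags
  feat <- matrix(NA_real_, length(site_ids), length(grid))
  lab <- character(length(site_ids))
  pat <- character(length(site_ids))
  kept_sites <- logical(length(site_ids))
  for (i in seq_along(site_ids)) {
    rows <- which(sim$labels$site_id == site_ids[i] & keep)
    kept_sites[i] <- length(rows) > 0
    if (!kept_sites[i]) next
    feat[i, ] <- colMeans(proc[rows, , drop = FALSE])
    lab[i] <- sim$labels$class[rows[1]]
    pat[i] <- sim$labels$patient_id[rows[1]]
  }
  structure(
    list(
      features = feat[kept_sites, , drop = FALSE],
      grid = grid,
      labels = factor(lab[kept_sites], levels = c("normal", "tumor")),
      patient_id = pat[kept_sites],
      site_id = site_ids[kept_sites],
      tissue = tissue,
      replicate_flags = as.logical(flags),
      meta = list(
        order = c("normalize", "smooth", "trim_resample",
                  "flag_outliers", "average_site"),
        grid = c(start_nm, stop_nm, step_nm),
        sg_window = window, sg_polyorder = polyorder,
        outlier_rule = sprintf(
          "value-level |resid - median| > %g * MAD (raw) vs %s median spectrum, row flagged when > %g of values outlying",
          times_mad, outlier_scope, row_fraction
        ),
        n_replicates = n, n_flagged = sum(flags)
      )
    ),
    class = "spectra_dataset"
  )
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectra_dataset: %d sites x %d wavelengths (%s), %s>\n",
    nrow(x$features), ncol(x$features),
    paste(table(x$labels), collapse = " normal / "), x$tissue
  ))
  invisible(x)
}

#' Write a processed dataset to CSV (+ JSON processing log)
#' @param dataset a `spectra_dataset`.
#' @param path CSV output path; a `.json` sidecar with the processing
#'   parameters is written next to it.
#' @return invisibly, `path`.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(
    site_id = dataset$site_id,
    label = as.character(dataset$labels),
    patient_id = dataset$patient_id,
    dataset$features,
    check.names = FALSE
  )
  names(df)[-(1:3)] <- sprintf("wl_%.1f", dataset$grid)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    dataset$meta, sub("\\.csv$", ".json", path),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#' @param path CSV path.
#' @param tissue tissue tag to attach.
#' @return a `spectra_dataset` (metadata restored from the JSON sidecar when
#'   present).
#' @export
read_dataset_csv <- function(path, tissue = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  grid <- as.numeric(sub("^wl_", "", names(df)[-(1:3)]))
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    list(
      features = as.matrix(df[, -(1:3), drop = FALSE]),
      grid = grid,
      labels = factor(df$label, levels = c("normal", "tumor")),
      patient_id = df$patient_id,
      site_id = df$site_id,
      tissue = tissue,
      replicate_flags = NULL,
      meta = meta
    ),
    class = "spectra_dataset"
  )
}
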