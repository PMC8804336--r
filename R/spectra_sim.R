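#' Configuration for the two-class reflectance spectra simulator
#'
#' Emulates a benchtop DRS acquisition: for every tissue site a fixed number
#' of replicate raw spectra are recorded together with dark-field and
#' white-standard reference spectra.  Class mean reflectance curves are
#' mixtures of Gaussian bumps on the wavelength grid; replicate-to-replicate
#' variability combines a per-replicate gain (contact pressure, illumination)
#' with per-point noise.  A configurable fraction of replicates is replaced by
#' near-unity "air" spectra, emulating lack of probe contact with the tissue.
#'
#' @param n_sites_per_class number of tissue sites per class.
#' @param replicates_per_site raw spectra acquired per site (default 20).
#' @param wavelength_grid numeric `c(start, stop, step)` in nm.
#' @param class_shapes named list with elements `normal` and `tumor`, each a
#'   data frame with columns `center`, `width` (nm) and `amplitude` describing
#'   Gaussian reflectance bumps added to a common baseline.
#' @param baseline baseline reflectance added under the bumps.
#' @param noise_sd multiplicative noise scale (per-point relative sd; half of
#'   it also acts as a per-replicate gain sd).
#' @param outlier_fraction fraction of replicates replaced by air spectra.
#' @param dark_level,white_level reference intensities in detector units.
#' @param n_patients sites are assigned to this many synthetic patients,
#'   round-robin within class.
#' @param seed integer seed; fixes all outputs.
#' @return object of class `spectra_sim_config`.
#' @export
spectra_sim_config <- function(n_sites_per_class = 40,
                               replicates_per_site = 20,
                               wavelength_grid = c(420, 1000, 0.5),
                               class_shapes = default_class_shapes(),
                               baseline = 0.25,
                               noise_sd = 0.03,
                               outlier_fraction = 0,
                               dark_level = 120,
                               white_level = 4000,
                               n_patients = 5,
                               seed = 1) {
  stopifnot(
    n_sites_per_class >= 1, replicates_per_site >= 1,
    length(wavelength_grid) == 3, wavelength_grid[3] > 0,
    wavelength_grid[2] > wavelength_grid[1],
    outlier_fraction >= 0, outlier_fraction < 1,
    noise_sd >= 0, baseline > 0
  )
  if (!all(c("normal", "tumor") %in% names(class_shapes))) {
    stop("class_shapes must define exactly the classes 'normal' and 'tumor'")
  }
  if (white_level <= dark_level) {
    stop("white_level must exceed dark_level at every wavelength")
  }
  structure(
    list(
      n_sites_per_class = as.integer(n_sites_per_class),
      replicates_per_site = as.integer(replicates_per_site),
      wavelength_grid = wavelength_grid,
      class_shapes = class_shapes,
      baseline = baseline,
      noise_sd = noise_sd,
      outlier_fraction = outlier_fraction,
      dark_level = dark_level,
      white_level = white_level,
      n_patients = as.integer(n_patients),
      seed = as.integer(seed)
    ),
    class = "spectra_sim_config"
  )
}

#' Default class reflectance shapes
#'
#' Broad bumps loosely shaped like hemoglobin-dominated soft-tissue
#' reflectance, with the tumor class redder (stronger long-wavelength rise)
#' and less reflective around 560 nm.
#'
#' @param separation multiplier on the tumor-vs-normal shape difference;
#'   1 gives the default separation, 0 makes the classes identical.
#' @return named list of bump tables for `normal` and `tumor`.
#' @export
default_class_shapes <- function(separation = 1) {
  normal <- data.frame(
    center = c(520, 620, 800),
    width = c(45, 70, 150),
    amplitude = c(0.18, 0.30, 0.22)
  )
  tumor <- normal
  tumor$amplitude <- normal$amplitude + separation * c(-0.10, 0.06, 0.10)
  tumor$center <- normal$center + separation * c(8, 12, 0)
  list(normal = normal, tumor = tumor)
}

#' Mean reflectance curve of a class
#'
#' @param shapes bump table (columns `center`, `width`, `amplitude`).
#' @param wavelengths grid in nm.
#' @param baseline baseline reflectance.
#' @return reflectance values in (0, 1), clipped at 0.97.
#' @export
class_reflectance <- function(shapes, wavelengths, baseline = 0.25) {
  r <- rep(baseline, length(wavelengths))
  for (i in seq_len(nrow(shapes))) {
    r <- r + shapes$amplitude[i] *
      exp(-((wavelengths - shapes$center[i])^2) / (2 * shapes$width[i]^2))
  }
  pmin(pmax(r, 0.01), 0.97)
}

#' Simulate a two-class DRS acquisition
#'
#' Raw replicate spectra are built as
#' `raw = dark + (white - dark) * reflectance * (1 + noise)`, so that the
#' reference normalization recovers the configured reflectance exactly when
#' `noise_sd = 0`.  Injected air outliers are recorded in the hidden
#' `is_outlier` truth column of the label table for test use.
#'
#' @param config a [spectra_sim_config()].
#' @return list with:
#'   * `wavelengths`: common grid (nm);
#'   * `raw`: matrix `length(grid) x n_replicates` of raw intensities;
#'   * `dark`, `white`: reference [spectrum()] objects;
#'   * `labels`: data frame with one row per replicate (`replicate`,
#'     `site_id`, `class`, `patient_id`, `is_outlier`);
#'   * `reflectance`: matrix of the noise-free reflectance used per replicate.
#' @export
simulate_spectra <- function(config) {
  g <- config$wavelength_grid
  wl <- seq(g[1], g[2], by = g[3])
  n_rep <- config$replicates_per_site
  n_sites <- 2L * config$n_sites_per_class
  n_tot <- n_sites * n_rep
  classes <- rep(c("normal", "tumor"), each = config$n_sites_per_class)
  site_id <- sprintf("site_%03d", seq_len(n_sites))
  patient_id <- sprintf(
    "patient_%02d",
    1 + (seq_len(config$n_sites_per_class) - 1) %% config$n_patients
  )
  patient_id <- c(patient_id, patient_id) # same patient pool for both classes
  dark <- rep(config$dark_level, length(wl))
  white <- rep(config$white_level, length(wl))
  mean_refl <- list(
    normal = class_reflectance(config$class_shapes$normal, wl, config$baseline),
    tumor = class_reflectance(config$class_shapes$tumor, wl, config$baseline)
  )
  with_seed(config$seed, {
    labels <- data.frame(
      replicate = seq_len(n_tot),
      site_id = rep(site_id, each = n_rep),
      class = rep(classes, each = n_rep),
      patient_id = rep(patient_id, each = n_rep),
      is_outlier = FALSE,
      stringsAsFactors = FALSE
    )
    n_out <- round(config$outlier_fraction * n_tot)
    if (n_out > 0) {
      labels$is_outlier[sample.int(n_tot, n_out)] <- TRUE
    }
    # per-site biological variation (gain and a mild spectral tilt); scales
    # with noise_sd so that noise_sd = 0 gives exactly the class curves
    site_gain <- 1 + stats::rnorm(n_sites, 0, 1.5 * config$noise_sd)
    site_tilt <- stats::rnorm(n_sites, 0, config$noise_sd)
    wl_c <- (wl - mean(wl)) / (max(wl) - min(wl))
    refl <- matrix(0, length(wl), n_tot)
    raw <- matrix(0, length(wl), n_tot)
    for (j in seq_len(n_tot)) {
      s <- (j - 1) %/% n_rep + 1
      if (labels$is_outlier[j]) {
        r <- pmin(0.95 + 0.02 * sin(wl / 120) +
          stats::rnorm(length(wl), 0, config$noise_sd / 2), 1.05)
      } else {
        gain <- 1 + stats::rnorm(1, 0, config$noise_sd / 2)
        r <- mean_refl[[labels$class[j]]] *
          site_gain[s] * (1 + site_tilt[s] * wl_c) * gain
      }
      refl[, j] <- r
      noise <- if (config$noise_sd > 0) {
        stats::rnorm(length(wl), 0, config$noise_sd)
      } else {
        0
      }
      raw[, j] <- dark + (white - dark) * r * (1 + noise)
    }
    list(
      wavelengths = wl,
      raw = raw,
      dark = spectrum(wl, dark, role = "dark"),
      white = spectrum(wl, white, role = "white"),
      labels = labels,
      reflectance = refl
    )
  })
}

#' Write a simulated acquisition to CSV files
#'
#' Spectra files have a `wavelength_nm` first column and one column per
#' replicate; comma separated, `.` decimal, UTF-8.
#'
#' @param sim output of [simulate_spectra()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_spectra_csv <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  raw <- data.frame(wavelength_nm = sim$wavelengths, sim$raw)
  names(raw)[-1] <- sprintf("rep_%04d", seq_len(ncol(sim$raw)))
  paths <- c(
    raw = file.path(out_dir, "raw.csv"),
    dark = file.path(out_dir, "dark.csv"),
    white = file.path(out_dir, "white.csv"),
    labels = file.path(out_dir, "labels.csv")
  )
  utils::write.csv(raw, paths["raw"], row.names = FALSE)
  utils::write.csv(
    data.frame(wavelength_nm = sim$wavelengths, intensity = sim$dark$intensities),
    paths["dark"],
    row.names = FALSE
  )
  utils::write.csv(
    data.frame(wavelength_nm = sim$wavelengths, intensity = sim$white$intensities),
    paths["white"],
    row.names = FALSE
  )
  utils::write.csv(sim$labels, paths["labels"], row.names = FALSE)
  invisible(paths)
}

#' Read an acquisition written by [write_spectra_csv()]
#' @param dir directory containing `raw.csv`, `dark.csv`, `white.csv`,
#'   `labels.csv`.
#' @return list in the format of [simulate_spectra()] (without the hidden
#'   `reflectance` matrix).
#' @export
read_spectra_csv <- function(dir) {
  raw <- utils::read.csv(file.path(dir, "raw.csv"))
  dark <- utils::read.csv(file.path(dir, "dark.csv"))
  white <- utils::read.csv(file.path(dir, "white.csv"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  wl <- raw$wavelength_nm
  list(
    wavelengths = wl,
    raw = as.matrix(raw[, -1, drop = FALSE]),
    dark = spectrum(wl, dark$intensity, role = "dark"),
    white = spectrum(wl, white$intensity, role = "white"),
    labels = labels
  )
}
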