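wl <- seq(400, 900, by = 0.5)

test_that("reference normalization satisfies its defining identities", {
  dark <- spectrum(wl, rep(100, length(wl)), role = "dark")
  white <- spectrum(wl, rep(4000, length(wl)), role = "white")
  as_raw <- function(v) spectrum(wl, v, role = "raw")

  expect_equal(
    normalize_spectrum(as_raw(white$intensities), dark, white)$intensities,
    rep(1, length(wl))
  )
  expect_equal(
    normalize_spectrum(as_raw(dark$intensities), dark, white)$intensities,
    rep(0, length(wl))
  )
  expect_equal(
    normalize_spectrum(
      as_raw((white$intensities + dark$intensities) / 2), dark, white
    )$intensities,
    rep(0.5, length(wl))
  )
})

test_that("a degenerate reference names the offending wavelength", {
  dark <- spectrum(wl, rep(100, length(wl)), role = "dark")
  w <- rep(4000, length(wl))
  w[wl == 650] <- 100
  white <- spectrum(wl, w, role = "white")
  raw <- spectrum(wl, rep(500, length(wl)))
  expect_error(normalize_spectrum(raw, dark, white), "650")
  expect_error(
    normalize_spectrum(spectrum(wl[-1], rep(1, length(wl) - 1)), dark, white),
    "grid"
  )
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  x <- (wl - 650) / 100
  cubic <- spectrum(wl, 0.3 + 0.2 * x - 0.05 * x^2 + 0.01 * x^3)
  sm <- smooth_spectrum(cubic, window = 11, polyorder = 3)
  expect_lt(max(abs(sm$intensities - cubic$intensities)), 1e-10)

  const <- spectrum(wl, rep(0.7, length(wl)))
  expect_equal(smooth_spectrum(const)$intensities, const$intensities,
               tolerance = 1e-12)
})

test_that("smoothing shrinks white-noise variance and is linear", {
  set.seed(14)
  noisy <- spectrum(wl, rnorm(length(wl)))
  sm <- smooth_spectrum(noisy, window = 11)
  expect_lt(stats::var(sm$intensities), stats::var(noisy$intensities))

  f <- spectrum(wl, sin(wl / 40))
  g <- spectrum(wl, rnorm(length(wl)))
  lhs <- smooth_spectrum(spectrum(wl, 2 * f$intensities + 3 * g$intensities))
  rhs <- 2 * smooth_spectrum(f)$intensities + 3 * smooth_spectrum(g)$intensities
  expect_lt(max(abs(lhs$intensities - rhs)), 1e-10)

  expect_error(smooth_spectrum(spectrum(1:5, 1:5), window = 11), "longer")
})

test_that("the canonical analysis grid has 505 points", {
  s <- spectrum(wl, runif(length(wl)))
  out <- trim_resample(s, 468, 720, 0.5)
  expect_length(out$wavelengths, 505)
  expect_equal(out$wavelengths[1], 468)
  expect_equal(out$wavelengths[505], 720)
})

test_that("resampling onto the source grid is the identity, and idempotent", {
  sub <- seq(468, 720, by = 0.5)
  s <- spectrum(sub, runif(length(sub)))
  out <- trim_resample(s, 468, 720, 0.5)
  expect_equal(out$intensities, s$intensities, tolerance = 1e-12)
  twice <- trim_resample(out, 468, 720, 0.5)
  expect_equal(twice$intensities, out$intensities, tolerance = 1e-12)
  expect_error(trim_resample(s, 400, 1000, 0.5), "outside")
})

test_that("site averaging is the pointwise mean on a common grid", {
  flat <- function(v) spectrum(wl, rep(v, length(wl)))
  expect_equal(
    average_site(list(flat(0.2), flat(0.4)))$intensities,
    rep(0.3, length(wl))
  )
  one <- spectrum(wl, runif(length(wl)))
  expect_equal(average_site(rep(list(one), 20))$intensities, one$intensities)
  expect_error(
    average_site(list(one, spectrum(wl + 1, one$intensities))),
    "mixed"
  )
})

test_that("replicate averaging concentrates as 1/sqrt(n)", {
  res <- make_dataset(n_per_class = 1, seed = 6)
  sim <- res$sim
  truth <- sim$reflectance
  refl <- (sim$raw - sim$dark$intensities) /
    (sim$white$intensities - sim$dark$intensities)
  reps <- which(sim$labels$site_id == "site_001")
  m <- rowMeans(refl[, reps])
  mu <- rowMeans(truth[, reps])
  sdev <- res$config$noise_sd * mu
  expect_true(all(abs(m - mu) < 4 * sdev / sqrt(length(reps))))
})

test_that("a lone air spectrum among identical rows is the only flag", {
  base <- sin(seq(0, 3, length.out = 200)) * 0.2 + 0.4
  x <- matrix(rep(base, each = 21), nrow = 21)
  x[21, ] <- 0.97
  flags <- flag_outliers(x)
  expect_equal(which(flags), 21)

  all_same <- matrix(rep(base, each = 10), nrow = 10)
  expect_false(any(flag_outliers(all_same)))

  expect_error(flag_outliers(x[1:3, ]), "at least 5")
})

test_that("injected air outliers are recovered from a full acquisition", {
  res <- make_dataset(n_per_class = 15, outlier_fraction = 0.1, seed = 31)
  ds <- process_spectra(res$sim)
  flags <- ds$replicate_flags
  truth <- res$sim$labels$is_outlier
  expect_gte(sum(flags & truth) / sum(truth), 0.9)
  expect_lte(sum(flags & !truth) / sum(!truth), 0.05)
})

test_that("processing yields a clean dataset with a logged order", {
  res <- make_dataset(n_per_class = 6, outlier_fraction = 0.05, seed = 13)
  ds <- process_spectra(res$sim)
  expect_s3_class(ds, "spectra_dataset")
  expect_false(any(is.na(ds$features)))
  expect_equal(ncol(ds$features), 505)
  expect_equal(levels(ds$labels), c("normal", "tumor"))
  expect_equal(
    ds$meta$order,
    c("normalize", "smooth", "trim_resample", "flag_outliers", "average_site")
  )
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ds.csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(unname(back$features), unname(ds$features), tolerance = 1e-10)
  expect_equal(back$labels, ds$labels)
})
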