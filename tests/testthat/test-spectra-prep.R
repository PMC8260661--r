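test_that("wavelength grids are inclusive arithmetic sequences", {
  expect_length(wavelength_grid(350, 1830, 1)$wavelengths, 1481L)
  g <- wavelength_grid(905, 1649, 6)
  expect_length(g$wavelengths, 125L)
  expect_equal(g$wavelengths[125], 1649)
  expect_equal(wavelength_grid(500, 500, 1)$wavelengths, 500)
  expect_error(wavelength_grid(500, 600, 0), "positive")
  expect_error(wavelength_grid(600, 500, 1), ">=")
})

test_that("absorbance transform is decadic log of 1/R", {
  expect_equal(absorbance_from_reflectance(1), 0)
  expect_equal(absorbance_from_reflectance(0.01), 2)
  expect_equal(absorbance_from_reflectance(c(0.1, 0.5)),
               c(1, log10(2)), tolerance = 1e-12)
  expect_error(absorbance_from_reflectance(0), "> 0")
  expect_error(absorbance_from_reflectance(c(0.5, -1)), "> 0")
})

make_raw <- function(values, grid) {
  structure(list(grid = grid, values = values), class = "raw_spectra")
}

test_that("replicate averaging takes the grand mean and flags gaps", {
  grid <- wavelength_grid(500, 501, 1)
  v <- array(2.5, dim = c(2, 5, 3, 2), dimnames = list(c("a1", "a2")))
  avg <- average_replicates(make_raw(v, grid))
  expect_equal(unname(avg$values), matrix(2.5, 2, 2))

  # one animal, one wavelength, cell values 1..15 -> mean 8
  g1 <- wavelength_grid(600, 600, 1)
  v1 <- array(1:15, dim = c(1, 5, 3, 1), dimnames = list("a1"))
  expect_equal(unname(average_replicates(make_raw(v1, g1))$values[1, 1]), 8)

  # 12 of 15 cells present: mean over the 12, flagged incomplete
  v1[1, 1:3, 1, 1] <- NA
  a <- average_replicates(make_raw(v1, g1))
  manual <- mean(v1[1, , , 1], na.rm = TRUE)
  expect_equal(unname(a$values[1, 1]), manual)
  expect_equal(a$incomplete, "a1")

  # an animal with nothing at all is excluded with a reason
  v2 <- array(1, dim = c(3, 5, 3, 2), dimnames = list(c("a1", "a2", "a3")))
  v2[2, , , ] <- NA
  a2 <- average_replicates(make_raw(v2, grid))
  expect_equal(rownames(a2$values), c("a1", "a3"))
  expect_equal(a2$excluded$animal, "a2")
  expect_equal(a2$excluded$reason, "no spectra")
})

test_that("Mahalanobis editing flags injected outliers and nothing else", {
  # 13 wavelengths at n = 80: the score space stays small relative to the
  # sample, so a 10-SD displacement is far outside the clean GH range
  cfg <- sim_config(n_animals = 80, n_sires = 10, n_dams = 75, n_herds = 4,
                    n_batches = 5, grid = wavelength_grid(905, 977, 6),
                    instrument = "micronir", seed = 3)
  ds <- simulate_dataset(cfg)

  avg_clean <- average_replicates(ds$spectra)
  ed_clean <- mahalanobis_edit(avg_clean)
  expect_equal(nrow(ed_clean$values), 80L)

  # threshold = Inf never excludes
  ed_inf <- mahalanobis_edit(avg_clean, threshold = Inf)
  expect_equal(ed_inf$values, avg_clean$values)

  spiked <- inject_outliers(ds$spectra, k = 5, magnitude = 10, seed = 99)
  expect_length(attr(spiked, "injected"), 5L)
  ed <- mahalanobis_edit(average_replicates(spiked))
  flagged <- ed$excluded$animal[ed$excluded$stage == "mahalanobis"]
  expect_setequal(flagged, attr(spiked, "injected"))

  # identical spectra: all distances zero (svd sees no variance)
  flat <- array(1, dim = c(5, 2, 2, 3), dimnames = list(paste0("a", 1:5)))
  g3 <- wavelength_grid(500, 502, 1)
  ed_flat <- mahalanobis_edit(average_replicates(make_raw(flat, g3)))
  expect_equal(nrow(ed_flat$values), 5L)
  expect_error(mahalanobis_edit(average_replicates(
    make_raw(flat[1:2, , , , drop = FALSE], g3))), "at least 3")
})

test_that("standardization yields exact z-scores and is idempotent", {
  set.seed(5)
  grid <- wavelength_grid(700, 704, 1)
  M <- matrix(rnorm(40 * 5, mean = 1.2, sd = 0.3), 40, 5,
              dimnames = list(paste0("a", 1:40), NULL))
  mat <- structure(list(grid = grid, values = M, stage = "averaged",
                        excluded = NULL, incomplete = character(0)),
                   class = "spectra_matrix")
  z <- center_standardize(mat)
  expect_lt(max(abs(colMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-10)
  z2 <- center_standardize(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-10)

  M[, 3] <- 2
  mat$values <- M
  expect_error(center_standardize(mat), "702")
})

test_that("min-cell filter reaches a fixpoint through cascades", {
  d <- data.frame(animal = paste0("a", 1:7),
                  herd = c("h1", "h1", "h1", "h1", "h1", "h2", "h2"),
                  batch = "b1", stringsAsFactors = FALSE)
  f <- min_cell_filter(d)
  expect_equal(f$animal, paste0("a", 1:5))
  expect_equal(attr(f, "dropped")$animal, c("a6", "a7"))

  # all cells >= 3: unchanged
  d2 <- data.frame(animal = paste0("a", 1:6),
                   herd = rep(c("h1", "h2"), each = 3),
                   batch = rep(c("b1", "b2"), 3), stringsAsFactors = FALSE)
  expect_equal(min_cell_filter(d2)$animal, d2$animal)

  # cascade: dropping the 2-animal herd pushes batch b2 from 3 to 2
  d3 <- data.frame(
    animal = paste0("a", 1:9),
    herd = c("h1", "h1", "h1", "h1", "h2", "h2", "h3", "h3", "h3"),
    batch = c("b1", "b1", "b1", "b2", "b2", "b2", "b3", "b3", "b3"),
    stringsAsFactors = FALSE)
  f3 <- min_cell_filter(d3)
  expect_setequal(f3$animal, c("a1", "a2", "a3", "a7", "a8", "a9"))
  expect_setequal(attr(f3, "dropped")$animal, c("a4", "a5", "a6"))

  d4 <- data.frame(animal = c("x", "y"), herd = c("h1", "h2"),
                   batch = c("b1", "b2"), stringsAsFactors = FALSE)
  expect_error(min_cell_filter(d4), "no animals survive")
})

test_that("preprocessing conserves animals across kept + excluded", {
  cfg <- sim_config(n_animals = 60, n_sires = 8, n_dams = 55, n_herds = 4,
                    n_batches = 5, grid = wavelength_grid(905, 1001, 6),
                    instrument = "micronir", seed = 8)
  ds <- simulate_dataset(cfg)
  spiked <- inject_outliers(ds$spectra, k = 2, magnitude = 12, seed = 4)
  prep <- preprocess_spectra(spiked, ds$design)
  kept <- rownames(prep$spectra$values)
  gone <- prep$exclusions$animal
  expect_setequal(c(kept, gone), ds$design$animal)
  expect_equal(prep$design$animal, kept)  # aligned
  expect_s3_class(prep$spectra, "spectra_matrix")
  expect_equal(prep$spectra$stage, "standardized")
})

test_that("spectra CSV round-trips in long and wide dialects", {
  cfg <- sim_config(n_animals = 6, n_sires = 2, n_dams = 6, n_herds = 2,
                    n_batches = 2, grid = wavelength_grid(905, 917, 6),
                    instrument = "micronir", n_positions = 2,
                    n_replicates = 2, seed = 13)
  ds <- simulate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, path)
  back <- read_spectra_csv(path)
  expect_equal(back$grid$wavelengths, ds$spectra$grid$wavelengths)
  expect_equal(dimnames(back$values)[[1]], dimnames(ds$spectra$values)[[1]])
  expect_equal(unname(back$values), unname(ds$spectra$values),
               tolerance = 1e-9)

  # wide dialect
  wide_path <- withr::local_tempfile(fileext = ".csv")
  long <- utils::read.csv(path)
  wide <- reshape(long, idvar = c("animal", "position", "replicate"),
                  timevar = "wavelength", direction = "wide")
  names(wide) <- sub("^absorbance\\.", "w", names(wide))
  utils::write.csv(wide, wide_path, row.names = FALSE)
  back2 <- read_spectra_csv(wide_path)
  expect_equal(back2$grid$wavelengths, ds$spectra$grid$wavelengths)
  expect_equal(sort(dimnames(back2$values)[[1]]),
               sort(dimnames(ds$spectra$values)[[1]]))
})
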