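test_that("design structures encode incidence and relationship correctly", {
  ped <- pedigree(data.frame(animal = sprintf("a%d", 1:6), sire = NA,
                             dam = NA))
  design <- data.frame(animal = sprintf("a%d", 1:6),
                       herd = rep(c("h1", "h2"), each = 3),
                       batch = rep(c("b1", "b2"), 3),
                       stringsAsFactors = FALSE)
  dsn <- mixed_model_design(design, ped)
  expect_equal(dim(dsn$B$herd), c(6L, 6L))
  # same-herd indicator blocks: row sums equal the animal's herd size
  expect_equal(unname(rowSums(dsn$B$herd)), rep(3, 6))
  expect_equal(unname(rowSums(dsn$B$batch)), rep(3, 6))
  expect_true(all(dsn$B$herd %in% 0:1))
  expect_equal(dsn$q_levels[["herd"]], 2)
  expect_equal(dsn$X, matrix(1, 6, 1))

  # the additive structure picks exactly the phenotyped block of A
  rp <- random_pedigree(30, 41)
  phen <- rp$animal[15:30]
  d2 <- data.frame(animal = phen, herd = rep(c("x", "y"), each = 8),
                   batch = rep(c("u", "v"), 8), stringsAsFactors = FALSE)
  dsn2 <- mixed_model_design(d2, rp)
  A <- relationship_matrix(rp)$A
  expect_equal(dsn2$B$additive, A[phen, phen])
  expect_error(mixed_model_design(data.frame(animal = "zz"), rp), "missing")
})

test_that("restricted likelihood matches closed form and a naive oracle", {
  set.seed(51)
  # sigma_c = sigma_q = sigma_a = 0: iid closed form in sigma_e and SS
  ped <- pedigree(data.frame(animal = sprintf("i%d", 1:10), sire = NA,
                             dam = NA))
  d <- data.frame(animal = sprintf("i%d", 1:10), stringsAsFactors = FALSE)
  dsn <- mixed_model_design(d, ped)
  y <- rnorm(10, 2, 1.3)
  s2e <- 0.8
  n <- 10
  ss <- sum((y - mean(y))^2)
  closed <- -0.5 * (n * log(s2e) + log(n / s2e) + ss / s2e)
  expect_equal(reml_loglik(dsn, y, c(additive = 0, residual = s2e)),
               closed, tolerance = 1e-9)

  # permutation invariance of the record order
  rp <- random_pedigree(40, 52)
  phen <- rp$animal[21:40]
  d3 <- data.frame(animal = phen, herd = rep(c("h1", "h2"), 10),
                   batch = rep(c("b1", "b2"), each = 10),
                   stringsAsFactors = FALSE)
  y3 <- rnorm(20)
  theta <- c(herd = 0.2, batch = 0.3, additive = 0.5, residual = 0.6)
  ll <- reml_loglik(mixed_model_design(d3, rp), y3, theta)
  perm <- sample(20)
  ll_p <- reml_loglik(mixed_model_design(d3[perm, ], rp), y3[perm], theta)
  expect_equal(ll, ll_p, tolerance = 1e-9)

  # dense naive oracle on 15 animals with all four components
  rp2 <- random_pedigree(30, 53)
  phen2 <- rp2$animal[16:30]
  d4 <- data.frame(animal = phen2, herd = rep(c("h1", "h2", "h3"), 5),
                   batch = rep(c("b1", "b2", "b3"), each = 5),
                   stringsAsFactors = FALSE)
  dsn4 <- mixed_model_design(d4, rp2)
  y4 <- rnorm(15, 1, 0.7)
  for (theta in list(c(herd = 0.1, batch = 0.25, additive = 0.4,
                       residual = 0.5),
                     c(herd = 1e-3, batch = 2, additive = 0.05,
                       residual = 1))) {
    expect_equal(reml_loglik(dsn4, y4, theta),
                 naive_reml_loglik(y4, dsn4$X, dsn4$B, theta),
                 tolerance = 1e-9)
  }
})

test_that("accepted REML iterations never decrease the likelihood", {
  sd <- small_scan_data(n_wl = 3, seed = 55)
  dsn <- mixed_model_design(sd$prep$design, sd$ds$pedigree)
  for (j in 1:3) {
    fit <- reml_fit(dsn, sd$prep$spectra$values[, j])
    expect_true(all(diff(fit$loglik_trace) > -1e-7))
    expect_true(fit$converged)
    expect_true(all(fit$sigma2 >= 0))
    expect_equal(sum(fit$proportions), 1, tolerance = 1e-10)
    expect_gte(fit$h2, 0)
    expect_lte(fit$h2, 1)
  }
})

test_that("fits are scale-equivariant in the phenotype", {
  sd <- small_scan_data(n_wl = 1, seed = 56)
  dsn <- mixed_model_design(sd$prep$design, sd$ds$pedigree)
  y <- sd$prep$spectra$values[, 1]
  k <- 3.7
  f1 <- reml_fit(dsn, y)
  f2 <- reml_fit(dsn, k * y)
  expect_equal(f2$sigma2, k^2 * f1$sigma2, tolerance = 1e-6)
  expect_equal(f2$proportions, f1$proportions, tolerance = 1e-8)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-8)
})

test_that("animal-model REML matches the balanced half-sib ANOVA estimator", {
  # 20 sires x 20 progeny, dams unknown, no herd/batch structure:
  # sigma2_additive should equal 4x the ANOVA sire component when interior
  ns <- 20L; k <- 20L
  sires <- sprintf("s%02d", 1:ns)
  prog <- sprintf("p%03d", 1:(ns * k))
  ped <- pedigree(data.frame(animal = c(sires, prog),
                             sire = c(rep(NA, ns), rep(sires, each = k)),
                             dam = NA, stringsAsFactors = FALSE))
  s2a <- 0.35; s2e <- 0.65
  u <- simulate_breeding_values(ped, s2a, seed = 57)
  set.seed(58)
  y <- drop(u[prog, 1]) + rnorm(ns * k, sd = sqrt(s2e))
  dsn <- mixed_model_design(data.frame(animal = prog), ped)
  fit <- reml_fit(dsn, y)
  expect_true(fit$converged)

  sire_f <- factor(rep(sires, each = k))
  ms <- anova(aov(y ~ sire_f))
  s2_sire <- (ms$`Mean Sq`[1] - ms$`Mean Sq`[2]) / k
  expect_gt(s2_sire, 0)  # interior case
  expect_equal(unname(fit$sigma2["additive"]), 4 * s2_sire,
               tolerance = 0.02)
})

test_that("i.i.d.-effects fits agree with lme4 to high precision", {
  # with the additive term dropped the model is a plain one/two-way
  # variance-components model, which lme4 fits by REML independently
  set.seed(71)
  n <- 240L
  herd <- factor(rep(sprintf("h%02d", 1:12), each = 20))
  batch <- factor(rep(sprintf("b%02d", 1:15), length.out = n))
  y <- 0.7 * rnorm(12)[herd] + 0.5 * rnorm(15)[batch] + rnorm(n)
  d <- data.frame(animal = sprintf("a%03d", 1:n), herd = herd,
                  batch = batch, stringsAsFactors = FALSE)
  dsn <- mixed_model_design(d, additive = FALSE)
  fit <- reml_fit(dsn, y)
  expect_true(fit$converged)
  expect_true(is.na(fit$h2))

  lm4 <- lme4::lmer(y ~ 1 + (1 | herd) + (1 | batch), REML = TRUE,
                    control = lme4::lmerControl(
                      optimizer = "bobyqa",
                      optCtrl = list(rhobeg = 1e-2, rhoend = 1e-12)))
  vc <- as.data.frame(lme4::VarCorr(lm4))
  ref <- stats::setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$sigma2["herd"]), unname(ref["herd"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["batch"]), unname(ref["batch"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), unname(ref["Residual"]),
               tolerance = 1e-6)
})

test_that("per-wavelength scans are complete, warm-start invariant and targeted", {
  sd <- small_scan_data(n_wl = 6, seed = 59)
  scan_w <- wavelength_scan(sd$prep$spectra, sd$prep$design, sd$ds$pedigree,
                            warm_start = TRUE)
  scan_c <- wavelength_scan(sd$prep$spectra, sd$prep$design, sd$ds$pedigree,
                            warm_start = FALSE)
  expect_equal(nrow(scan_w), 6L)
  expect_equal(scan_w$wavelength_nm, sd$prep$spectra$grid$wavelengths)
  expect_true(all(scan_w$converged))
  for (col in c("sigma2_herd", "sigma2_batch", "sigma2_additive",
                "sigma2_residual", "h2")) {
    expect_lt(max(abs(scan_w[[col]] - scan_c[[col]])), 1e-6)
  }

  # middle wavelength simulated as pure noise -> h2 near zero there only
  grid3 <- wavelength_grid(500, 510, 5)
  tr <- truth_profile(grid3, p_batch = c(0.10, 0, 0.10),
                      p_herd = c(0.08, 0, 0.08),
                      p_genetic = c(0.35, 0, 0.35),
                      p_residual = c(0.47, 1, 0.47))
  cfg <- sim_config(n_animals = 600, n_sires = 30, n_dams = 570,
                    n_herds = 10, n_batches = 12, grid = grid3,
                    instrument = "uvvisnir", truth = tr, seed = 60)
  ds <- simulate_dataset(cfg)
  prep <- preprocess_spectra(ds$spectra, ds$design)
  scan <- wavelength_scan(prep$spectra, prep$design, ds$pedigree)
  expect_lt(scan$h2[2], 0.12)
  expect_gt(scan$h2[1], 0.15)
  expect_gt(scan$h2[3], 0.15)
})

test_that("summaries split proportions and intra-herd/batch heritability", {
  fit <- list(sigma2 = c(herd = 1, batch = 1, additive = 1, residual = 1))
  s <- summarize_fit(fit)
  expect_equal(unname(s$proportions), rep(0.25, 4))
  expect_equal(s$h2, 0.5)

  # component percentages 18 genetic / 47 residual give h2 = 18/65
  fit2 <- list(sigma2 = c(herd = 5, batch = 30, additive = 18,
                          residual = 47))
  expect_equal(summarize_fit(fit2)$h2, 18 / 65, tolerance = 1e-12)

  fit3 <- list(sigma2 = c(herd = 0.2, batch = 0.3, additive = 0,
                          residual = 0.5))
  expect_equal(summarize_fit(fit3)$h2, 0)
  expect_error(summarize_fit(list(sigma2 = c(additive = 0, residual = 0))),
               "zero")
})
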