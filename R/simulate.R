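#' Simulation configuration
#'
#' Describes a synthetic population of pedigreed, spectra-phenotyped animals:
#' unrelated artificial-insemination sires and dams, one phenotyped progeny
#' generation assigned to rearing herds and slaughter batches, and replicate
#' reflectance spectra per animal. Default counts mirror a commercial beef
#' progeny-test structure (200 sires, 1150 dams, 1185 phenotyped young
#' bulls, 93 herds, 115 slaughter batches) and the default measurement
#' layout is 5 probe positions x 3 replicates per animal.
#'
#' @param n_animals Number of phenotyped progeny.
#' @param n_sires,n_dams Numbers of founder sires and dams.
#' @param n_herds,n_batches Numbers of rearing herds and slaughter batches.
#' @param grid [wavelength_grid()] of the simulated instrument.
#' @param instrument Instrument label used for the default truth profile.
#' @param truth A [truth_profile()]; defaults to
#'   [band_truth_profile()]`(grid, instrument)`.
#' @param n_positions,n_replicates Probe positions per animal and replicate
#'   scans per position.
#' @param position_sd,replicate_sd Within-animal noise SDs for position and
#'   replicate effects, in units of the per-wavelength phenotypic SD.
#' @param strict_min_cell Guarantee every herd and batch at least 3 animals
#'   (errors when `n_animals` is too small to honour it).
#' @param seed Master seed; named substreams (pedigree, effects, noise,
#'   outliers) are derived from it so stages are independently reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 1185, n_sires = 200, n_dams = 1150,
                       n_herds = 93, n_batches = 115,
                       grid = wavelength_grid(905, 1649, 6),
                       instrument = c("micronir", "uvvisnir"),
                       truth = NULL,
                       n_positions = 5, n_replicates = 3,
                       position_sd = 0.1, replicate_sd = 0.05,
                       strict_min_cell = TRUE, seed = 1L) {
  instrument <- match.arg(instrument)
  counts <- c(n_animals, n_sires, n_dams, n_herds, n_batches,
              n_positions, n_replicates)
  if (any(counts < 1)) stop("all counts must be positive")
  if (position_sd < 0 || replicate_sd < 0) stop("noise SDs must be >= 0")
  if (is.null(truth)) truth <- band_truth_profile(grid, instrument)
  if (length(truth$total_sd) != length(grid$wavelengths))
    stop("truth profile does not match the wavelength grid")
  if (strict_min_cell && n_animals < 3 * max(n_herds, n_batches))
    stop("n_animals too small to give every herd and batch 3 animals")
  structure(list(n_animals = n_animals, n_sires = n_sires, n_dams = n_dams,
                 n_herds = n_herds, n_batches = n_batches, grid = grid,
                 instrument = instrument, truth = truth,
                 n_positions = n_positions, n_replicates = n_replicates,
                 position_sd = position_sd, replicate_sd = replicate_sd,
                 strict_min_cell = strict_min_cell, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic substream seed from master seed and stream name (< 2^31)
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Per-wavelength truth profile for the simulator
#'
#' Specifies, for every wavelength of a grid, the fractions of phenotypic
#' variance attributed to slaughter batch, rearing herd, additive genetics
#' and residual, together with the phenotypic SD and mean absorbance level.
#'
#' @param grid A [wavelength_grid()].
#' @param p_batch,p_herd,p_genetic,p_residual Variance fractions, recycled
#'   to the grid length; must sum to 1 at every wavelength (tolerance
#'   1e-12).
#' @param total_sd Phenotypic SD per wavelength (absorbance units).
#' @param mean_abs Mean absorbance per wavelength.
#' @return Object of class `truth_profile` with matrix `fractions`
#'   (wavelength x 4, columns batch/herd/genetic/residual), `total_sd`,
#'   `mean_abs`.
#' @export
truth_profile <- function(grid, p_batch, p_herd, p_genetic, p_residual,
                          total_sd = 0.1, mean_abs = 1) {
  p <- length(grid$wavelengths)
  fr <- cbind(batch = rep_len(p_batch, p), herd = rep_len(p_herd, p),
              genetic = rep_len(p_genetic, p),
              residual = rep_len(p_residual, p))
  if (any(fr < 0)) stop("variance fractions must be non-negative")
  if (any(abs(rowSums(fr) - 1) > 1e-12))
    stop("variance fractions must sum to 1 at every wavelength")
  structure(list(grid = grid, fractions = fr,
                 total_sd = rep_len(total_sd, p),
                 mean_abs = rep_len(mean_abs, p)),
            class = "truth_profile")
}

#' Truth profile built from the reference band architecture
#'
#' Expands [reference_band_profile()] to a per-wavelength truth profile:
#' each wavelength takes the variance fractions of its band, and the mean
#' absorbance curve interpolates the band means at the band midpoints
#' (yielding a smooth simulated mean spectrum).
#'
#' @param grid A [wavelength_grid()].
#' @param instrument `"uvvisnir"` or `"micronir"`.
#' @param total_sd Phenotypic SD per wavelength (default 0.1 absorbance
#'   units, a realistic between-animal scale for meat spectra).
#' @return A [truth_profile()].
#' @export
band_truth_profile <- function(grid, instrument = c("uvvisnir", "micronir"),
                               total_sd = 0.1) {
  instrument <- match.arg(instrument)
  bands <- band_table(instrument)
  prof <- reference_band_profile(instrument)
  map <- assign_bands(grid, bands)
  i <- match(map, prof$band)
  mid <- (bands$lo_nm + bands$hi_nm) / 2
  mean_curve <- stats::approx(mid, prof$mean_abs[match(bands$band, prof$band)],
                              xout = grid$wavelengths, rule = 2)$y
  truth_profile(grid,
                p_batch = prof$pct_batch[i] / 100,
                p_herd = prof$pct_herd[i] / 100,
                p_genetic = prof$pct_genetic[i] / 100,
                p_residual = prof$pct_residual[i] / 100,
                total_sd = total_sd, mean_abs = mean_curve)
}

#' Simulate a pedigree and herd/batch design
#'
#' Builds a two-generation pedigree (unrelated founder sires and dams,
#' progeny by random mating, hence paternal half-sib families) and assigns
#' each progeny one rearing herd and one slaughter batch. Herds and batches
#' are assigned independently, so batches cut across herds as in a
#' commercial abattoir. With `strict_min_cell` every herd and batch is first
#' given 3 animals before the remainder are allocated at random, so the
#' minimum-cell filter is a no-op on clean data.
#'
#' @param cfg A [sim_config()].
#' @return List with `pedigree` (a [pedigree()]) and `design` (data.frame
#'   `animal,herd,batch` over the phenotyped progeny).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$strict_min_cell &&
      cfg$n_animals < 3 * max(cfg$n_herds, cfg$n_batches))
    stop("n_animals too small to give every herd and batch 3 animals")
  set.seed(substream_seed(cfg$seed, "pedigree"))
  sires <- sprintf("S%04d", seq_len(cfg$n_sires))
  dams <- sprintf("D%04d", seq_len(cfg$n_dams))
  prog <- sprintf("A%04d", seq_len(cfg$n_animals))
  rec <- data.frame(
    animal = c(sires, dams, prog),
    sire = c(rep(NA, cfg$n_sires + cfg$n_dams),
             sample(sires, cfg$n_animals, replace = TRUE)),
    dam = c(rep(NA, cfg$n_sires + cfg$n_dams),
            sample(dams, cfg$n_animals, replace = TRUE)),
    stringsAsFactors = FALSE)
  ped <- pedigree(rec)

  assign_cells <- function(n, labels, min_n) {
    lab <- if (min_n > 0) rep(labels, length.out = min_n * length(labels))
           else character(0)
    lab <- c(lab, sample(labels, n - length(lab), replace = TRUE))
    sample(lab)  # shuffle so guaranteed slots are not positional
  }
  min_n <- if (cfg$strict_min_cell) 3L else 0L
  design <- data.frame(
    animal = prog,
    herd = assign_cells(cfg$n_animals, sprintf("H%03d", seq_len(cfg$n_herds)),
                        min_n),
    batch = assign_cells(cfg$n_animals,
                         sprintf("B%03d", seq_len(cfg$n_batches)), min_n),
    stringsAsFactors = FALSE)
  list(pedigree = ped, design = design)
}

#' Simulate breeding values by Mendelian-sampling recursion
#'
#' Draws additive genetic values down an ordered pedigree:
#' `u_i = 0.5 (u_s + u_d) + m_i` with Mendelian-sampling variance
#' `sigma2_a * (0.5 - 0.25 (F_s + F_d))`; a missing parent contributes a
#' founder-like term instead, so every animal has unconditional variance
#' `sigma2_a (1 + F_i)`. The resulting vectors have covariance
#' `A * sigma2_a` across animals; columns (traits/wavelengths) are
#' independent.
#'
#' @param ped A [pedigree()].
#' @param sigma2_a Additive genetic variance (>= 0).
#' @param seed Integer seed.
#' @param n_traits Number of independent columns to draw.
#' @param F Optional precomputed inbreeding coefficients in pedigree order;
#'   computed via [relationship_matrix()] when omitted.
#' @return Matrix (pedigree order x n_traits), rownames = animal ids.
#' @export
simulate_breeding_values <- function(ped, sigma2_a, seed, n_traits = 1L,
                                     F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (sigma2_a < 0) stop("sigma2_a must be >= 0")
  n <- nrow(ped)
  u <- matrix(0, n, n_traits, dimnames = list(ped$animal, NULL))
  if (sigma2_a == 0) return(u)
  if (is.null(F)) F <- relationship_matrix(ped)$F
  idx <- attr(ped, "index")
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  set.seed(seed)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    pa <- 0; vm <- 1
    if (!is.na(s)) { pa <- pa + 0.5 * u[s, ]; vm <- vm - 0.25 * (1 + F[s]) }
    if (!is.na(d)) { pa <- pa + 0.5 * u[d, ]; vm <- vm - 0.25 * (1 + F[d]) }
    u[i, ] <- pa + stats::rnorm(n_traits, sd = sqrt(sigma2_a * vm))
  }
  u
}

#' Simulate replicate absorbance spectra
#'
#' For each wavelength, the animal-level phenotype is
#' `mean + sd * (sqrt(p_batch) Q_batch + sqrt(p_herd) C_herd +
#' sqrt(p_genetic) U_animal + sqrt(p_residual) E_animal)` with standardized
#' effect realizations (herd and batch i.i.d. per level, breeding values
#' with covariance `A` across animals). Effect realizations are drawn
#' independently per wavelength; the smoothness of simulated spectra comes
#' from the smooth mean and SD profiles. The animal value is then expanded
#' into `n_positions x n_replicates` scans by adding position- and
#' replicate-level Gaussian noise.
#'
#' @param ped A [pedigree()] containing all design animals.
#' @param design data.frame `animal,herd,batch`.
#' @param cfg A [sim_config()] (its `truth`, layout and seed are used).
#' @return A `raw_spectra` object; attributes `true_u`, `true_c`, `true_q`,
#'   `true_e` hold the realized standardized effects (`true_u` over the full
#'   pedigree), and `animal_values` the animal-level phenotype matrix.
#' @export
simulate_spectra <- function(ped, design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- cfg$grid
  p <- length(grid$wavelengths)
  tr <- cfg$truth
  if (nrow(tr$fractions) != p) stop("truth profile does not match grid")
  animals <- design$animal
  n <- length(animals)
  herds <- sort(unique(design$herd))
  batches <- sort(unique(design$batch))

  u <- simulate_breeding_values(ped, 1, substream_seed(cfg$seed, "genetic"),
                                n_traits = p)
  set.seed(substream_seed(cfg$seed, "effects"))
  C <- matrix(stats::rnorm(length(herds) * p), length(herds), p,
              dimnames = list(herds, NULL))
  Q <- matrix(stats::rnorm(length(batches) * p), length(batches), p,
              dimnames = list(batches, NULL))
  E <- matrix(stats::rnorm(n * p), n, p, dimnames = list(animals, NULL))

  fb <- sqrt(tr$fractions[, "batch"]); fh <- sqrt(tr$fractions[, "herd"])
  fg <- sqrt(tr$fractions[, "genetic"])
  fe <- sqrt(tr$fractions[, "residual"])
  g <- Q[design$batch, , drop = FALSE] * rep(fb, each = n) +
       C[design$herd, , drop = FALSE] * rep(fh, each = n) +
       u[animals, , drop = FALSE] * rep(fg, each = n) +
       E * rep(fe, each = n)
  y <- rep(tr$mean_abs, each = n) + g * rep(tr$total_sd, each = n)

  set.seed(substream_seed(cfg$seed, "noise"))
  npos <- cfg$n_positions; nrep <- cfg$n_replicates
  arr <- array(NA_real_, dim = c(n, npos, nrep, p),
               dimnames = list(animals, NULL, NULL, NULL))
  for (ip in seq_len(npos)) {
    pos_eff <- matrix(stats::rnorm(n * p), n, p) *
      rep(cfg$position_sd * tr$total_sd, each = n)
    for (ir in seq_len(nrep)) {
      rep_eff <- matrix(stats::rnorm(n * p), n, p) *
        rep(cfg$replicate_sd * tr$total_sd, each = n)
      arr[, ip, ir, ] <- y + pos_eff + rep_eff
    }
  }
  out <- structure(list(grid = grid, values = arr), class = "raw_spectra")
  attr(out, "true_u") <- u
  attr(out, "true_c") <- C
  attr(out, "true_q") <- Q
  attr(out, "true_e") <- E
  attr(out, "animal_values") <- y
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: population, breeding values and spectra from one
#' configuration. Bitwise reproducible given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_dataset`: list with `pedigree`, `design`,
#'   `spectra` (a `raw_spectra`), `truth` and the realized effect matrices
#'   `true_u`, `true_c`, `true_q`, `true_e`.
#' @export
simulate_dataset <- function(cfg) {
  pop <- simulate_population(cfg)
  sp <- simulate_spectra(pop$pedigree, pop$design, cfg)
  structure(list(pedigree = pop$pedigree, design = pop$design, spectra = sp,
                 truth = cfg$truth, config = cfg,
                 true_u = attr(sp, "true_u"), true_c = attr(sp, "true_c"),
                 true_q = attr(sp, "true_q"), true_e = attr(sp, "true_e")),
            class = "sim_dataset")
}

#' Inject artificial outlier spectra
#'
#' Shifts `k` randomly chosen animals' spectra (all positions and
#' replicates) by `magnitude` phenotypic SDs along a random smooth spectral
#' direction, to exercise Mahalanobis editing.
#'
#' @param raw A `raw_spectra` object.
#' @param k Number of animals to perturb (`k <= n`).
#' @param magnitude Shift size in per-wavelength phenotypic SD units
#'   (>= 0).
#' @param seed Integer seed.
#' @param total_sd Per-wavelength phenotypic SD used to scale the shift;
#'   defaults to the empirical SD of the animal-average spectra.
#' @return The modified `raw_spectra`; attribute `injected` lists the
#'   perturbed animal ids.
#' @export
inject_outliers <- function(raw, k, magnitude, seed, total_sd = NULL) {
  stopifnot(inherits(raw, "raw_spectra"))
  if (magnitude < 0) stop("magnitude must be >= 0")
  n <- dim(raw$values)[1L]
  if (k > n) stop("k exceeds the number of animals")
  if (k == 0) {
    attr(raw, "injected") <- character(0)
    return(raw)
  }
  p <- dim(raw$values)[4L]
  if (is.null(total_sd)) {
    avg <- apply(raw$values, c(1L, 4L), mean)
    total_sd <- apply(avg, 2L, stats::sd)
  }
  set.seed(seed)
  ids <- sample(dimnames(raw$values)[[1L]], k)
  x <- seq(0, 1, length.out = p)
  for (id in ids) {
    # random smooth direction: low-order Fourier mixture, unit RMS
    co <- stats::rnorm(4L)
    d <- co[1L] + co[2L] * sin(pi * x) + co[3L] * cos(pi * x) +
      co[4L] * sin(2 * pi * x)
    d <- d / sqrt(mean(d^2))
    shift <- magnitude * total_sd * d
    raw$values[id, , , ] <- raw$values[id, , , ] +
      rep(shift, each = dim(raw$values)[2L] * dim(raw$values)[3L])
  }
  attr(raw, "injected") <- ids
  raw
}
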