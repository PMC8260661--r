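# Independent oracles and fixture builders shared across tests.
# These are written directly from first principles (recursive coancestry,
# the restricted-likelihood formula with naive matrix inversion) and must
# stay independent of the package's own code paths.

# 2 x coancestry oracle for the relationship matrix: phi(i,i) =
# 0.5 * (1 + phi(s, d)), phi(i, j) = 0.5 * (phi(s_i, j) + phi(d_i, j))
# taking the later-born animal's parents; unknown parents contribute 0.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- attr(ped, "index")
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      k <- max(i, j); l <- min(i, j)  # k is younger: never an ancestor of l
      0.5 * (phi(si[k], l) + phi(di[k], l))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# random multi-generation pedigree for property tests
random_pedigree <- function(n, seed, p_known = 0.7) {
  set.seed(seed)
  id <- sprintf("X%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    pool <- seq_len(i - 1L)
    if (stats::runif(1) < p_known) sire[i] <- id[sample(pool, 1L)]
    if (stats::runif(1) < p_known) {
      d <- id[sample(pool, 1L)]
      if (is.na(sire[i]) || d != sire[i]) dam[i] <- d
    }
  }
  pedigree(data.frame(animal = id, sire = sire, dam = dam,
                      stringsAsFactors = FALSE))
}

# restricted log-likelihood written straight from the formula, with naive
# inversion (no factorization tricks)
naive_reml_loglik <- function(y, X, Blist, theta) {
  n <- length(y)
  V <- diag(theta["residual"], n)
  for (nm in names(Blist)) V <- V + theta[nm] * Blist[[nm]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (log(det(V)) + log(det(XtViX)) + drop(t(y) %*% P %*% y))
}

# fixed small dataset with herd/batch/genetic/residual structure, sized so
# the REML optimum is interior in all four components (seed recorded here)
fixture30 <- function() {
  grid1 <- wavelength_grid(600, 600, 1)
  cfg <- sim_config(n_animals = 30, n_sires = 5, n_dams = 28, n_herds = 5,
                    n_batches = 6, grid = grid1, instrument = "uvvisnir",
                    truth = truth_profile(grid1, 0.2, 0.15, 0.25, 0.4,
                                          total_sd = 1, mean_abs = 0),
                    position_sd = 0, replicate_sd = 0, seed = 2032)
  ds <- simulate_dataset(cfg)
  y <- drop(attr(ds$spectra, "animal_values"))
  list(ds = ds, y = y)
}

# small standardized dataset for scan-level tests
small_scan_data <- function(n_wl = 6, seed = 11, n_animals = 150) {
  grid <- wavelength_grid(500, 500 + 5 * (n_wl - 1), 5)
  cfg <- sim_config(n_animals = n_animals, n_sires = 15,
                    n_dams = n_animals - 10, n_herds = 6, n_batches = 8,
                    grid = grid, instrument = "uvvisnir",
                    truth = truth_profile(grid, 0.1, 0.08, 0.25, 0.57),
                    seed = seed)
  ds <- simulate_dataset(cfg)
  prep <- preprocess_spectra(ds$spectra, ds$design)
  list(ds = ds, prep = prep)
}
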