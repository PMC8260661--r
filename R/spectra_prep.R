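#' Inclusive arithmetic wavelength grid
#'
#' @param lo_nm,hi_nm Wavelength bounds in nm (`hi_nm >= lo_nm`).
#' @param step_nm Spacing in nm (> 0).
#' @return Object of class `wavelength_grid`: list with `lo_nm`, `hi_nm`,
#'   `step_nm` and the `wavelengths` vector `lo, lo+step, ...` (both
#'   endpoints included when `hi - lo` is a multiple of `step`).
#' @examples
#' length(wavelength_grid(350, 1830, 1)$wavelengths)  # 1481
#' length(wavelength_grid(905, 1649, 6)$wavelengths)  # 125
#' @export
wavelength_grid <- function(lo_nm, hi_nm, step_nm) {
  if (step_nm <= 0) stop("step_nm must be positive")
  if (hi_nm < lo_nm) stop("hi_nm must be >= lo_nm")
  # guard against floating-point shortfall when (hi - lo)/step is integral
  w <- lo_nm + step_nm * seq.int(0L, floor((hi_nm - lo_nm) / step_nm + 1e-9))
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm, step_nm = step_nm,
                 wavelengths = w),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat("Wavelength grid:", x$lo_nm, "-", x$hi_nm, "nm, step", x$step_nm,
      "nm (", length(x$wavelengths), "points )\n")
  invisible(x)
}

#' Absorbance from reflectance
#'
#' `A = log10(1 / R)`, the standard NIRS absorbance transform (decadic
#' logarithm).
#'
#' @param R Reflectance fractions in `(0, 1]` (vector, matrix or array).
#' @return Absorbance, same shape as `R`.
#' @examples
#' absorbance_from_reflectance(c(1, 0.01))  # 0, 2
#' @export
absorbance_from_reflectance <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("reflectance must be finite and > 0")
  -log10(R)
}

#' Average replicate spectra per animal
#'
#' Collapses a raw spectra set (animal x position x replicate x wavelength)
#' to one spectrum per animal by the grand mean over the position x replicate
#' cells; with a balanced layout this equals the mean of position means.
#' Animals with missing cells are averaged over what is present and flagged
#' `"incomplete"`; animals with no data at all are excluded.
#'
#' @param raw A `raw_spectra` object (see [simulate_spectra()] or
#'   [read_spectra_csv()]).
#' @return Object of class `spectra_matrix`: list with `grid`, `values`
#'   (animal x wavelength matrix, dimnames set), `stage = "averaged"` and
#'   `excluded` (data.frame `animal,stage,reason,statistic`).
#' @export
average_replicates <- function(raw) {
  stopifnot(inherits(raw, "raw_spectra"))
  v <- raw$values  # n x pos x rep x wavelength
  n <- dim(v)[1L]
  p <- dim(v)[4L]
  M <- matrix(NA_real_, n, p, dimnames = list(dimnames(v)[[1L]], NULL))
  excl <- empty_exclusions()
  flags <- character(0)
  for (i in seq_len(n)) {
    sl <- v[i, , , , drop = FALSE]
    dim(sl) <- c(dim(v)[2L] * dim(v)[3L], p)
    present <- stats::complete.cases(sl)
    if (!any(present)) {
      excl <- rbind(excl, data.frame(
        animal = dimnames(v)[[1L]][i], stage = "average",
        reason = "no spectra", statistic = NA_real_,
        stringsAsFactors = FALSE))
      next
    }
    if (!all(present)) flags <- c(flags, dimnames(v)[[1L]][i])
    M[i, ] <- colMeans(sl[present, , drop = FALSE])
  }
  keep <- !is.na(M[, 1L])
  structure(list(grid = raw$grid, values = M[keep, , drop = FALSE],
                 stage = "averaged", excluded = excl,
                 incomplete = flags),
            class = "spectra_matrix")
}

empty_exclusions <- function() {
  data.frame(animal = character(0), stage = character(0),
             reason = character(0), statistic = numeric(0),
             stringsAsFactors = FALSE)
}

#' Mahalanobis (GH) outlier editing of animal spectra
#'
#' Computes principal components of the centered animal x wavelength matrix
#' retaining at least `var_retained` of the total variance (capped at
#' `n - 1` components), the Mahalanobis distance of each animal in that
#' score space, and the standardized distance `GH = D^2 / k` where `k` is
#' the number of retained components. Animals with `GH > threshold` are
#' moved to the exclusion list. A single pass is made by default; with
#' `iterate = TRUE` the edit is repeated on the survivors until no animal
#' exceeds the threshold.
#'
#' @param mat A `spectra_matrix` (at least 3 animals).
#' @param threshold GH cutoff (default 3, the common NIRS convention).
#' @param var_retained Fraction of spectral variance the score space must
#'   retain (default 0.999).
#' @param iterate Repeat until no exclusions (default `FALSE`).
#' @return The edited `spectra_matrix`, `stage = "edited"`, with exclusions
#'   appended (`statistic` = GH value).
#' @export
mahalanobis_edit <- function(mat, threshold = 3, var_retained = 0.999,
                             iterate = FALSE) {
  stopifnot(inherits(mat, "spectra_matrix"))
  excl <- mat$excluded
  M <- mat$values
  repeat {
    n <- nrow(M)
    if (n < 3L) stop("Mahalanobis editing needs at least 3 animals")
    gh <- gh_distance(M, var_retained)
    out <- which(gh > threshold)
    if (length(out)) {
      excl <- rbind(excl, data.frame(
        animal = rownames(M)[out], stage = "mahalanobis",
        reason = paste0("GH > ", threshold), statistic = unname(gh[out]),
        stringsAsFactors = FALSE))
      M <- M[-out, , drop = FALSE]
    }
    if (!iterate || !length(out)) break
  }
  structure(list(grid = mat$grid, values = M, stage = "edited",
                 excluded = excl, incomplete = mat$incomplete),
            class = "spectra_matrix")
}

# standardized Mahalanobis distance in PC score space
gh_distance <- function(M, var_retained) {
  n <- nrow(M)
  C <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(C, nu = 0)
  ev <- sv$d^2 / (n - 1)
  if (max(ev) <= 0)  # constant spectra: every distance is zero
    return(stats::setNames(rep(0, n), rownames(M)))
  pos <- which(ev > max(ev) * 1e-12)
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  k <- min(min(which(cum >= var_retained), length(pos)), n - 1L)
  scores <- C %*% sv$v[, seq_len(k), drop = FALSE]
  d2 <- rowSums(sweep(scores^2, 2L, ev[seq_len(k)], "/"))
  stats::setNames(d2 / k, rownames(M))
}

#' Center and standardize spectra per wavelength
#'
#' Replaces each wavelength column by its z-score across retained animals,
#' so downstream variance components are directly interpretable as
#' proportions of phenotypic variance.
#'
#' @param mat A `spectra_matrix` with at least 2 animals.
#' @return `spectra_matrix` with `stage = "standardized"`; attributes
#'   `center` and `scale` store the removed column means/SDs.
#' @export
center_standardize <- function(mat) {
  stopifnot(inherits(mat, "spectra_matrix"))
  M <- mat$values
  if (nrow(M) < 2L) stop("standardization needs at least 2 animals")
  mu <- colMeans(M)
  sdv <- apply(M, 2L, stats::sd)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero))
    stop("zero-variance wavelength at ",
         mat$grid$wavelengths[which(zero)[1L]], " nm")
  Z <- scale(M, center = mu, scale = sdv)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  out <- structure(list(grid = mat$grid, values = Z, stage = "standardized",
                        excluded = mat$excluded, incomplete = mat$incomplete),
                   class = "spectra_matrix")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' Minimum cell-size filter for herd and batch
#'
#' Drops animals belonging to herds or batches with fewer than `min_n`
#' observations, re-applying the rule until a fixpoint (a drop can shrink
#' other cells below the minimum).
#'
#' @param design data.frame with columns `animal`, `herd`, `batch`.
#' @param min_n Minimum observations per herd and per batch (default 3).
#' @return The filtered design; attribute `dropped` holds a data.frame
#'   `animal,stage,reason,statistic` of removed animals.
#' @export
min_cell_filter <- function(design, min_n = 3L) {
  stopifnot(all(c("animal", "herd", "batch") %in% names(design)))
  dropped <- empty_exclusions()
  repeat {
    ht <- table(design$herd)
    bt <- table(design$batch)
    bad_h <- names(ht)[ht < min_n]
    bad_b <- names(bt)[bt < min_n]
    sel <- design$herd %in% bad_h | design$batch %in% bad_b
    if (!any(sel)) break
    why <- ifelse(design$herd[sel] %in% bad_h,
                  paste0("herd cell < ", min_n),
                  paste0("batch cell < ", min_n))
    sizes <- ifelse(design$herd[sel] %in% bad_h,
                    as.numeric(ht[design$herd[sel]]),
                    as.numeric(bt[design$batch[sel]]))
    dropped <- rbind(dropped, data.frame(
      animal = design$animal[sel], stage = "min_cell", reason = why,
      statistic = sizes, stringsAsFactors = FALSE))
    design <- design[!sel, , drop = FALSE]
    if (!nrow(design)) stop("no animals survive min-cell filtering")
  }
  attr(design, "dropped") <- dropped
  design
}

#' Run the standard preprocessing chain
#'
#' Fixed order: replicate averaging, Mahalanobis editing, minimum-cell
#' filtering of the design (restricted to spectra survivors), then
#' per-wavelength centering and standardization over the animals that
#' survive all edits.
#'
#' @param raw A `raw_spectra` set.
#' @param design data.frame `animal,herd,batch` covering the raw animals.
#' @param gh_threshold GH cutoff for [mahalanobis_edit()].
#' @param min_n Minimum herd/batch cell size.
#' @return List with `spectra` (standardized `spectra_matrix`), `design`
#'   (filtered, aligned to the spectra rows), `absorbance_mean`
#'   (per-wavelength mean absorbance before standardization) and
#'   `exclusions` (all stages combined).
#' @export
preprocess_spectra <- function(raw, design, gh_threshold = 3, min_n = 3L) {
  avg <- average_replicates(raw)
  ed <- mahalanobis_edit(avg, threshold = gh_threshold)
  design2 <- design[design$animal %in% rownames(ed$values), , drop = FALSE]
  design3 <- min_cell_filter(design2, min_n = min_n)
  keep <- rownames(ed$values) %in% design3$animal
  kept <- structure(list(grid = ed$grid,
                         values = ed$values[keep, , drop = FALSE],
                         stage = "edited", excluded = ed$excluded,
                         incomplete = ed$incomplete),
                    class = "spectra_matrix")
  abs_mean <- colMeans(kept$values)
  std <- center_standardize(kept)
  design3 <- design3[match(rownames(std$values), design3$animal), , drop = FALSE]
  exclusions <- rbind(ed$excluded, attr(design3, "dropped"))
  list(spectra = std, design = design3, absorbance_mean = abs_mean,
       exclusions = exclusions)
}

#' Read raw spectra from CSV
#'
#' Accepts either the long dialect (`animal,position,replicate,wavelength,
#' absorbance`) or the wide dialect (`animal,position,replicate` followed by
#' one numeric column per wavelength named `w<nm>` or `<nm>`); the dialect
#' is detected from the header.
#'
#' @param path CSV path.
#' @param grid Optional [wavelength_grid()]; when omitted it is inferred
#'   from the wavelengths present (requires an even spacing).
#' @return A `raw_spectra` object.
#' @export
read_spectra_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  lower <- tolower(names(df))
  if (all(c("wavelength", "absorbance") %in% lower)) {
    names(df) <- lower
    long <- df
  } else {
    names(df)[1:3] <- lower[1:3]
    wcols <- setdiff(names(df), c("animal", "position", "replicate"))
    wl <- as.numeric(sub("^w", "", wcols))
    if (anyNA(wl)) stop("cannot parse wavelength columns in wide spectra CSV")
    long <- data.frame(
      animal = rep(df$animal, times = length(wl)),
      position = rep(df$position, times = length(wl)),
      replicate = rep(df$replicate, times = length(wl)),
      wavelength = rep(wl, each = nrow(df)),
      absorbance = as.vector(as.matrix(df[wcols])),
      stringsAsFactors = FALSE)
  }
  wl <- sort(unique(long$wavelength))
  if (is.null(grid)) {
    step <- if (length(wl) > 1L) wl[2L] - wl[1L] else 1
    grid <- wavelength_grid(min(wl), max(wl), step)
  }
  if (!isTRUE(all.equal(wl, grid$wavelengths)))
    stop("spectra wavelengths do not match the grid")
  animals <- unique(as.character(long$animal))
  npos <- max(long$position)
  nrep <- max(long$replicate)
  arr <- array(NA_real_, dim = c(length(animals), npos, nrep, length(wl)),
               dimnames = list(animals, NULL, NULL, NULL))
  arr[cbind(match(as.character(long$animal), animals), long$position,
            long$replicate, match(long$wavelength, wl))] <- long$absorbance
  structure(list(grid = grid, values = arr), class = "raw_spectra")
}

#' Write raw spectra to CSV (long dialect)
#' @param raw A `raw_spectra` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(raw, path) {
  v <- raw$values
  dn <- dimnames(v)[[1L]]
  idx <- expand.grid(animal = seq_len(dim(v)[1L]),
                     position = seq_len(dim(v)[2L]),
                     replicate = seq_len(dim(v)[3L]),
                     wavelength = seq_len(dim(v)[4L]))
  out <- data.frame(animal = dn[idx$animal], position = idx$position,
                    replicate = idx$replicate,
                    wavelength = raw$grid$wavelengths[idx$wavelength],
                    absorbance = as.vector(v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
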