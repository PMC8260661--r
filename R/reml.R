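#' Build the mixed-model design for the animal model
#'
#' Prepares everything the REML engine needs for the univariate animal model
#' `y = Xb + W1 c + W2 q + Z u + e` with a single intercept in `X`, random
#' herd (`c ~ N(0, I sigma2_c)`) and slaughter-batch
#' (`q ~ N(0, I sigma2_q)`) effects, additive genetic effects
#' (`u ~ N(0, A sigma2_a)`) and residual (`e ~ N(0, I sigma2_e)`). Because
#' every animal carries one record, the model is held in observation space:
#' the covariance contributors `W1 W1'`, `W2 W2'` and `Z A Z'` are stored as
#' dense n x n matrices.
#'
#' @param design data.frame with column `animal` and optionally `herd`
#'   and/or `batch` (a random term is included for each column present).
#' @param ped A [pedigree()] containing every design animal (ancestors
#'   included); may be `NULL` when `additive = FALSE`.
#' @param A Optional precomputed relationship matrix over `ped` (from
#'   [relationship_matrix()]); computed when omitted.
#' @param additive Include the pedigree-based additive term (default
#'   `TRUE`); with `FALSE` the model reduces to plain i.i.d. variance
#'   components (useful for benchmarking against standard mixed-model
#'   software).
#' @return Object of class `mm_design`: list with `n`, `animals`, `X`,
#'   incidence factors, the covariance structures `B` (named list, always
#'   ending with `additive`), and `q_levels` (effect dimensions used by the
#'   EM fallback).
#' @export
mixed_model_design <- function(design, ped = NULL, A = NULL,
                               additive = TRUE) {
  if (!"animal" %in% names(design)) stop("design needs an 'animal' column")
  animals <- as.character(design$animal)
  if (anyDuplicated(animals)) stop("duplicate animal in design")
  n <- length(animals)
  if (additive) {
    stopifnot(inherits(ped, "pedigree"))
    miss <- setdiff(animals, ped$animal)
    if (length(miss))
      stop("design animal(s) missing from pedigree: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    if (is.null(A)) A <- relationship_matrix(ped)$A
  }
  B <- list()
  q_levels <- c()
  factors <- list()
  for (term in c("herd", "batch")) {
    if (term %in% names(design)) {
      if (anyNA(design[[term]]))
        stop("animal lacking a ", term, " label")
      f <- factor(design[[term]])
      factors[[term]] <- f
      B[[term]] <- 1 * outer(f, f, "==")
      q_levels[term] <- nlevels(f)
    }
  }
  if (additive) {
    B$additive <- A[animals, animals, drop = FALSE]
    q_levels["additive"] <- n
  }
  q_levels["residual"] <- n - 1
  structure(list(n = n, animals = animals, X = matrix(1, n, 1),
                 factors = factors, B = B, q_levels = q_levels),
            class = "mm_design")
}

# V and derived REML quantities for one parameter vector
reml_core <- function(dsn, y, theta) {
  n <- dsn$n
  V <- matrix(0, n, n)
  for (nm in names(dsn$B)) V <- V + theta[nm] * dsn$B[[nm]]
  diag(V) <- diag(V) + theta["residual"]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  Vi <- chol2inv(cV)
  ViX <- Vi %*% dsn$X
  XtViX <- crossprod(dsn$X, ViX)
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1L] +
                  sum(y * Py))
  list(P = P, Py = Py, loglik = as.numeric(ll))
}

#' Restricted log-likelihood of the animal model
#'
#' Evaluates `-0.5 [log|V| + log|X' V^-1 X| + y' P y]` (without the
#' `-0.5 (n - p) log(2 pi)` constant) for
#' `V = sigma2_herd W1 W1' + sigma2_batch W2 W2' + sigma2_additive Z A Z' +
#' sigma2_residual I`, via Cholesky factorization.
#'
#' @param dsn A [mixed_model_design()].
#' @param y Phenotype vector (length `dsn$n`).
#' @param theta Named non-negative variance components; names must cover
#'   `names(dsn$B)` plus `"residual"`.
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(dsn, y, theta) {
  stopifnot(inherits(dsn, "mm_design"), length(y) == dsn$n)
  need <- c(names(dsn$B), "residual")
  if (!all(need %in% names(theta)))
    stop("theta must name components: ", paste(need, collapse = ", "))
  if (any(theta[need] < 0)) stop("variance components must be >= 0")
  core <- reml_core(dsn, y, theta[need])
  if (is.null(core)) stop("singular covariance matrix V")
  core$loglik
}

# score and average-information matrix at the current point
reml_derivs <- function(dsn, y, core) {
  comp <- c(names(dsn$B), "residual")
  k <- length(comp)
  n <- dsn$n
  Tm <- matrix(0, n, k, dimnames = list(NULL, comp))
  trPB <- yPBPy <- stats::setNames(numeric(k), comp)
  for (j in seq_along(names(dsn$B))) {
    nm <- names(dsn$B)[j]
    Tm[, nm] <- dsn$B[[nm]] %*% core$Py
    trPB[nm] <- sum(core$P * dsn$B[[nm]])
    yPBPy[nm] <- sum(core$Py * Tm[, nm])
  }
  Tm[, "residual"] <- core$Py
  trPB["residual"] <- sum(diag(core$P))
  yPBPy["residual"] <- sum(core$Py^2)
  grad <- -0.5 * (trPB - yPBPy)
  AI <- 0.5 * crossprod(Tm, core$P %*% Tm)
  list(grad = grad, AI = AI, trPB = trPB, yPBPy = yPBPy)
}

#' Fit the animal model by average-information REML
#'
#' Maximizes the restricted likelihood over the non-negative orthant by
#' average-information (AI) updates with step halving and an EM-REML
#' fallback whenever an AI step fails to increase the likelihood, so
#' accepted iterations are monotone in the restricted log-likelihood.
#' Components driven below `1e-8 * var(y)` are pinned at that bound and
#' flagged; a pinned component is released if its gradient turns positive.
#' Standard errors come from the inverse AI matrix over free components,
#' and the SE of the intra-herd/batch heritability
#' `h2 = sigma2_additive / (sigma2_additive + sigma2_residual)` by the
#' delta method.
#'
#' @param dsn A [mixed_model_design()].
#' @param y Phenotype vector.
#' @param init Optional named starting values (e.g. a warm start from a
#'   neighbouring wavelength); defaults to an equal split of `var(y)`
#'   favouring the residual.
#' @param max_iter Maximum iterations (default 200).
#' @param tol_par Relative parameter-change tolerance (default 1e-8).
#' @param tol_grad Scaled gradient tolerance (default 1e-6).
#' @return Object of class `reml_fit`: list with `sigma2` (named vector:
#'   herd/batch if present, additive, residual), `proportions`, `h2`, `se`,
#'   `se_h2`, `loglik`, `loglik_trace`, `converged`, `n_iter`, `boundary`
#'   (named logical).
#' @export
reml_fit <- function(dsn, y, init = NULL, max_iter = 200L,
                     tol_par = 1e-8, tol_grad = 1e-6) {
  stopifnot(inherits(dsn, "mm_design"), length(y) == dsn$n)
  comp <- c(names(dsn$B), "residual")
  k <- length(comp)
  if (dsn$n <= sum(dsn$q_levels[setdiff(comp, c("additive", "residual"))]) + 2)
    stop("too few observations for the number of herd/batch levels")
  vy <- stats::var(y)
  if (vy <= 0) stop("phenotype has zero variance")
  lb <- 1e-8 * vy
  theta <- stats::setNames(rep(0.15 * vy, k), comp)
  theta["residual"] <- vy * (1 - 0.15 * (k - 1))
  if (!is.null(init)) {
    init <- pmax(init[comp], lb)
    if (!anyNA(init)) theta <- stats::setNames(init, comp)
  }
  pinned <- stats::setNames(rep(FALSE, k), comp)

  core <- reml_core(dsn, y, theta)
  if (is.null(core)) stop("initial covariance matrix is singular")
  trace <- core$loglik
  converged <- FALSE
  iter <- 0L
  gscale <- dsn$n / vy  # typical gradient magnitude scale

  while (iter < max_iter) {
    iter <- iter + 1L
    d <- reml_derivs(dsn, y, core)
    pinned[pinned & d$grad > 0] <- FALSE       # release if ascent possible
    free <- !pinned
    gnorm <- max(abs(d$grad[free])) / gscale

    step <- rep(0, k)
    ok_dir <- FALSE
    AIf <- d$AI[free, free, drop = FALSE]
    sol <- tryCatch(solve(AIf, d$grad[free]), error = function(e) NULL)
    if (!is.null(sol) && all(is.finite(sol))) {
      step[free] <- sol
      ok_dir <- TRUE
    }

    new_core <- NULL
    new_theta <- theta
    if (ok_dir) {
      fac <- 1
      for (h in 1:12) {
        cand <- theta + fac * step
        cand <- pmax(cand, lb)
        cand[pinned] <- theta[pinned]
        cc <- reml_core(dsn, y, cand)
        if (!is.null(cc) && cc$loglik >= core$loglik - 1e-10) {
          new_core <- cc; new_theta <- cand
          break
        }
        fac <- fac / 2
      }
    }
    if (is.null(new_core)) {
      # EM-REML step: guaranteed-ascent fallback
      cand <- theta + theta^2 / dsn$q_levels[comp] * (d$yPBPy - d$trPB)
      cand <- pmax(cand, lb)
      cand[pinned] <- theta[pinned]
      cc <- reml_core(dsn, y, cand)
      if (is.null(cc) || cc$loglik < core$loglik - 1e-8) {
        break  # cannot make progress; report unconverged
      }
      new_core <- cc; new_theta <- cand
    }

    rel <- max(abs(new_theta - theta) / pmax(theta, lb))
    pinned <- new_theta <= lb * (1 + 1e-12)
    theta <- new_theta
    core <- new_core
    trace <- c(trace, core$loglik)
    if (rel < tol_par && gnorm < tol_grad) {
      converged <- TRUE
      break
    }
  }

  d <- reml_derivs(dsn, y, core)
  free <- !pinned
  se <- stats::setNames(rep(NA_real_, k), comp)
  Cfree <- tryCatch(solve(d$AI[free, free, drop = FALSE]),
                    error = function(e) NULL)
  if (!is.null(Cfree)) {
    v <- diag(Cfree)
    v[v < 0] <- NA_real_
    se[free] <- sqrt(v)
  }
  h2 <- if ("additive" %in% comp) {
    unname(theta["additive"] / (theta["additive"] + theta["residual"]))
  } else NA_real_
  se_h2 <- NA_real_
  if (!is.null(Cfree) && all(c("additive", "residual") %in% comp[free])) {
    ia <- match("additive", comp[free])
    ie <- match("residual", comp[free])
    s <- theta["additive"] + theta["residual"]
    g <- c(theta["residual"], -theta["additive"]) / s^2
    vh <- drop(t(g) %*% Cfree[c(ia, ie), c(ia, ie)] %*% g)
    if (is.finite(vh) && vh >= 0) se_h2 <- sqrt(vh)
  }
  structure(list(sigma2 = theta, proportions = theta / sum(theta), h2 = h2,
                 se = se, se_h2 = se_h2, loglik = core$loglik,
                 loglik_trace = trace, converged = converged, n_iter = iter,
                 boundary = pinned),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations )\n")
  out <- data.frame(sigma2 = x$sigma2, proportion = x$proportions,
                    se = x$se, boundary = x$boundary)
  print(round(out, 5))
  cat(sprintf("intra-herd/batch h2 = %.4f (SE %.4f), logL = %.4f\n",
              x$h2, x$se_h2, x$loglik))
  invisible(x)
}

#' Variance proportions and heritability from a fit
#'
#' Proportions are each component over the four-component phenotypic total;
#' the intra-herd/batch heritability divides the additive variance by
#' additive + residual only (herd and batch variance removed from the
#' denominator).
#'
#' @param fit A [reml_fit()] result (or any list with a named `sigma2`).
#' @return List with `proportions` (named, sums to 1) and `h2`.
#' @export
summarize_fit <- function(fit) {
  s <- fit$sigma2
  if (sum(s) <= 0) stop("all variance components are zero")
  list(proportions = s / sum(s),
       h2 = unname(s["additive"] / (s["additive"] + s["residual"])))
}

#' Per-wavelength REML scan
#'
#' Fits the animal model independently at every wavelength of a
#' (standardized) spectra matrix, reusing the design structures across
#' wavelengths and warm-starting each fit from the previous wavelength's
#' estimates. Individual failures are recorded in the result row
#' (`converged = FALSE`), never raised.
#'
#' @param spectra A `spectra_matrix` (ideally `stage = "standardized"`).
#' @param design data.frame `animal,herd,batch` aligned with the spectra
#'   rows (same animals, any order).
#' @param ped A [pedigree()] covering the animals.
#' @param A Optional precomputed relationship matrix.
#' @param instrument Label copied into the output.
#' @param warm_start Warm-start each wavelength from the previous one
#'   (default `TRUE`).
#' @param verbose Print a progress line every 25 wavelengths.
#' @param ... Passed to [reml_fit()] (`max_iter`, tolerances).
#' @return data.frame with one row per wavelength: `instrument`,
#'   `wavelength_nm`, `sigma2_herd`, `sigma2_batch`, `sigma2_additive`,
#'   `sigma2_residual`, `p_herd`, `p_batch`, `p_genetic`, `p_residual`,
#'   `h2`, `se_h2`, `loglik`, `converged`, `n_iter`.
#' @export
wavelength_scan <- function(spectra, design, ped, A = NULL,
                            instrument = "uvvisnir", warm_start = TRUE,
                            verbose = FALSE, ...) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  design <- design[match(rownames(spectra$values), design$animal), ,
                   drop = FALSE]
  if (anyNA(design$animal)) stop("design does not cover all spectra animals")
  dsn <- mixed_model_design(design, ped, A = A)
  wl <- spectra$grid$wavelengths
  rows <- vector("list", length(wl))
  init <- NULL
  for (j in seq_along(wl)) {
    y <- spectra$values[, j]
    fit <- tryCatch(reml_fit(dsn, y, init = init, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rows[[j]] <- data.frame(
        instrument = instrument, wavelength_nm = wl[j],
        sigma2_herd = NA_real_, sigma2_batch = NA_real_,
        sigma2_additive = NA_real_, sigma2_residual = NA_real_,
        p_herd = NA_real_, p_batch = NA_real_, p_genetic = NA_real_,
        p_residual = NA_real_, h2 = NA_real_, se_h2 = NA_real_,
        loglik = NA_real_, converged = FALSE, n_iter = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      s <- fit$sigma2
      pr <- fit$proportions
      rows[[j]] <- data.frame(
        instrument = instrument, wavelength_nm = wl[j],
        sigma2_herd = unname(s["herd"] %na% NA_real_),
        sigma2_batch = unname(s["batch"] %na% NA_real_),
        sigma2_additive = unname(s["additive"]),
        sigma2_residual = unname(s["residual"]),
        p_herd = unname(pr["herd"] %na% 0),
        p_batch = unname(pr["batch"] %na% 0),
        p_genetic = unname(pr["additive"]),
        p_residual = unname(pr["residual"]),
        h2 = fit$h2, se_h2 = fit$se_h2, loglik = fit$loglik,
        converged = fit$converged, n_iter = fit$n_iter,
        stringsAsFactors = FALSE)
      if (warm_start && fit$converged) init <- fit$sigma2
    }
    if (verbose && (j %% 25L == 0L || j == length(wl)))
      message("scan: ", j, "/", length(wl), " wavelengths")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# x if present and non-NA, else default (for optional components)
`%na%` <- function(x, default) {
  if (length(x) == 0L || is.na(x)) default else x
}
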