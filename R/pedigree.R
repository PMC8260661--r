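#' Validate and topologically order a pedigree
#'
#' Builds a validated pedigree object from animal/sire/dam triples. Parents
#' must themselves appear as animals; unknown parents are encoded as `NA`,
#' `""` or `"0"`. Records are reordered so that every known parent precedes
#' its offspring (the order required by the tabular relationship-matrix
#' recursion and by Mendelian-sampling simulation).
#'
#' @param records data.frame with columns `animal`, `sire`, `dam` (character
#'   or coercible). Additional columns are ignored.
#' @return An object of class `pedigree`: a data.frame with columns
#'   `animal`, `sire`, `dam` (character, `NA` = unknown parent) in
#'   parent-before-offspring order, plus a logical `founder` column
#'   (both parents unknown). Attribute `index` maps id to row.
#' @examples
#' ped <- pedigree(data.frame(animal = c("O", "S", "D"),
#'                            sire   = c("S", NA,  NA),
#'                            dam    = c("D", NA,  NA)))
#' ped$animal  # founders first
#' @export
pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(records)))
    stop("pedigree records need columns 'animal', 'sire', 'dam'")
  id   <- normalize_id(records$animal)
  sire <- normalize_id(records$sire)
  dam  <- normalize_id(records$dam)
  if (anyNA(id)) stop("missing animal id in pedigree records")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate animal id in pedigree: ", dup)
  }
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("self-parent: animal ", id[self[1L]], " listed as its own parent")
  known <- stats::na.omit(c(sire, dam))
  miss <- setdiff(known, id)
  if (length(miss))
    stop("parent id(s) not present as animals: ",
         paste(utils::head(miss, 5L), collapse = ", "))

  ord <- topo_order(id, sire, dam)
  out <- data.frame(animal = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  out$founder <- is.na(out$sire) & is.na(out$dam)
  idx <- seq_len(nrow(out))
  names(idx) <- out$animal
  attr(out, "index") <- idx
  class(out) <- c("pedigree", "data.frame")
  out
}

# unknown-parent codes: NA, "", "0", "NA"
normalize_id <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "0", "NA")] <- NA_character_
  x
}

# Kahn topological sort over parent -> offspring edges; names an animal on
# the cycle when one exists.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n)
  names(pos) <- id
  si <- pos[sire]
  di <- pos[dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # keep input order among ties for reproducibility
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    stop("cycle in pedigree involving animal ", id[left[1L]])
  }
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals (", sum(x$founder), "founders )\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix `A` over a validated
#' pedigree by the tabular recursion
#' `A[i,j] = 0.5 * (A[j, sire(i)] + A[j, dam(i)])` for `j < i` and
#' `A[i,i] = 1 + 0.5 * A[sire(i), dam(i)]`, with unknown parents treated as
#' unrelated non-inbred founders. Inbreeding coefficients are
#' `F_i = A[i,i] - 1`.
#'
#' @param ped A [pedigree()] object.
#' @return List with `A` (dense symmetric matrix, dimnames = animal ids in
#'   pedigree order) and `F` (named numeric vector of inbreeding
#'   coefficients).
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- attr(ped, "index")
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  Fcoef <- diag(A) - 1
  names(Fcoef) <- ped$animal
  list(A = A, F = Fcoef)
}

#' Restrict a pedigree to phenotyped animals and their ancestors
#'
#' Keeps exactly the given animals plus the closure of their known ancestors;
#' relationships among retained animals are unchanged by the restriction.
#'
#' @param ped A [pedigree()] object.
#' @param keep_ids Character vector of (phenotyped) animal ids to retain.
#' @return A [pedigree()] over the ancestor closure of `keep_ids`.
#' @export
prune_pedigree <- function(ped, keep_ids) {
  stopifnot(inherits(ped, "pedigree"))
  keep_ids <- unique(normalize_id(keep_ids))
  miss <- setdiff(keep_ids, ped$animal)
  if (length(miss))
    stop("phenotyped id(s) absent from pedigree: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  idx <- attr(ped, "index")
  keep <- logical(nrow(ped))
  keep[idx[keep_ids]] <- TRUE
  # pedigree is parent-before-offspring, so one reverse sweep closes ancestry
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  pedigree(as.data.frame(ped)[keep, c("animal", "sire", "dam")])
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns `animal,sire,dam`; empty fields, `0` or `NA`
#' denote unknown parents.
#'
#' @param path Path to a CSV file.
#' @return A [pedigree()].
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  pedigree(df)
}

#' Write a pedigree to CSV
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)[, c("animal", "sire", "dam")]
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
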