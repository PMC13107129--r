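.as_ca <- function(x) {
  if (inherits(x, "ProteinStructure")) return(x$ca)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) stop("expected an n x 3 coordinate matrix")
  m
}

#' Optimal rigid-body superposition with a given 1:1 correspondence
#'
#' Least-squares Kabsch fit of the mobile points onto the target points
#' (reflections excluded). Degenerate inputs (fewer than 3 points, or all
#' points collinear) are an error.
#'
#' @param mobile_points,target_points Matrices (n x 3) or
#'   `ProteinStructure`s with equal residue counts.
#' @return Object of class `Superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `correspondence`, `rmsd`.
#' @export
kabsch_superpose <- function(mobile_points, target_points) {
  M <- .as_ca(mobile_points)
  T_ <- .as_ca(target_points)
  if (nrow(M) != nrow(T_)) stop("point counts differ")
  if (nrow(M) < 3L) stop("need at least 3 points")
  for (P in list(M, T_)) {
    s <- svd(scale(P, scale = FALSE))$d
    if (s[2] < 1e-8 * max(s[1], 1)) stop("degenerate (collinear) configuration")
  }
  f <- .kabsch_cpp(M, T_)
  structure(list(rotation = f$rotation, translation = as.numeric(f$translation),
                 correspondence = cbind(seq_len(nrow(M)), seq_len(nrow(M))),
                 rmsd = f$rmsd, tm_score = NA_real_,
                 norm_length = NA_integer_, d0 = NA_real_),
            class = "Superposition")
}

#' Apply a superposition to coordinates
#' @param sup A `Superposition`.
#' @param x Coordinate matrix (n x 3) or `ProteinStructure`.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, x) {
  M <- .as_ca(x)
  sweep(M %*% t(sup$rotation), 2L, -sup$translation)
}

#' TM-score of a correspondence between two structures
#'
#' TM = (1/L_norm) * sum over aligned pairs of 1 / (1 + (d_i/d0)^2),
#' evaluated in the superposition that maximizes the score (found by
#' iterative subset superposition), with d0 = 1.24 (L_norm - 15)^(1/3)
#' - 1.8 Angstroms, floored at 0.5 (the floor also covers L_norm < 16).
#'
#' @param mobile,target `ProteinStructure`s or coordinate matrices.
#' @param correspondence Two-column matrix of (mobile index, target index)
#'   pairs, 1-based, strictly increasing in both columns. Default: the
#'   identity correspondence (requires equal lengths).
#' @param norm Normalization length: "target" (the target chain length,
#'   default) or "shorter" (the shorter chain).
#' @return The TM-score (numeric scalar) with attributes `rmsd` (over the
#'   full correspondence in the best superposition) and `d0`.
#' @export
tm_score <- function(mobile, target, correspondence = NULL,
                     norm = c("target", "shorter")) {
  norm <- match.arg(norm)
  M <- .as_ca(mobile)
  T_ <- .as_ca(target)
  if (is.null(correspondence)) {
    if (nrow(M) != nrow(T_)) stop("identity correspondence needs equal lengths")
    correspondence <- cbind(seq_len(nrow(M)), seq_len(nrow(M)))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) == 0L) stop("empty correspondence")
  if (any(diff(correspondence[, 1L]) <= 0) ||
      any(diff(correspondence[, 2L]) <= 0))
    stop("correspondence must be strictly increasing in both columns")
  if (max(correspondence[, 1L]) > nrow(M) ||
      max(correspondence[, 2L]) > nrow(T_) || min(correspondence) < 1L)
    stop("correspondence index out of range")
  lnorm <- if (norm == "target") nrow(T_) else min(nrow(M), nrow(T_))
  storage.mode(correspondence) <- "integer"
  r <- .tm_optimize_cpp(M, T_, correspondence, lnorm)
  out <- r$tm
  attr(out, "rmsd") <- r$rmsd
  attr(out, "d0") <- r$d0
  out
}

#' Heuristic structural alignment (TM-align-style search)
#'
#' Seeds correspondences from gapless threading at all offsets and from
#' fragment pairs (length-`window` windows at stride `step`); each seed is
#' refined by alternating superposition with Needleman-Wunsch on the
#' distance-derived score matrix S(i,j) = 1/(1 + (d_ij/d0)^2) with a
#' linear gap penalty, until the correspondence is stable (or `max_iter`
#' rounds). The best final TM-score wins; ties go to the earliest seed,
#' making the search deterministic.
#'
#' @param a,b `ProteinStructure`s (a is mobile, b is target) or
#'   coordinate matrices; at least 3 residues each.
#' @param norm TM normalization: "target" (default) or "shorter".
#' @param gap NW gap penalty (default -0.6).
#' @param window,step Fragment-seed window length and stride (8 / 4).
#' @param max_iter Maximum refinement rounds per seed (default 30).
#' @return A `Superposition` with `correspondence`, `rmsd`, `tm_score`,
#'   `norm_length` and `d0` filled in.
#' @export
align_structures <- function(a, b, norm = c("target", "shorter"),
                             gap = -0.6, window = 8L, step = 4L,
                             max_iter = 30L) {
  norm <- match.arg(norm)
  M <- .as_ca(a)
  T_ <- .as_ca(b)
  if (nrow(M) < 3L || nrow(T_) < 3L) stop("structures too short to align")
  lnorm <- if (norm == "target") nrow(T_) else min(nrow(M), nrow(T_))
  r <- .align_structures_cpp(M, T_, lnorm, gap, as.integer(window),
                             as.integer(step), as.integer(max_iter))
  structure(list(rotation = r$rotation,
                 translation = as.numeric(r$translation),
                 correspondence = r$correspondence, rmsd = r$rmsd,
                 tm_score = r$tm, norm_length = lnorm, d0 = r$d0),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d aligned pairs, RMSD %.3f A",
              nrow(x$correspondence), x$rmsd))
  if (!is.na(x$tm_score))
    cat(sprintf(", TM-score %.4f (L_norm %d, d0 %.3f A)",
                x$tm_score, x$norm_length, x$d0))
  cat("\n")
  invisible(x)
}

#' Extract a domain from a structure by residue span
#'
#' @param structure A `ProteinStructure`.
#' @param start,end 1-based inclusive residue positions (positions in the
#'   chain, not author numbering).
#' @return A `ProteinStructure` with residues renumbered 1..n; sequence,
#'   pLDDT and backbone atoms carried over.
#' @export
extract_domain <- function(structure, start, end) {
  stopifnot(inherits(structure, "ProteinStructure"))
  L <- length(structure$resno)
  if (start < 1L || end > L || start > end)
    stop("domain span out of range: ", start, "..", end, " for length ", L)
  idx <- seq.int(start, end)
  protein_structure(
    id = structure$id,
    ca = structure$ca[idx, , drop = FALSE],
    aa = structure$aa[idx],
    resno = seq_along(idx),
    n_atoms = if (is.null(structure$n)) NULL else
      structure$n[idx, , drop = FALSE],
    c_atoms = if (is.null(structure$c)) NULL else
      structure$c[idx, , drop = FALSE],
    plddt = if (is.null(structure$plddt)) NULL else structure$plddt[idx]
  )
}

#' All-vs-all TM-score similarity matrix
#'
#' Entry (i, j) is the mean of TM(i -> j) and TM(j -> i), both normalized
#' by the target (second) structure; the mean removes the normalization
#' asymmetry, so the matrix is symmetric by construction. Diagonal is 1.
#'
#' @param domains List of `ProteinStructure`s (unique ids required).
#' @param families Optional named character vector mapping id to family
#'   tag; carried as annotation.
#' @param verbose Log each computed pair (default FALSE).
#' @return Object of class `SimilarityMatrix`: `values` (labelled
#'   symmetric matrix) and `family`.
#' @export
similarity_matrix <- function(domains, families = NULL, verbose = FALSE) {
  stopifnot(length(domains) >= 2L)
  ids <- vapply(domains, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("duplicate structure ids: ",
                               ids[duplicated(ids)][1L])
  n <- length(domains)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      tij <- align_structures(domains[[i]], domains[[j]], norm = "target")
      tji <- align_structures(domains[[j]], domains[[i]], norm = "target")
      m[i, j] <- m[j, i] <- (tij$tm_score + tji$tm_score) / 2
      if (verbose) {
        message(sprintf("%s vs %s: TM %.3f (rmsd %.2f / %.2f A)",
                        ids[i], ids[j], m[i, j], tij$rmsd, tji$rmsd))
      }
    }
  }
  fam <- if (is.null(families)) setNames(rep(NA_character_, n), ids) else
    families[ids]
  structure(list(values = m, family = fam), class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat("SimilarityMatrix:", nrow(x$values), "structures")
  if (!all(is.na(x$family)))
    cat(",", length(unique(stats::na.omit(x$family))), "families")
  cat("\n")
  invisible(x)
}
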