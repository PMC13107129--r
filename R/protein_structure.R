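#' Construct a ProteinStructure object
#'
#' The container all structure operations act on: an ordered backbone with
#' mandatory CA coordinates, optional N/C coordinates, the one-letter
#' sequence, and optional per-residue pLDDT confidence (0-100). Residue
#' indices are 1-based and strictly increasing.
#'
#' @param id Structure identifier.
#' @param ca Numeric matrix (n x 3) of CA coordinates in Angstroms.
#' @param aa Character vector of one-letter residue codes (length n).
#' @param resno Integer residue numbers (default `1:n`), strictly increasing.
#' @param n_atoms,c_atoms Optional (n x 3) matrices of backbone N / C
#'   coordinates; rows may be NA where the atom is absent.
#' @param plddt Optional numeric vector of per-residue pLDDT in \[0, 100\],
#'   or NULL when the model carries no confidence (e.g. experimental).
#' @return An object of class `ProteinStructure`.
#' @export
protein_structure <- function(id, ca, aa = NULL, resno = NULL,
                              n_atoms = NULL, c_atoms = NULL, plddt = NULL) {
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  dimnames(ca) <- NULL
  nres <- nrow(ca)
  if (ncol(ca) != 3L || nres < 1L) stop("ca must be an n x 3 matrix")
  if (any(!is.finite(ca))) stop("CA coordinates must be finite")
  if (is.null(aa)) aa <- rep("A", nres)
  if (is.null(resno)) resno <- seq_len(nres)
  resno <- as.integer(resno)
  if (length(aa) != nres || length(resno) != nres)
    stop("aa/resno length must match number of residues")
  if (any(diff(resno) <= 0L)) stop("residue indices must be strictly increasing")
  if (!is.null(plddt)) {
    plddt <- as.numeric(plddt)
    if (length(plddt) != nres) stop("plddt length must match residues")
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
      stop("plddt must lie in [0, 100]")
  }
  if (nres > 1L) {
    d <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-nres, , drop = FALSE])^2))
    if (any(!is.finite(d)) || any(d <= 0))
      stop("consecutive CA-CA distances must be finite and > 0")
  }
  chk3 <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    if (nrow(m) != nres || ncol(m) != 3L)
      stop(what, " must be an n x 3 matrix matching CA")
    m
  }
  structure(
    list(id = as.character(id), resno = resno, aa = as.character(aa),
         ca = ca, n = chk3(n_atoms, "n_atoms"), c = chk3(c_atoms, "c_atoms"),
         plddt = plddt),
    class = "ProteinStructure"
  )
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat("ProteinStructure", x$id, "-", length(x$resno), "residues")
  if (!is.null(x$plddt))
    cat(sprintf("; mean pLDDT %.1f", mean(x$plddt, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
length.ProteinStructure <- function(x) length(x$resno)

#' Sequence of a ProteinStructure as a single string
#' @param s A `ProteinStructure`.
#' @return One-letter sequence string.
#' @export
structure_sequence <- function(s) {
  stopifnot(inherits(s, "ProteinStructure"))
  paste(s$aa, collapse = "")
}
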