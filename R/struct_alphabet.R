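#' Encode a structure into a deterministic geometric structural alphabet
#'
#' Each interior residue i (3 <= i <= L-1) is described by two internal
#' coordinates of the CA trace: the pseudo bond angle theta at
#' (i-1, i, i+1) and the pseudo dihedral tau over (i-2, i-1, i, i+1).
#' Both are discretized -- theta into bins \[0,90), \[90,105), \[105,120),
#' \[120,180\] degrees and tau into quadrants \[-180,-90), \[-90,0),
#' \[0,90), \[90,180) -- and the pair is mapped to one of 16 letters A..P
#' (state index 4*theta_bin + tau_bin). Positions where the angles are
#' undefined (the first two residues and the last) are encoded 'X'.
#' Because the alphabet is built from internal coordinates it is exactly
#' invariant under rigid motion.
#'
#' @param s A `ProteinStructure` with at least 4 residues.
#' @return List with `id` and `states` (a string of length equal to the
#'   chain length).
#' @export
encode_structure <- function(s) {
  stopifnot(inherits(s, "ProteinStructure"))
  L <- length(s$resno)
  if (L < 4L) stop("need at least 4 residues to encode")
  st <- rep("X", L)
  for (i in 3:(L - 1L)) {
    th <- .pseudo_angle(s$ca[i - 1L, ], s$ca[i, ], s$ca[i + 1L, ])
    ta <- .pseudo_dihedral(s$ca[i - 2L, ], s$ca[i - 1L, ], s$ca[i, ],
                           s$ca[i + 1L, ])
    st[i] <- LETTERS[.alphabet_state(th, ta) + 1L]
  }
  list(id = s$id, states = paste(st, collapse = ""))
}

.pseudo_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cs <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}

.pseudo_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

.alphabet_state <- function(theta, tau) {
  tb <- if (theta < 90) 0L else if (theta < 105) 1L else if (theta < 120) 2L
        else 3L
  if (tau >= 180) tau <- -180  # atan2 boundary: +180 and -180 coincide
  ab <- if (tau < -90) 0L else if (tau < 0) 1L else if (tau < 90) 2L else 3L
  4L * tb + ab
}

.profile_of <- function(rows) {
  # rows: character vectors (equal length) over A..P, X, '-'
  ncol_a <- length(rows[[1L]])
  prof <- matrix(0, 16L, ncol_a)
  for (r in rows) {
    idx <- match(r, LETTERS[1:16])   # X and '-' -> NA, contribute nothing
    ok <- !is.na(idx)
    for (j in which(ok)) prof[idx[j], j] <- prof[idx[j], j] + 1
  }
  prof / length(rows)
}

#' Progressive alignment of structural strings
#'
#' Substitution scoring is the identity matrix on the 16-letter alphabet
#' (1 for equal states, 0 otherwise; 'X' scores 0 against everything).
#' Pairwise guide distances are 1 minus the shared 3-mer fraction
#' (|shared 3-mer types| / min set size); the guide tree is UPGMA on
#' those distances, and profiles are merged progressively with affine
#' gaps (default open 1.0, extend 0.1). Profile column score is the mean
#' pairwise identity (dot product of state frequencies). Tie-breaking in
#' the dynamic program prefers the diagonal, then the gap consuming the
#' first profile.
#'
#' @param strings Encoded structures: either a list of
#'   [encode_structure()] results or a named character vector of state
#'   strings.
#' @param gap_open Affine gap-opening penalty (default 1.0).
#' @param gap_extend Affine gap-extension penalty (default 0.1).
#' @return A structural MSA: data frame with columns `id`, `aligned`
#'   (rows in input order; degapping any row recovers its input string).
#' @export
progressive_align <- function(strings, gap_open = 1.0, gap_extend = 0.1) {
  if (is.list(strings) && !is.null(strings[[1L]]$states)) {
    ids <- vapply(strings, `[[`, "", "id")
    seqs <- vapply(strings, `[[`, "", "states")
  } else {
    ids <- names(strings)
    seqs <- unname(strings)
  }
  if (length(seqs) < 2L) stop("need at least 2 strings to align")
  if (is.null(ids) || any(!nzchar(ids))) stop("strings must be named")

  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 3L) return(character(0))
    unique(substring(s, 1:(n - 2L), 3:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      shared <- length(intersect(kmers[[a]], kmers[[b]])) /
        max(1L, min(length(kmers[[a]]), length(kmers[[b]])))
      d[a, b] <- d[b, a] <- 1 - shared
    }
  }
  guide <- upgma(d)

  align_groups <- function(node) {
    if (is.null(node$children)) {
      i <- match(node$label, ids)
      return(list(ids = ids[i], rows = list(strsplit(seqs[i], "")[[1L]])))
    }
    parts <- lapply(node$children, align_groups)
    acc <- parts[[1L]]
    for (k in seq(2L, length(parts))) {
      acc <- .merge_profiles(acc, parts[[k]], gap_open, gap_extend)
    }
    acc
  }
  res <- align_groups(guide)
  aligned <- vapply(res$rows, paste, "", collapse = "")
  out <- data.frame(id = res$ids, aligned = aligned, stringsAsFactors = FALSE)
  out[match(ids, out$id), , drop = FALSE]
}

.merge_profiles <- function(ga, gb, gap_open, gap_extend) {
  A <- .profile_of(ga$rows)
  B <- .profile_of(gb$rows)
  moves <- .nw_profile_cpp(A, B, gap_open, gap_extend)
  na_rows <- length(ga$rows)
  nb_rows <- length(gb$rows)
  out_rows <- vector("list", na_rows + nb_rows)
  ia <- 0L
  ib <- 0L
  cols_a <- integer(0)  # source column (0 = gap) per output column
  cols_b <- integer(0)
  for (m in moves) {
    if (m == 0L) {
      ia <- ia + 1L
      ib <- ib + 1L
      cols_a <- c(cols_a, ia)
      cols_b <- c(cols_b, ib)
    } else if (m == 1L) {
      ia <- ia + 1L
      cols_a <- c(cols_a, ia)
      cols_b <- c(cols_b, 0L)
    } else {
      ib <- ib + 1L
      cols_a <- c(cols_a, 0L)
      cols_b <- c(cols_b, ib)
    }
  }
  take <- function(row, cols) {
    out <- rep("-", length(cols))
    out[cols > 0L] <- row[cols[cols > 0L]]
    out
  }
  for (r in seq_len(na_rows)) out_rows[[r]] <- take(ga$rows[[r]], cols_a)
  for (r in seq_len(nb_rows))
    out_rows[[na_rows + r]] <- take(gb$rows[[r]], cols_b)
  list(ids = c(ga$ids, gb$ids), rows = out_rows)
}
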