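#' Alignment-based pairwise sequence identity and coverage
#'
#' Global alignment with free terminal gaps (match +1, mismatch -1, a gap
#' of length k costs 5 + k, i.e. open 5 / extend 1). Identity is the
#' fraction of identical aligned pairs over aligned columns excluding
#' terminal-gap columns; coverage of each sequence is the fraction of its
#' residues inside the aligned (non-terminal) region.
#'
#' @param a,b Protein sequences (strings) or single-row records with a
#'   `residues` column.
#' @return List with `identity`, `coverage_a`, `coverage_b`, `score`.
#' @examples
#' pairwise_identity("AAAA", "AATA")$identity  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  sa <- if (is.data.frame(a)) a$residues[1L] else a
  sb <- if (is.data.frame(b)) b$residues[1L] else b
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  letters_all <- sort(unique(c(strsplit(sa, "")[[1L]], strsplit(sb, "")[[1L]])))
  sub <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "overlap", substitutionMatrix = sub,
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  # alignedPattern/alignedSubject cover the overlap region only, so every
  # remaining column is non-terminal
  ncols <- length(pa)
  ident <- sum(pa == pb & pa != "-") / ncols
  list(identity = ident,
       coverage_a = sum(pa != "-") / nchar(sa),
       coverage_b = sum(pb != "-") / nchar(sb),
       score = Biostrings::score(aln))
}

#' Greedy redundancy clustering (CD-HIT-style)
#'
#' Records are sorted by decreasing length (ties by id, lexicographic).
#' The first unassigned record founds a cluster; each subsequent record
#' joins the first representative (in creation order) with identity >=
#' `min_identity` and bidirectional coverage (the minimum of both
#' coverages) >= `min_coverage`, otherwise it founds a new cluster. The
#' canonical sort makes the result invariant to input order.
#'
#' @param records Data frame with columns `id`, `residues`.
#' @param min_identity Identity threshold in (0, 1\].
#' @param min_coverage Coverage threshold in (0, 1\].
#' @return List of class `ClusterSet`: `clusters` (each with
#'   `representative`, `members`, `identity`, `coverage`) and
#'   `thresholds`.
#' @export
greedy_cluster <- function(records, min_identity = 0.9, min_coverage = 0.9) {
  stopifnot(nrow(records) >= 1L,
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  ord <- order(-nchar(records$residues), records$id)
  rec <- records[ord, , drop = FALSE]
  reps <- integer(0)   # row indices of representatives, creation order
  clusters <- list()
  for (k in seq_len(nrow(rec))) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      p <- pairwise_identity(rec$residues[k], rec$residues[reps[ci]])
      if (p$identity >= min_identity &&
          min(p$coverage_a, p$coverage_b) >= min_coverage) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, rec$id[k])
        clusters[[ci]]$identity <- c(clusters[[ci]]$identity, p$identity)
        clusters[[ci]]$coverage <- c(clusters[[ci]]$coverage,
                                     min(p$coverage_a, p$coverage_b))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, k)
      clusters[[length(clusters) + 1L]] <- list(
        representative = rec$id[k], members = rec$id[k],
        identity = 1, coverage = 1)
    }
  }
  structure(list(clusters = clusters,
                 thresholds = list(min_identity = min_identity,
                                   min_coverage = min_coverage)),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat("ClusterSet:", length(x$clusters), "clusters at identity >=",
      x$thresholds$min_identity, "/ coverage >=",
      x$thresholds$min_coverage, "\n")
  invisible(x)
}

#' Cluster membership as a flat table
#' @param cs A `ClusterSet`.
#' @return Data frame: `representative`, `member`, `identity`, `coverage`.
#' @export
cluster_table <- function(cs) {
  stopifnot(inherits(cs, "ClusterSet"))
  do.call(rbind, lapply(cs$clusters, function(cl)
    data.frame(representative = cl$representative, member = cl$members,
               identity = cl$identity, coverage = cl$coverage,
               stringsAsFactors = FALSE)))
}

#' Filter structures by mean pLDDT
#'
#' Retains structures whose mean per-residue pLDDT is strictly greater
#' than `min_mean`. Structures without pLDDT (experimental models) pass
#' with a warning, since they carry no model-confidence estimate.
#'
#' @param structures List of `ProteinStructure`s.
#' @param min_mean Threshold (default 70; retention requires mean > 70).
#' @return List with `retained` (structures) and `report` (data frame:
#'   `id`, `mean_plddt`, `retained`).
#' @export
filter_mean_plddt <- function(structures, min_mean = 70) {
  ids <- vapply(structures, function(s) s$id, "")
  means <- vapply(structures, function(s)
    if (is.null(s$plddt)) NA_real_ else mean(s$plddt, na.rm = TRUE), 0)
  keep <- ifelse(is.na(means), TRUE, means > min_mean)
  if (any(is.na(means))) {
    warning("structures without pLDDT retained unfiltered: ",
            paste(ids[is.na(means)], collapse = ", "))
  }
  list(retained = structures[keep],
       report = data.frame(id = ids, mean_plddt = means, retained = keep,
                           stringsAsFactors = FALSE))
}
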