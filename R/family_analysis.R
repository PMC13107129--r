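#' Per-column conservation profile of a protein MSA (sequence-logo math)
#'
#' For each column j, over non-gap residues: Shannon entropy
#' H_j = -sum p log2 p and information content
#' IC_j = log2(20) - H_j - e_n, where e_n = 19 / (2 ln(2) n) is the
#' small-sample correction for n observed residues (floored at 0, and
#' toggleable). Letter heights are p * IC_j, so column heights sum to
#' IC_j. All-gap columns get IC 0 and are flagged.
#'
#' @param msa Data frame with columns `id`, `aligned` (protein MSA, gap
#'   '-'), or a named character vector of aligned rows.
#' @param correction Apply the small-sample correction (default TRUE).
#' @return List of class `ConservationProfile`: `table` (per-column data
#'   frame with `n`, `entropy`, `ic`, `consensus`, `all_gap`) and
#'   `heights` (20 x n_col matrix of letter heights).
#' @export
conservation_profile <- function(msa, correction = TRUE) {
  if (!is.data.frame(msa)) {
    msa <- data.frame(id = names(msa), aligned = unname(msa),
                      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(msa) >= 2L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  chars <- do.call(rbind, strsplit(msa$aligned, ""))
  ncolumns <- ncol(chars)
  heights <- matrix(0, 20L, ncolumns, dimnames = list(aas, NULL))
  tab <- data.frame(column = seq_len(ncolumns), n = 0L,
                    entropy = NA_real_, ic = 0, consensus = NA_character_,
                    all_gap = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncolumns)) {
    col <- chars[, j]
    col <- col[col %in% aas]
    n <- length(col)
    if (n == 0L) {
      tab$all_gap[j] <- TRUE
      next
    }
    counts <- table(factor(col, levels = aas))
    p <- as.numeric(counts) / n
    H <- -sum(ifelse(p > 0, p * log2(p), 0))
    en <- if (correction) 19 / (2 * log(2) * n) else 0
    ic <- max(0, log2(20) - H - en)
    tab$n[j] <- n
    tab$entropy[j] <- H
    tab$ic[j] <- ic
    tab$consensus[j] <- aas[which.max(counts)]
    heights[, j] <- p * ic
  }
  structure(list(table = tab, heights = heights),
            class = "ConservationProfile")
}

#' Find motif occurrences (restricted pattern over letters and 'x')
#'
#' The pattern alphabet is uppercase letters plus 'x' for "any residue".
#' Matches may overlap; all 1-based start positions are returned.
#'
#' @param x A sequence string, or an MSA (data frame `id`, `aligned`) whose
#'   consensus (via [conservation_profile()]) is searched.
#' @param pattern Pattern such as "YxxK" or "KHYYM".
#' @return Integer vector of match start positions (possibly empty).
#' @examples
#' find_motif("AYAAKA", "YxxK")  # 2
#' @export
find_motif <- function(x, pattern) {
  if (!nzchar(pattern) || !grepl("^[A-Zx]+$", pattern))
    stop("malformed pattern (uppercase letters and 'x' only): ", pattern)
  if (is.data.frame(x)) {
    prof <- conservation_profile(x, correction = FALSE)
    x <- paste(ifelse(is.na(prof$table$consensus), "X",
                      prof$table$consensus), collapse = "")
  }
  rx <- paste0("(?=", gsub("x", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, x, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Check conservation of catalytic sites against a reference sequence
#'
#' Each site is given as a 1-based position in the ungapped reference
#' sequence plus the expected residue; the MSA column is located through
#' the reference row's gaps, and the conservation fraction is the share
#' of rows carrying the expected residue in that column (gaps excluded).
#'
#' @param msa Data frame with columns `id`, `aligned`.
#' @param ref_id Id of the reference row.
#' @param sites Data frame with columns `position`, `expected` (one-letter).
#' @return Data frame of class `CatalyticReport`: `position`, `expected`,
#'   `observed` (reference row), `column`, `conservation`.
#' @export
check_catalytic_sites <- function(msa, ref_id, sites) {
  stopifnot(is.data.frame(msa), ref_id %in% msa$id,
            all(c("position", "expected") %in% names(sites)))
  ref <- strsplit(msa$aligned[msa$id == ref_id], "")[[1L]]
  ungapped_pos <- cumsum(ref != "-")
  ref_len <- max(ungapped_pos)
  chars <- do.call(rbind, strsplit(msa$aligned, ""))
  out <- data.frame(position = as.integer(sites$position),
                    expected = sites$expected,
                    observed = NA_character_, column = NA_integer_,
                    conservation = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(sites))) {
    p <- sites$position[k]
    if (p < 1L || p > ref_len)
      stop("site position ", p, " beyond reference length ", ref_len)
    col <- which(ungapped_pos == p & ref != "-")[1L]
    letters_col <- chars[, col]
    nong <- letters_col[letters_col != "-"]
    out$observed[k] <- ref[col]
    out$column[k] <- col
    out$conservation[k] <- if (length(nong) == 0L) 0 else
      mean(nong == sites$expected[k])
  }
  class(out) <- c("CatalyticReport", class(out))
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table by the
#' standard closed form; 1 for identical partitions, ~0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length (any types coercible to
#'   factors).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Delineate similarity blocks and score agreement with family labels
#'
#' The predicted partition is obtained by average-linkage (UPGMA)
#' clustering of 1 - TM and cutting at the height that maximizes the
#' mean silhouette width over all candidate cut heights (midpoints
#' between consecutive merge heights, 2 <= k <= n-1 clusters). This is
#' the operational definition of the visual "similarity blocks" of a
#' clustered heatmap. Agreement with the given family labels is scored
#' by adjusted Rand index and purity.
#'
#' @param x A `SimilarityMatrix`, a labelled symmetric TM matrix, or a
#'   `repscan_tree` (then cophenetic distances are used for silhouette).
#' @param labels Named vector mapping every id to its true family; when
#'   `x` is a `SimilarityMatrix` with family annotation it is the default.
#' @return List of class `AgreementScores`: `block_count`,
#'   `adjusted_rand_index`, `purity`, `cut_height`, `partition`.
#' @export
partition_agreement <- function(x, labels = NULL) {
  if (inherits(x, "SimilarityMatrix")) {
    if (is.null(labels)) labels <- x$family
    d <- 1 - x$values
    diag(d) <- 0
    tree <- upgma(d)
  } else if (inherits(x, "repscan_tree")) {
    tree <- x
    d <- tree_cophenetic(x)
  } else {
    d <- 1 - as.matrix(x)
    diag(d) <- 0
    tree <- upgma(d)
  }
  if (is.null(labels) || all(is.na(labels))) stop("family labels required")
  ids <- sort(tree_leaves(tree))
  if (!all(ids %in% names(labels))) stop("every id must be labelled")
  if (length(unique(labels[ids])) < 2L) stop("need at least 2 labels")

  hts <- sort(unique(tree_heights(tree)))
  cuts <- (c(0, hts[-length(hts)]) + hts) / 2
  n <- length(ids)
  best_sil <- -Inf
  best <- NULL
  dsub <- d[ids, ids]
  for (h in rev(cuts)) {  # prefer fewer blocks on silhouette ties
    part <- cut_tree(tree, h)[ids]
    k <- length(unique(part))
    if (k < 2L || k > n - 1L) next
    sil <- mean(cluster::silhouette(part, dmatrix = dsub)[, "sil_width"])
    if (sil > best_sil + 1e-12) {
      best_sil <- sil
      best <- list(partition = part, cut_height = h)
    }
  }
  if (is.null(best)) stop("no admissible cut height")
  truth <- labels[ids]
  purity <- sum(vapply(split(truth, best$partition),
                       function(g) max(table(g)), 0)) / n
  structure(list(block_count = length(unique(best$partition)),
                 adjusted_rand_index = adjusted_rand_index(best$partition,
                                                           truth),
                 purity = purity, cut_height = best$cut_height,
                 partition = best$partition, silhouette = best_sil),
            class = "AgreementScores")
}

#' @export
print.AgreementScores <- function(x, ...) {
  cat(sprintf("AgreementScores: %d blocks, ARI %.3f, purity %.3f\n",
              x$block_count, x$adjusted_rand_index, x$purity))
  invisible(x)
}

#' Rank other families by mean structural similarity to a query family
#'
#' @param simmat A `SimilarityMatrix` with family annotation (or a
#'   labelled matrix plus a `families` map).
#' @param query_family Family tag to rank against.
#' @param families Named id-to-family vector (defaults to the matrix
#'   annotation).
#' @return Data frame `family`, `mean_tm`, sorted by decreasing mean TM
#'   (ties by tag, alphabetical).
#' @export
nearest_family <- function(simmat, query_family, families = NULL) {
  if (inherits(simmat, "SimilarityMatrix")) {
    m <- simmat$values
    if (is.null(families)) families <- simmat$family
  } else {
    m <- as.matrix(simmat)
  }
  if (is.null(families)) stop("family annotation required")
  fams <- families[rownames(m)]
  if (!query_family %in% fams) stop("unknown family tag: ", query_family)
  if (length(unique(fams)) < 2L) stop("need at least 2 families")
  q_ids <- rownames(m)[fams == query_family]
  others <- setdiff(unique(fams), query_family)
  means <- vapply(others, function(f) {
    mean(m[q_ids, rownames(m)[fams == f], drop = FALSE])
  }, 0)
  out <- data.frame(family = others, mean_tm = unname(means),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_tm, out$family), , drop = FALSE]
}
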