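#' Average-linkage (UPGMA) agglomeration of a labelled distance matrix
#'
#' Classic UPGMA: repeatedly join the pair of clusters with the smallest
#' average linkage; the new node sits at half the joining distance, so the
#' result is ultrametric (leaves at height 0). Ties are broken by the
#' lexicographically smallest pair of cluster labels, a cluster's label
#' being its smallest leaf label; this makes the topology deterministic.
#'
#' @param d Symmetric, non-negative numeric matrix with zero diagonal and
#'   row/column names (asymmetry beyond 1e-9 is an error), or a `dist`.
#' @return A rooted tree of class `repscan_tree`: nested nodes with fields
#'   `height`, `children` (internal) or `label` (leaf), and `support`
#'   (percent, NA until [bootstrap_tree()] fills it in).
#' @examples
#' d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' tr <- upgma(d)
#' tr$height  # 2: half the joining distance
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) >= 2L)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")

  labs <- rownames(d)
  nodes <- lapply(labs, function(l)
    structure(list(height = 0, label = l, children = NULL, support = NA_real_),
              class = "repscan_tree"))
  sizes <- rep(1L, length(labs))
  minlab <- labs           # smallest leaf label per live cluster
  D <- d
  live <- seq_along(labs)

  while (length(live) > 1L) {
    sub <- D[live, live, drop = FALSE]
    best <- Inf
    bi <- bj <- NA_integer_
    for (a in seq_along(live)) {
      for (b in seq_along(live)) {
        if (b <= a) next
        v <- sub[a, b]
        pick <- FALSE
        if (is.na(bi) || v < best - 1e-12) {
          pick <- TRUE
        } else if (v <= best + 1e-12) {
          # tie: lexicographically smallest sorted label pair
          cur <- sort(c(minlab[live[a]], minlab[live[b]]))
          old <- sort(c(minlab[live[bi]], minlab[live[bj]]))
          if (cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2]))
            pick <- TRUE
        }
        if (pick) {
          best <- min(best, v)
          bi <- a
          bj <- b
        }
      }
    }
    i <- live[bi]
    j <- live[bj]
    new_node <- structure(
      list(height = best / 2, label = NULL,
           children = list(nodes[[i]], nodes[[j]]), support = NA_real_),
      class = "repscan_tree")
    ni <- sizes[i]
    nj <- sizes[j]
    # average-linkage update of distances to the merged cluster
    for (k in live) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (ni * D[i, k] + nj * D[j, k]) / (ni + nj)
    }
    nodes[[i]] <- new_node
    sizes[i] <- ni + nj
    minlab[i] <- min(minlab[i], minlab[j])
    live <- setdiff(live, j)
  }
  nodes[[live]]
}

#' Leaf labels of a tree, in traversal order
#' @param tree A `repscan_tree`.
#' @return Character vector of leaf labels.
#' @export
tree_leaves <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Leaf-set clades of all internal nodes
#' @param tree A `repscan_tree`.
#' @return List of sorted character vectors, one per internal node
#'   (root included).
#' @export
tree_clades <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    out[[length(out) + 1L]] <<- sort(tree_leaves(node))
    for (ch in node$children) walk(ch)
    invisible()
  }
  walk(tree)
  out
}

#' Cut an ultrametric tree at a height
#' @param tree A `repscan_tree`.
#' @param h Cut height.
#' @return Named integer vector: cluster membership per leaf label.
#' @export
cut_tree <- function(tree, h) {
  groups <- list()
  walk <- function(node) {
    if (node$height <= h || is.null(node$children)) {
      groups[[length(groups) + 1L]] <<- tree_leaves(node)
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree)
  membership <- integer(0)
  for (g in seq_along(groups))
    membership[groups[[g]]] <- g
  membership
}

#' Heights of all internal nodes
#' @param tree A `repscan_tree`.
#' @return Numeric vector of internal node heights (root first).
#' @export
tree_heights <- function(tree) {
  if (is.null(tree$children)) return(numeric(0))
  c(tree$height, unlist(lapply(tree$children, tree_heights)))
}

#' Pairwise distances induced by an ultrametric tree
#' @param tree A `repscan_tree`.
#' @return Symmetric labelled matrix: 2 x height of the smallest clade
#'   containing each leaf pair.
#' @export
tree_cophenetic <- function(tree) {
  leaves <- sort(tree_leaves(tree))
  m <- matrix(0, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    sets <- lapply(node$children, tree_leaves)
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (b <= a) next
        m[sets[[a]], sets[[b]]] <<- 2 * node$height
        m[sets[[b]], sets[[a]]] <<- 2 * node$height
      }
    }
    for (ch in node$children) walk(ch)
    invisible()
  }
  walk(tree)
  m
}

#' Convert a repscan tree to an ape "phylo" object
#'
#' Branch lengths are parent height minus child height; bootstrap supports
#' (when present) become internal `node.label`s.
#'
#' @param tree A `repscan_tree`.
#' @return An [ape::as.phylo] compatible `phylo` object.
#' @export
tree_as_phylo <- function(tree) {
  leaves <- tree_leaves(tree)
  n_tip <- length(leaves)
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  node_lab <- character(0)
  next_internal <- n_tip
  tip_i <- 0L
  assign_num <- function(node) {
    if (is.null(node$children)) {
      tip_i <<- tip_i + 1L
      return(tip_i)
    }
    next_internal <<- next_internal + 1L
    me <- next_internal
    node_lab[me - n_tip] <<- if (is.na(node$support)) "" else
      format(node$support)
    for (ch in node$children) {
      chn <- assign_num(ch)
      edges <<- rbind(edges, c(me, chn))
      lens <<- c(lens, node$height - ch$height)
    }
    me
  }
  assign_num(tree)
  phy <- list(edge = edges, edge.length = lens, tip.label = leaves,
              Nnode = next_internal - n_tip, node.label = node_lab)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' p-distance matrix of an aligned set of strings
#'
#' Mismatch fraction over columns where neither row has a gap ('-') and
#' neither has the undefined state 'X' (treated as missing data).
#'
#' @param msa A structural MSA: data frame with columns `id`, `aligned`.
#' @param on_empty What to do for a row pair with zero comparable columns:
#'   "error" (default) or "max" (distance 1, used inside bootstrap
#'   replicates where column resampling can empty a pair).
#' @return Symmetric labelled distance matrix.
#' @export
msa_pdistance <- function(msa, on_empty = c("error", "max")) {
  on_empty <- match.arg(on_empty)
  chars <- do.call(rbind, strsplit(msa$aligned, ""))
  rownames(chars) <- msa$id
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  usable <- chars != "-" & chars != "X"
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      comp <- usable[a, ] & usable[b, ]
      if (!any(comp)) {
        if (on_empty == "error")
          stop("no comparable columns between ", msa$id[a], " and ", msa$id[b])
        d[a, b] <- d[b, a] <- 1
      } else {
        d[a, b] <- d[b, a] <- mean(chars[a, comp] != chars[b, comp])
      }
    }
  }
  d
}

#' UPGMA dendrogram with column-bootstrap supports
#'
#' Builds the reference tree by UPGMA on the p-distance of the MSA, then
#' resamples alignment columns with replacement `n_reps` times; the
#' support of each internal node is the percentage of replicate trees
#' containing the same leaf bipartition (clade). Rows are sorted by id
#' before any sampling so supports are invariant to input order.
#'
#' @param msa Structural MSA (data frame `id`, `aligned`).
#' @param n_reps Number of bootstrap replicates (default 1500).
#' @param seed Integer seed for column resampling.
#' @return The reference `repscan_tree` with `support` set on internal
#'   nodes (percent).
#' @export
bootstrap_tree <- function(msa, n_reps = 1500L, seed = 1L) {
  stopifnot(nrow(msa) >= 3L, n_reps >= 1L)
  msa <- msa[order(msa$id), , drop = FALSE]
  ref <- upgma(msa_pdistance(msa, on_empty = "error"))
  clades <- tree_clades(ref)
  keys <- vapply(clades, paste, "", collapse = "\r")
  hits <- setNames(numeric(length(keys)), keys)
  ncol_aln <- nchar(msa$aligned[1L])
  chars <- do.call(rbind, strsplit(msa$aligned, ""))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_msa <- data.frame(
      id = msa$id,
      aligned = apply(chars[, cols, drop = FALSE], 1L, paste, collapse = ""),
      stringsAsFactors = FALSE)
    rep_tree <- upgma(msa_pdistance(rep_msa, on_empty = "max"))
    rep_keys <- vapply(tree_clades(rep_tree), paste, "", collapse = "\r")
    seen <- keys %in% rep_keys
    hits[seen] <- hits[seen] + 1
  }
  support <- 100 * hits / n_reps
  decorate <- function(node) {
    if (is.null(node$children)) return(node)
    key <- paste(sort(tree_leaves(node)), collapse = "\r")
    node$support <- unname(support[key])
    node$children <- lapply(node$children, decorate)
    node
  }
  decorate(ref)
}
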