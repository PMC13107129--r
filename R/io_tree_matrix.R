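#' Serialize a tree as Newick
#'
#' Branch lengths are parent height minus child height; bootstrap supports
#' (when present) are written as internal-node labels. Leaf labels
#' containing Newick-reserved characters ( `(),:;` or whitespace ) are
#' single-quoted when `quote = TRUE`, otherwise they are an error.
#'
#' @param tree A `repscan_tree`.
#' @param path Optional output path; when NULL the string is returned.
#' @param quote Quote reserved labels instead of erroring (default FALSE).
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL, quote = FALSE) {
  fmt_label <- function(l) {
    if (grepl("[(),:;[:space:]]", l)) {
      if (!quote) stop("label contains Newick-reserved characters: ", l)
      l <- paste0("'", gsub("'", "''", l), "'")
    }
    l
  }
  rec <- function(node, parent_height) {
    bl <- sprintf(":%g", parent_height - node$height)
    if (is.null(node$children)) return(paste0(fmt_label(node$label), bl))
    inner <- paste(vapply(node$children, rec, "", node$height), collapse = ",")
    sup <- if (!is.null(node$support) && !is.na(node$support))
      format(node$support) else ""
    paste0("(", inner, ")", sup, bl)
  }
  if (is.null(tree$children)) {
    s <- paste0(fmt_label(tree$label), ";")
  } else {
    inner <- paste(vapply(tree$children, rec, "", tree$height), collapse = ",")
    sup <- if (!is.null(tree$support) && !is.na(tree$support))
      format(tree$support) else ""
    s <- paste0("(", inner, ")", sup, ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Write a labelled matrix as TSV (header row and label column)
#' @param m Numeric matrix with dimnames, or a `SimilarityMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "SimilarityMatrix")) m <- m$values
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix from TSV
#' @param path TSV written by [write_matrix_tsv()].
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a square PHYLIP distance matrix
#' @param m Symmetric labelled numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path) {
  if (inherits(m, "SimilarityMatrix")) m <- m$values
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(sprintf("%-10s", rownames(m)[i]),
                      paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#' @param path File written by [write_phylip_matrix()].
#' @return Numeric matrix with dimnames.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    labs[i] <- parts[1L]
    m[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(m) <- list(labs, labs)
  m
}
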