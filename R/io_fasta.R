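#' Read a FASTA file into a sequence-record table
#'
#' Parses FASTA with a strict dialect: the '>' header line is split at the
#' first whitespace into `id` and `description`, wrapped sequence lines are
#' joined, and residues are uppercased. With `alphabet = "dna"` records may
#' contain only A, C, G, T, N.
#'
#' @param path Path to a text FASTA file.
#' @param alphabet One of "protein" (letters A-Z) or "dna" (A,C,G,T,N).
#' @return A `data.frame` with columns `id`, `description`, `residues`,
#'   in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "ACGT"), tf)
#' read_fasta(tf, alphabet = "dna")
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)          # CRLF tolerance
  lines <- sub("[ \t]+$", "", lines)      # trailing whitespace tolerance
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no records in ", path)
  ok <- if (alphabet == "dna") "^[ACGTN]*$" else "^[A-Z]*$"
  ids <- character(length(hdr))
  descs <- character(length(hdr))
  seqs <- character(length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[k]])
    ids[k] <- sub("[ \t].*$", "", h)
    descs[k] <- if (grepl("[ \t]", h)) sub("^[^ \t]+[ \t]+", "", h) else ""
    body_idx <- seq(hdr[k] + 1L, length.out = bounds[k + 1L] - hdr[k] - 1L)
    body <- toupper(lines[body_idx])
    bad <- body_idx[!grepl(ok, body)]
    if (length(bad) > 0L) {
      stop("illegal characters in sequence at line ", bad[1L], " of ", path)
    }
    seqs[k] <- paste(body, collapse = "")
  }
  if (any(ids == "")) stop("empty record id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate record id: ", dup[1L])
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record: ", ids[which(nchar(seqs) == 0L)[1L]])
  }
  data.frame(id = ids, description = descs, residues = seqs,
             stringsAsFactors = FALSE)
}

#' Write a sequence-record table as FASTA
#'
#' @param records Data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[k] else ""
    hdr <- if (nzchar(desc)) paste0(">", records$id[k], " ", desc) else
      paste0(">", records$id[k])
    writeLines(hdr, con)
    s <- records$residues[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
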