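#' Read replicon feature annotations (GFF3 or TSV)
#'
#' A minimal GFF3 dialect: 9 tab-separated columns, `#` comment lines
#' skipped, feature type taken from column 3, `ID=` parsed from column 9
#' when present. Coordinates are 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return Data frame with columns `seq_id`, `feature`, `start`, `end`,
#'   `strand`, `attr_id`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(), feature = character(),
                      start = integer(), end = integer(),
                      strand = character(), attr_id = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 8L)) stop("malformed GFF3 line in ", path)
  out <- data.frame(
    seq_id = vapply(f, `[`, "", 1L),
    feature = vapply(f, `[`, "", 3L),
    start = as.integer(vapply(f, `[`, "", 4L)),
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L),
    attr_id = vapply(f, function(x) {
      a <- if (length(x) >= 9L) x[9L] else ""
      m <- regmatches(a, regexpr("(?<=ID=)[^;]+", a, perl = TRUE))
      if (length(m)) m else ""
    }, ""),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("annotation with start > end in ", path)
  out
}

#' Write replicon feature annotations as GFF3
#'
#' @param ann Data frame with columns `seq_id`, `feature`, `start`, `end`,
#'   `strand` (and optionally `attr_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  need <- c("seq_id", "feature", "start", "end", "strand")
  stopifnot(is.data.frame(ann), all(need %in% names(ann)))
  ids <- if ("attr_id" %in% names(ann)) ann$attr_id else
    paste0(ann$feature, seq_len(nrow(ann)))
  body <- sprintf("%s\trepscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                  ann$seq_id, ann$feature, as.integer(ann$start),
                  as.integer(ann$end), ann$strand, ids)
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}
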