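#' Reverse complement of a DNA string
#' @param s DNA string over A,C,G,T,N.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' Configuration for the synthetic replicon generator
#'
#' Defaults reproduce the layout of a betapleolipovirus-like rolling-
#' circle replicon: a rep ORF followed by a noncoding region of 270 nt
#' whose inverted repeat sits at region positions 156-166 and whose
#' hairpin motif lies within 176-197.
#'
#' @param orf_length ORF length in nt (multiple of 3, default 1200).
#' @param region_length Noncoding region length (default 270).
#' @param ir_span Region coordinates of the inverted repeat
#'   (default c(156, 166)).
#' @param hairpin_span Region coordinates hosting the hairpin
#'   (default c(176, 197)).
#' @param stem_len Planted hairpin stem length in bp (default 6).
#' @param loop_len Planted hairpin loop length in nt (default 4).
#' @param seed Integer seed.
#' @return A validated `RepliconConfig` list.
#' @export
replicon_config <- function(orf_length = 1200L, region_length = 270L,
                            ir_span = c(156L, 166L),
                            hairpin_span = c(176L, 197L),
                            stem_len = 6L, loop_len = 4L, seed = 1L) {
  if (orf_length %% 3L != 0L) stop("orf_length must be a multiple of 3")
  if (ir_span[2L] >= hairpin_span[1L])
    stop("ir_span must lie upstream of hairpin_span")
  if (hairpin_span[2L] > region_length || ir_span[1L] < 1L)
    stop("spans must lie within the region")
  hp_len <- hairpin_span[2L] - hairpin_span[1L] + 1L
  if (2L * stem_len + loop_len > hp_len)
    stop("hairpin span cannot host the requested stem/loop")
  if (loop_len < 3L) stop("loop must be >= 3 nt")
  structure(list(orf_length = as.integer(orf_length),
                 region_length = as.integer(region_length),
                 ir_span = as.integer(ir_span),
                 hairpin_span = as.integer(hairpin_span),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len), seed = as.integer(seed)),
            class = "RepliconConfig")
}

#' Generate a synthetic replicon with a planted bipartite origin
#'
#' Emits a rep ORF (ATG + random non-stop codons + TAA) followed by a
#' noncoding region with (a) an exact inverted repeat filling `ir_span`
#' (two complementary arms around a spacer) and (b) a perfect hairpin
#' (stem of `stem_len` Watson-Crick pairs around a `loop_len` loop)
#' planted at the start of `hairpin_span`; all remaining positions are
#' i.i.d. uniform. Region coordinates are 1-based from the first
#' nucleotide after the ORF stop codon.
#'
#' @param config A [replicon_config()].
#' @return List: `record` (sequence data frame), `annotations` (GFF-style
#'   data frame with absolute coordinates), `planted` (region-coordinate
#'   list: `ir` with arms/spacer, `hairpin` with stem/loop spans).
#' @export
make_replicon <- function(config = replicon_config()) {
  stopifnot(inherits(config, "RepliconConfig"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codons <- config$orf_length / 3L - 2L
  orf <- paste0("ATG", paste(sample(codons, n_codons, replace = TRUE),
                             collapse = ""), "TAA")
  region <- sample(bases, config$region_length, replace = TRUE)

  # inverted repeat filling ir_span: arm | spacer | revcomp(arm)
  ir_len <- config$ir_span[2L] - config$ir_span[1L] + 1L
  arm <- (ir_len - 3L) %/% 2L
  spacer <- ir_len - 2L * arm
  if (arm < 3L) stop("ir_span too short to host an inverted repeat")
  left <- sample(bases, arm, replace = TRUE)
  right <- strsplit(reverse_complement(paste(left, collapse = "")), "")[[1L]]
  ir_pos <- config$ir_span[1L]
  region[ir_pos:(ir_pos + arm - 1L)] <- left
  region[(ir_pos + arm + spacer):(ir_pos + ir_len - 1L)] <- right

  # hairpin at the start of hairpin_span: stem | loop | revcomp(stem)
  hp_start <- config$hairpin_span[1L]
  stem <- sample(bases, config$stem_len, replace = TRUE)
  loop <- sample(bases, config$loop_len, replace = TRUE)
  stem_rc <- strsplit(reverse_complement(paste(stem, collapse = "")), "")[[1L]]
  hp_len <- 2L * config$stem_len + config$loop_len
  region[hp_start:(hp_start + hp_len - 1L)] <- c(stem, loop, stem_rc)

  seq_full <- paste0(orf, paste(region, collapse = ""))
  off <- config$orf_length
  rid <- paste0("replicon", config$seed)
  ann <- data.frame(
    seq_id = rid,
    feature = c("rep_orf", "ir", "hairpin"),
    start = c(1L, off + config$ir_span[1L], off + hp_start),
    end = c(off, off + config$ir_span[2L], off + hp_start + hp_len - 1L),
    strand = "+",
    attr_id = c("rep", "ir1", "hp1"),
    stringsAsFactors = FALSE)
  planted <- list(
    ir = list(left_arm = c(ir_pos, ir_pos + arm - 1L),
              right_arm = c(ir_pos + arm + spacer, ir_pos + ir_len - 1L),
              spacer_len = spacer),
    hairpin = list(span = c(hp_start, hp_start + hp_len - 1L),
                   stem_len = config$stem_len,
                   loop_span = c(hp_start + config$stem_len,
                                 hp_start + config$stem_len +
                                   config$loop_len - 1L)))
  list(record = data.frame(id = rid, description = "synthetic replicon",
                           residues = seq_full, stringsAsFactors = FALSE),
       annotations = ann, planted = planted)
}
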