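.comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.is_wc <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

.is_pairable <- function(a, b) {
  .is_wc(a, b) | (a == "G" & b == "T") | (a == "T" & b == "G")
}

.pair_weight <- function(a, b) {
  ifelse((a == "G" & b == "C") | (a == "C" & b == "G"), 3,
         ifelse((a == "A" & b == "T") | (a == "T" & b == "A"), 2,
                ifelse((a == "G" & b == "T") | (a == "T" & b == "G"), 1, 0)))
}

#' Find inverted repeats in a DNA sequence
#'
#' Reports all maximal inverted repeats (right arm = reverse complement
#' of the left arm up to `max_mismatch` mismatches; N never matches)
#' with arm length >= `min_arm` and spacer <= `max_spacer`, sorted by
#' (arm length descending, start ascending). An IR whose full span is
#' contained in the span of an already-reported longer IR is suppressed
#' as a sub-repeat.
#'
#' @param seq DNA string over A,C,G,T,N.
#' @param min_arm Minimum arm length (default 4).
#' @param max_spacer Maximum spacer length (default 10).
#' @param max_mismatch Maximum arm mismatches (default 1).
#' @return Data frame: `left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm`, `spacer_len`, `mismatches` (possibly 0 rows).
#' @examples
#' find_inverted_repeats("GAATTC", min_arm = 3, max_mismatch = 0)
#' @export
find_inverted_repeats <- function(seq, min_arm = 4L, max_spacer = 10L,
                                  max_mismatch = 1L) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over A,C,G,T,N")
  n <- length(chars)
  cand <- list()
  # For a fixed (left-arm end e, spacer sp) only the longest admissible arm
  # can be reported: every shorter arm at the same anchor lies inside its
  # span and is suppressed as a sub-repeat. So grow arms outward from each
  # anchor, tracking cumulative mismatches.
  for (e in seq_len(n)) {
    for (sp in 0:max_spacer) {
      f <- e + sp + 1L
      if (f > n) break
      mm <- 0L
      best_arm <- 0L
      best_mm <- 0L
      k <- 0L
      while (e - k >= 1L && f + k <= n) {
        a <- chars[e - k]
        b <- chars[f + k]
        if (!.is_wc(a, b)) mm <- mm + 1L
        if (mm > max_mismatch) break
        k <- k + 1L
        if (k >= min_arm) {
          best_arm <- k
          best_mm <- mm
        }
      }
      if (best_arm >= min_arm) {
        s <- e - best_arm + 1L
        cand[[length(cand) + 1L]] <- c(s, e, f, f + best_arm - 1L,
                                       best_arm, sp, best_mm)
      }
    }
  }
  out <- data.frame(left_start = integer(), left_end = integer(),
                    right_start = integer(), right_end = integer(),
                    arm = integer(), spacer_len = integer(),
                    mismatches = integer())
  if (length(cand) == 0L) return(out)
  m <- do.call(rbind, cand)
  ord <- order(-m[, 5L], m[, 1L], m[, 3L])
  m <- m[ord, , drop = FALSE]
  kept <- matrix(0L, 0L, 7L)
  for (k in seq_len(nrow(m))) {
    covered <- FALSE
    if (nrow(kept) > 0L) {
      # a sub-repeat is one whose span lies inside a strictly longer-armed
      # reported IR; equal-armed repeats never suppress each other, which
      # keeps the result exactly mirror-symmetric under reverse complement
      covered <- any(kept[, 1L] <= m[k, 1L] & kept[, 4L] >= m[k, 4L] &
                       kept[, 5L] > m[k, 5L])
    }
    if (!covered) kept <- rbind(kept, m[k, ])
  }
  data.frame(left_start = kept[, 1L], left_end = kept[, 2L],
             right_start = kept[, 3L], right_end = kept[, 4L],
             arm = kept[, 5L], spacer_len = kept[, 6L],
             mismatches = kept[, 7L])
}

#' Fold a DNA window into its best-scoring secondary structure
#'
#' Maximum-weight nested base pairing by dynamic programming with pair
#' weights GC = 3, AU(AT) = 2, GU(GT) = 1, minimum loop 3 (a pair (i, j)
#' requires j - i >= 4). With `hairpin_only = TRUE` (the default used by
#' the origin scanner) the structure is restricted to a single helix
#' around one terminal loop (bulges allowed, no bifurcation); otherwise
#' general nested structures (Nussinov-style with bifurcation) are
#' scored. Co-optimal ties resolve to the structure whose outermost pair
#' is most 5'.
#'
#' @param window DNA string, 8-200 nt.
#' @param hairpin_only Restrict to hairpin topology (default TRUE).
#' @param min_loop Minimum loop length (default 3).
#' @return List of class `Hairpin`: `pairing` (2-column matrix, i < j),
#'   `score`, `span` (first to last paired position, or NULL), and
#'   `loop_span` (innermost unpaired stretch; hairpin mode only).
#' @examples
#' fold_hairpin("GGGAAACCC")$score  # 9: three G-C pairs
#' @export
fold_hairpin <- function(window, hairpin_only = TRUE, min_loop = 3L) {
  chars <- strsplit(toupper(window), "")[[1L]]
  n <- length(chars)
  if (n < 8L || n > 200L) stop("window length must be in [8, 200]")
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j - i > min_loop) W[i, j] <- .pair_weight(chars[i], chars[j])
    }
  }
  S <- matrix(0, n, n)
  # choice per (i,j): 0 none/unpaired-right, 1 pair(i,j), 2 drop-left,
  # 3 drop-right, 4+k bifurcation at k (general mode only)
  CH <- matrix(0L, n, n)
  for (len in 2:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- S[i, j - 1L]   # j unpaired
      ch <- 3L
      alt <- if (len > 2L) S[i + 1L, j] else 0
      if (alt > best) {
        best <- alt
        ch <- 2L
      }
      if (W[i, j] > 0) {
        inner <- if (j - 1L >= i + 1L) S[i + 1L, j - 1L] else 0
        v <- W[i, j] + inner
        if (v > best) {
          best <- v
          ch <- 1L
        }
      }
      if (!hairpin_only && len > 3L) {
        for (k in seq(i + 1L, j - 2L)) {
          v <- S[i, k] + S[k + 1L, j]
          if (v > best) {
            best <- v
            ch <- 4L + k
          }
        }
      }
      S[i, j] <- best
      CH[i, j] <- ch
    }
  }
  pairs <- matrix(0L, 0L, 2L)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]
    j <- iv[2L]
    if (i >= j) next
    ch <- CH[i, j]
    if (ch == 1L) {
      pairs <- rbind(pairs, c(i, j))
      if (j - 1L >= i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else if (ch == 2L) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (ch == 3L) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else if (ch >= 4L) {
      k <- ch - 4L
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k + 1L, j)
    }
  }
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  loop_span <- NULL
  span <- NULL
  if (nrow(pairs) > 0L) {
    span <- c(min(pairs[, 1L]), max(pairs[, 2L]))
    if (hairpin_only) {
      inner <- pairs[nrow(pairs), ]
      loop_span <- c(inner[1L] + 1L, inner[2L] - 1L)
    }
  }
  structure(list(pairing = pairs, score = S[1L, n], span = span,
                 loop_span = loop_span, window = toupper(window)),
            class = "Hairpin")
}

#' Scan a replicon for the bipartite origin architecture
#'
#' Looks in the window downstream of the rep ORF stop codon for
#' candidate (inverted repeat, hairpin) pairs: the hairpin must start
#' downstream of the IR with a gap of at most `max_gap` nt and fold with
#' score >= `min_score`. Candidates are ranked by composite score =
#' hairpin score + IR arm length - IR mismatches. All reported
#' coordinates are 1-based relative to the first nucleotide after the
#' stop codon (`region_*`), with absolute coordinates alongside.
#'
#' @param seq Replicon DNA string.
#' @param rep_orf One-row annotation data frame (`start`, `end`,
#'   `strand`) for the rep ORF.
#' @param window Downstream window length scanned (default 270).
#' @param min_arm,max_spacer,max_mismatch IR thresholds (see
#'   [find_inverted_repeats()]).
#' @param max_gap Maximum IR-end to hairpin-start gap (default 40).
#' @param min_score Minimum hairpin folding score (default 12).
#' @param stem_min Minimum stem arm used to nucleate hairpin candidates
#'   (default 4).
#' @param max_loop Maximum hairpin loop length considered (default 10).
#' @return Data frame of candidates sorted by decreasing
#'   `composite_score`: IR and hairpin coordinates in region and
#'   absolute frames, `ir_hairpin_gap`, `hairpin_score`,
#'   `composite_score`.
#' @export
scan_replicon <- function(seq, rep_orf, window = 270L, min_arm = 4L,
                          max_spacer = 10L, max_mismatch = 1L,
                          max_gap = 40L, min_score = 12, stem_min = 4L,
                          max_loop = 10L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (rep_orf$end[1L] > n || rep_orf$start[1L] < 1L)
    stop("rep ORF extends beyond the sequence")
  minus <- identical(rep_orf$strand[1L], "-")
  if (minus) {
    seq <- reverse_complement(seq)
    orf_end <- n - rep_orf$start[1L] + 1L
  } else {
    orf_end <- rep_orf$end[1L]
  }
  region_start <- orf_end + 1L
  region_end <- min(n, orf_end + window)
  if (region_start > region_end) {
    return(.empty_ori())
  }
  region <- substr(seq, region_start, region_end)

  irs <- find_inverted_repeats(region, min_arm = min_arm,
                               max_spacer = max_spacer,
                               max_mismatch = max_mismatch)
  if (nrow(irs) == 0L) return(.empty_ori())
  # hairpin nuclei: complementary stems with loop-sized spacers; spacer-0
  # palindromes are kept because folding enforces the minimum loop anyway
  stems <- find_inverted_repeats(region, min_arm = stem_min,
                                 max_spacer = max_loop, max_mismatch = 0L)
  if (nrow(stems) == 0L) return(.empty_ori())

  rows <- list()
  for (ii in seq_len(nrow(irs))) {
    ir <- irs[ii, ]
    for (si in seq_len(nrow(stems))) {
      st <- stems[si, ]
      gap <- st$left_start - ir$right_end - 1L
      if (gap < 0L || gap > max_gap) next
      hp <- fold_hairpin(substr(region, st$left_start, st$right_end),
                         hairpin_only = TRUE)
      if (hp$score < min_score) next
      hp_start <- st$left_start + hp$span[1L] - 1L
      hp_end <- st$left_start + hp$span[2L] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        region_ir_start = ir$left_start, region_ir_end = ir$right_end,
        ir_arm = ir$arm, ir_mismatches = ir$mismatches,
        ir_spacer = ir$spacer_len,
        region_hairpin_start = hp_start, region_hairpin_end = hp_end,
        ir_hairpin_gap = gap, hairpin_score = hp$score,
        composite_score = hp$score + ir$arm - ir$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_ori())
  out <- do.call(rbind, rows)
  out <- out[order(-out$composite_score, out$region_hairpin_start,
                   out$region_ir_start), , drop = FALSE]
  key <- paste(out$region_ir_start, out$region_ir_end,
               out$region_hairpin_start, out$region_hairpin_end)
  out <- out[!duplicated(key), , drop = FALSE]
  off <- region_start - 1L
  out$abs_ir_start <- out$region_ir_start + off
  out$abs_ir_end <- out$region_ir_end + off
  out$abs_hairpin_start <- out$region_hairpin_start + off
  out$abs_hairpin_end <- out$region_hairpin_end + off
  rownames(out) <- NULL
  out
}

.empty_ori <- function() {
  data.frame(region_ir_start = integer(), region_ir_end = integer(),
             ir_arm = integer(), ir_mismatches = integer(),
             ir_spacer = integer(), region_hairpin_start = integer(),
             region_hairpin_end = integer(), ir_hairpin_gap = integer(),
             hairpin_score = numeric(), composite_score = numeric(),
             abs_ir_start = integer(), abs_ir_end = integer(),
             abs_hairpin_start = integer(), abs_hairpin_end = integer())
}

#' Build an origin-element description for mutation classification
#'
#' @param sequence The replicon (or region) DNA string the coordinates
#'   refer to.
#' @param hairpin_pairing 2-column matrix of paired positions (i, j) in
#'   `sequence` coordinates.
#' @param hairpin_loop Integer vector `c(start, end)` of the loop span.
#' @param ir_arms Optional list with `left = c(start, end)` and
#'   `right = c(start, end)` of the inverted-repeat arms.
#' @return List of class `OriElement`.
#' @export
ori_element <- function(sequence, hairpin_pairing, hairpin_loop,
                        ir_arms = NULL) {
  structure(list(sequence = toupper(sequence),
                 hairpin_pairing = hairpin_pairing,
                 hairpin_loop = as.integer(hairpin_loop),
                 ir_arms = ir_arms),
            class = "OriElement")
}

#' Classify the structural effect of substitutions on an origin element
#'
#' Substitutions hitting hairpin stem positions are re-paired: if every
#' affected pair remains Watson-Crick/GU complementary after applying
#' all substitutions the mutation is `structure_preserving`, otherwise
#' `stem_disrupt`. Substitutions falling entirely inside the hairpin
#' loop are `loop_mutation`. Substitutions inside the inverted-repeat
#' arms are re-checked for dyad symmetry: an unchanged arm-mismatch
#' count is `symmetry_preserving`, an increase `symmetry_disrupting`.
#' Substitutions outside both elements are `none`.
#'
#' @param element An [ori_element()].
#' @param substitutions Data frame with columns `position`, `ref`, `alt`
#'   (1-based; `ref` must match the sequence), or a spec string like
#'   "G188C,C195G".
#' @return List of class `MutationClassification`: `class`, `element`
#'   ("hairpin", "ir" or "none").
#' @export
classify_mutation <- function(element, substitutions) {
  stopifnot(inherits(element, "OriElement"))
  if (is.character(substitutions)) {
    substitutions <- parse_mutation_spec(substitutions)
  }
  chars <- strsplit(element$sequence, "")[[1L]]
  if (nrow(substitutions) == 0L) {
    return(structure(list(class = "structure_preserving", element = "none"),
                     class = "MutationClassification"))
  }
  for (k in seq_len(nrow(substitutions))) {
    p <- substitutions$position[k]
    if (p < 1L || p > length(chars)) stop("position out of range: ", p)
    if (chars[p] != substitutions$ref[k])
      stop("reference base mismatch at position ", p, ": sequence has ",
           chars[p], ", spec says ", substitutions$ref[k])
  }
  mutated <- chars
  mutated[substitutions$position] <- substitutions$alt
  pos <- substitutions$position

  pairing <- element$hairpin_pairing
  stem_pos <- if (is.null(pairing) || nrow(pairing) == 0L) integer(0) else
    c(pairing[, 1L], pairing[, 2L])
  loop_pos <- if (length(element$hairpin_loop) < 2L) integer(0) else
    seq.int(element$hairpin_loop[1L], element$hairpin_loop[2L])
  ir_pos <- integer(0)
  if (!is.null(element$ir_arms)) {
    ir_pos <- c(seq.int(element$ir_arms$left[1L], element$ir_arms$left[2L]),
                seq.int(element$ir_arms$right[1L], element$ir_arms$right[2L]))
  }

  if (any(pos %in% stem_pos)) {
    hit_pairs <- pairing[pairing[, 1L] %in% pos | pairing[, 2L] %in% pos, ,
                         drop = FALSE]
    ok <- all(.is_pairable(mutated[hit_pairs[, 1L]], mutated[hit_pairs[, 2L]]))
    cls <- if (ok) "structure_preserving" else "stem_disrupt"
    return(structure(list(class = cls, element = "hairpin"),
                     class = "MutationClassification"))
  }
  if (length(loop_pos) > 0L && all(pos %in% loop_pos)) {
    return(structure(list(class = "loop_mutation", element = "hairpin"),
                     class = "MutationClassification"))
  }
  if (length(ir_pos) > 0L && any(pos %in% ir_pos)) {
    la <- element$ir_arms$left
    ra <- element$ir_arms$right
    mm_of <- function(ch) {
      l <- ch[la[1L]:la[2L]]
      r <- rev(ch[ra[1L]:ra[2L]])
      sum(!.is_wc(l, r))
    }
    cls <- if (mm_of(mutated) <= mm_of(chars)) "symmetry_preserving" else
      "symmetry_disrupting"
    return(structure(list(class = cls, element = "ir"),
                     class = "MutationClassification"))
  }
  structure(list(class = "none", element = "none"),
            class = "MutationClassification")
}

#' Parse a compact mutation spec string
#'
#' Accepts forms like "G188C,C195G" or "G188CC195G" (reference base,
#' 1-based position, alternate base, concatenated or comma-separated).
#'
#' @param spec Specification string.
#' @return Data frame with columns `position`, `ref`, `alt`.
#' @export
parse_mutation_spec <- function(spec) {
  spec <- gsub("[ ,]", "", spec)
  m <- gregexpr("[ACGT][0-9]+[ACGT]", spec)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(spec))
    stop("malformed mutation spec: ", spec)
  toks <- regmatches(spec, gregexpr("[ACGT][0-9]+[ACGT]", spec))[[1L]]
  data.frame(
    position = as.integer(gsub("[ACGT]", "", toks)),
    ref = substr(toks, 1L, 1L),
    alt = substring(toks, nchar(toks)),
    stringsAsFactors = FALSE)
}

#' Canonical SNJ2-layout origin element for mutation analysis
#'
#' A synthetic stand-in for the hairpin of the betapleolipovirus origin
#' region, built so that the published compensatory-mutation design is
#' expressible: stem pairs (186,197), (187,196), (188,195), (189,194)
#' around the loop 190-193, in 1-based region coordinates (region = the
#' noncoding stretch downstream of the rep ORF stop). Base identities at
#' the mutated sites match the published reference alleles (T186, G187,
#' G188, A191, A192, T194, C195, C196, A197); all other positions are
#' filler, since the true region sequence is not public in the main
#' text. The element carries no inverted-repeat annotation.
#'
#' @param region_length Length of the carrier region (default 210).
#' @return An [ori_element()] in region coordinates.
#' @export
snj2_origin_element <- function(region_length = 210L) {
  stopifnot(region_length >= 197L)
  chars <- rep("A", region_length)
  chars[186:189] <- c("T", "G", "G", "A")   # left stem
  chars[190:193] <- c("C", "A", "A", "T")   # loop (A191, A192 mutable)
  chars[194:197] <- c("T", "C", "C", "A")   # right stem
  pairing <- cbind(186:189, 197:194)
  ori_element(paste(chars, collapse = ""), pairing, c(190L, 193L))
}
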