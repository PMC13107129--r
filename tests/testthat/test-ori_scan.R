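test_that("inverted-repeat search matches hand-checkable palindromes", {
  ir <- find_inverted_repeats("GAATTC", min_arm = 3, max_spacer = 2,
                              max_mismatch = 0)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$left_start, 1L)
  expect_equal(ir$left_end, 3L)
  expect_equal(ir$right_start, 4L)
  expect_equal(ir$right_end, 6L)
  expect_equal(ir$spacer_len, 0L)
  expect_equal(ir$mismatches, 0L)

  expect_equal(nrow(find_inverted_repeats("AAAAAAAA", min_arm = 3,
                                          max_mismatch = 0)), 0L)
  expect_error(find_inverted_repeats("ACGU"), "A,C,G,T,N")
})

test_that("inverted-repeat search equals brute-force placement enumeration", {
  set.seed(55)
  for (k in 1:120) {
    n <- sample(4:12, 1)
    s <- random_dna(n, seed = 7000 + k)
    for (mm in 0:1) {
      got <- find_inverted_repeats(s, min_arm = 2, max_spacer = 3,
                                   max_mismatch = mm)
      oracle <- oracle_find_irs(s, min_arm = 2, max_spacer = 3,
                                max_mismatch = mm)
      rownames(got) <- rownames(oracle) <- NULL
      expect_equal(got, oracle, label = paste("seq", s, "mm", mm))
    }
  }
})

test_that("IR detection mirrors under reverse complement", {
  set.seed(66)
  for (k in 1:20) {
    s <- random_dna(30, seed = 8000 + k)
    fw <- find_inverted_repeats(s, min_arm = 3, max_spacer = 4,
                                max_mismatch = 0)
    rv <- find_inverted_repeats(reverse_complement(s), min_arm = 3,
                                max_spacer = 4, max_mismatch = 0)
    n <- nchar(s)
    mirrored <- data.frame(left_start = n - rv$right_end + 1L,
                           left_end = n - rv$right_start + 1L,
                           right_start = n - rv$left_end + 1L,
                           right_end = n - rv$left_start + 1L,
                           arm = rv$arm, spacer_len = rv$spacer_len,
                           mismatches = rv$mismatches)
    ord <- function(d) d[order(-d$arm, d$left_start, d$right_start), ]
    a <- ord(fw); b <- ord(mirrored)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, label = paste("seq", k))
  }
})

test_that("hairpin folding matches hand-foldable cases", {
  hp <- fold_hairpin("GGGAAACCC")
  expect_equal(hp$score, 9)
  expect_equal(hp$pairing, cbind(c(1L, 2L, 3L), c(9L, 8L, 7L)),
               ignore_attr = TRUE)
  expect_equal(hp$loop_span, c(4L, 6L))

  polyA <- fold_hairpin("AAAAAAAAAA")
  expect_equal(polyA$score, 0)
  expect_equal(nrow(polyA$pairing), 0L)

  # minimum loop: pairs need j - i >= 4
  expect_equal(fold_hairpin("GGCCGGCC", hairpin_only = TRUE)$score,
               oracle_fold_hairpin("GGCCGGCC"))
  expect_error(fold_hairpin("GGGAAAC", hairpin_only = TRUE), "length")
})

test_that("general folding equals the enumeration oracle on small windows", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(8:20, 1)
    s <- random_dna(n, seed = 9000 + k)
    expect_equal(fold_hairpin(s, hairpin_only = FALSE)$score,
                 oracle_fold_general(s), label = paste("window", s))
  }
})

test_that("hairpin-topology folding equals explicit chain enumeration", {
  set.seed(37)
  for (k in 1:20) {
    n <- sample(8:14, 1)
    s <- random_dna(n, seed = 9500 + k)
    expect_equal(fold_hairpin(s, hairpin_only = TRUE)$score,
                 oracle_fold_hairpin(s), label = paste("window", s))
  }
})

test_that("folding score grows when a complementary pair is appended", {
  set.seed(41)
  for (k in 1:15) {
    stem_len <- sample(3:6, 1)
    stem <- paste(sample(c("A", "C", "G", "T"), stem_len, replace = TRUE),
                  collapse = "")
    loop <- random_dna(4, seed = 100 + k)
    base <- paste0(stem, loop, reverse_complement(stem))
    ext <- sample(c("A", "C", "G", "T"), 1)
    bigger <- paste0(ext, base, chartr("ACGT", "TGCA", ext))
    expect_gte(fold_hairpin(bigger)$score, fold_hairpin(base)$score)
  }
})

test_that("replicon scanning recovers the planted bipartite origin", {
  rp <- make_replicon(replicon_config(seed = 7))
  orf <- rp$annotations[rp$annotations$feature == "rep_orf", ]
  cand <- scan_replicon(rp$record$residues, orf)
  expect_gt(nrow(cand), 0L)
  hp <- rp$planted$hairpin$span
  ir <- rp$planted$ir
  hit <- cand$region_hairpin_start <= hp[2] & cand$region_hairpin_end >= hp[1] &
    cand$region_ir_start <= ir$right_arm[2] & cand$region_ir_end >= ir$left_arm[1]
  expect_true(any(hit))
  # composite score is the documented combination
  expect_equal(cand$composite_score,
               cand$hairpin_score + cand$ir_arm - cand$ir_mismatches)
  # ranked by decreasing composite
  expect_true(all(diff(cand$composite_score) <= 0))
})

test_that("a hairpin upstream of the IR is not a candidate", {
  # poly-A carrier: no spurious complementarity; hairpin precedes the IR
  chars <- rep("A", 270)
  chars[20:25] <- c("G", "G", "C", "C", "G", "G")       # hairpin left stem
  chars[30:35] <- c("C", "C", "G", "G", "C", "C")       # right stem
  chars[60:63] <- c("G", "C", "T", "G")                 # IR left arm
  chars[67:70] <- c("C", "A", "G", "C")                 # IR right arm
  seqrep <- paste0(paste(rep("A", 27), collapse = ""), "TAA",
                   paste(chars, collapse = ""))
  orf <- data.frame(start = 1L, end = 30L, strand = "+")
  cand <- scan_replicon(seqrep, orf, min_score = 12)
  if (nrow(cand) > 0) {
    # nothing may pair the upstream hairpin with the downstream IR
    expect_true(all(cand$region_hairpin_start > cand$region_ir_end))
  }
  expect_false(any(cand$region_hairpin_start <= 35 & cand$region_ir_start >= 60))
})

test_that("scanning the minus strand mirrors plus-strand candidates", {
  rp <- make_replicon(replicon_config(seed = 13))
  orf <- rp$annotations[rp$annotations$feature == "rep_orf", ]
  fw <- scan_replicon(rp$record$residues, orf)
  rc <- reverse_complement(rp$record$residues)
  n <- nchar(rc)
  orf_m <- data.frame(start = n - orf$end + 1L, end = n - orf$start + 1L,
                      strand = "-")
  rv <- scan_replicon(rc, orf_m)
  expect_equal(fw, rv)
})

test_that("empirical false-positive candidates on unplanted sequence", {
  # regression: candidate counts on pure i.i.d. DNA (no planted elements),
  # frozen from the first run at these seeds
  counts <- vapply(1:20, function(k) {
    s <- paste0("ATG", random_dna(297, seed = 12000 + k), "TAA",
                random_dna(270, seed = 22000 + k))
    orf <- data.frame(start = 1L, end = 303L, strand = "+")
    nrow(scan_replicon(s, orf))
  }, 0L)
  expect_equal(mean(counts), 50.15, tolerance = 1e-9)
})

test_that("mutation classification reproduces the published effect classes", {
  el <- snj2_origin_element()
  expect_equal(classify_mutation(el, "G188CC195G")$class,
               "structure_preserving")
  expect_equal(classify_mutation(el, "A191TA192T")$class, "loop_mutation")
  expect_equal(classify_mutation(el, "T186GG187T")$class, "stem_disrupt")
  expect_equal(classify_mutation(el, "C195AC196A")$class, "stem_disrupt")
  expect_equal(classify_mutation(el, data.frame(position = integer(),
                                                ref = character(),
                                                alt = character()))$class,
               "structure_preserving")
  expect_error(classify_mutation(el, "A188T"), "reference base mismatch")
  # outside both elements
  expect_equal(classify_mutation(el, "A10T")$class, "none")
})

test_that("compensatory swaps preserve and single GC hits disrupt", {
  set.seed(91)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in 1:40) {
    stem_len <- sample(4:6, 1)
    loop_len <- sample(3:6, 1)
    stem <- sample(bases, stem_len, replace = TRUE)
    loop <- sample(bases, loop_len, replace = TRUE)
    seqc <- c(stem, loop, rev(comp[stem]))
    n <- length(seqc)
    pairing <- cbind(seq_len(stem_len), n + 1L - seq_len(stem_len))
    el <- ori_element(paste(seqc, collapse = ""), pairing,
                      c(stem_len + 1L, stem_len + loop_len))
    # swap a random stem pair: always structure-preserving
    i <- sample(stem_len, 1)
    j <- n + 1L - i
    swap <- data.frame(position = c(i, j), ref = seqc[c(i, j)],
                       alt = seqc[c(j, i)], stringsAsFactors = FALSE)
    expect_equal(classify_mutation(el, swap)$class, "structure_preserving")
    # substitution to A at a G-C stem position: A cannot pair with the
    # remaining G or C, so the re-pair check must report a disrupted stem
    # (a C->T change would instead leave a G.T wobble and be preserving)
    gc_pos <- which(seqc[seq_len(stem_len)] %in% c("G", "C"))
    for (p in gc_pos) {
      mut <- data.frame(position = p, ref = seqc[p], alt = "A",
                        stringsAsFactors = FALSE)
      expect_equal(classify_mutation(el, mut)$class, "stem_disrupt")
    }
  }
})

test_that("IR mutations are classified by dyad-symmetry change", {
  # arms 1..4 and 9..12 around a 4-nt spacer
  seqc <- c("G", "C", "T", "A", "A", "A", "A", "A", "T", "A", "G", "C")
  el <- ori_element(paste(seqc, collapse = ""),
                    matrix(integer(0), 0, 2), NULL,
                    ir_arms = list(left = c(1L, 4L), right = c(9L, 12L)))
  # compensatory arm change keeps symmetry
  keep <- data.frame(position = c(1L, 12L), ref = c("G", "C"),
                     alt = c("A", "T"), stringsAsFactors = FALSE)
  expect_equal(classify_mutation(el, keep)$class, "symmetry_preserving")
  # one-sided change breaks it
  brk <- data.frame(position = 1L, ref = "G", alt = "T",
                    stringsAsFactors = FALSE)
  expect_equal(classify_mutation(el, brk)$class, "symmetry_disrupting")
})
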