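test_that("conservation profiles follow sequence-logo arithmetic", {
  msa <- data.frame(id = c("r1", "r2"),
                    aligned = c("YAC-", "YTC-"), stringsAsFactors = FALSE)
  prof <- conservation_profile(msa, correction = FALSE)
  # invariant column: IC = log2(20)
  expect_equal(prof$table$ic[1], log2(20), tolerance = 1e-12)
  # two letters at 0.5/0.5: IC = log2(20) - 1
  expect_equal(prof$table$ic[2], log2(20) - 1, tolerance = 1e-12)
  # all-gap column: flagged, IC 0
  expect_true(prof$table$all_gap[4])
  expect_equal(prof$table$ic[4], 0)
  # letter heights per column sum to IC
  expect_equal(colSums(prof$heights), prof$table$ic, tolerance = 1e-12,
               ignore_attr = TRUE)

  # uniform column over all 20 residues: IC 0 before correction
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  m20 <- data.frame(id = paste0("u", 1:20), aligned = aas,
                    stringsAsFactors = FALSE)
  expect_equal(conservation_profile(m20, correction = FALSE)$table$ic, 0,
               tolerance = 1e-12)

  # the small-sample correction subtracts 19 / (2 ln2 n); at n = 2 the
  # correction exceeds log2(20) entirely and the floor at zero applies
  p2 <- conservation_profile(msa, correction = TRUE)
  expect_equal(p2$table$ic[1], 0)
  m10 <- data.frame(id = paste0("r", 1:10), aligned = rep("Y", 10),
                    stringsAsFactors = FALSE)
  expect_equal(conservation_profile(m10, correction = TRUE)$table$ic,
               log2(20) - 19 / (2 * log(2) * 10), tolerance = 1e-12)
})

test_that("information content decreases as column entropy increases", {
  make_col <- function(k) {
    # k distinct letters among 20 rows -> entropy grows with k
    letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    data.frame(id = paste0("s", 1:20),
               aligned = rep(letters20[seq_len(k)], length.out = 20),
               stringsAsFactors = FALSE)
  }
  ics <- vapply(c(1, 2, 4, 5, 10, 20), function(k)
    conservation_profile(make_col(k), correction = FALSE)$table$ic[1], 0)
  expect_true(all(diff(ics) < 0))
})

test_that("motif search returns all (overlapping) hits", {
  expect_equal(find_motif("AYAAKA", "YxxK"), 2L)
  expect_equal(find_motif("YAAKYAAK", "YxxK"), c(1L, 5L))
  expect_equal(find_motif("AAAA", "YxxK"), integer(0))
  # catalytic motif planted at the published coordinate
  set.seed(77)
  seqchars <- sample(strsplit("ACDEFGILNPQRSTVW", "")[[1L]], 320,
                     replace = TRUE)
  seqchars[281:285] <- c("K", "H", "Y", "Y", "M")
  planted <- paste(seqchars, collapse = "")
  expect_equal(find_motif(planted, "KHYYM"), 281L)
  expect_error(find_motif("AAAA", "Yx?K"), "malformed")
})

test_that("catalytic-site checks map positions through reference gaps", {
  msa <- data.frame(
    id = c("ref", "h1", "h2"),
    aligned = c("--MK-YV", "AAMKAYV", "GGMKAYA"),
    stringsAsFactors = FALSE)
  sites <- data.frame(position = c(3, 4), expected = c("Y", "V"))
  rep_out <- check_catalytic_sites(msa, "ref", sites)
  # ref position 3 (Y) sits in alignment column 6 (two leading gaps + one
  # internal gap before it)
  expect_equal(rep_out$column, c(6L, 7L))
  expect_equal(rep_out$observed, c("Y", "V"))
  expect_equal(rep_out$conservation[1], 1.0)       # Y in all rows
  expect_equal(rep_out$conservation[2], 2 / 3)     # V in 2 of 3 rows

  none <- check_catalytic_sites(msa, "ref",
                                data.frame(position = 1, expected = "W"))
  expect_equal(none$conservation, 0)
  expect_error(check_catalytic_sites(msa, "ref",
                                     data.frame(position = 9,
                                                expected = "Y")),
               "beyond reference length")
})

test_that("adjusted Rand index matches its contingency closed form", {
  a <- rep(c("x", "y", "z"), each = 4)
  expect_equal(adjusted_rand_index(a, a), 1)
  # label permutation invariance
  b <- c(x = "q", y = "r", z = "s")[a]
  expect_equal(adjusted_rand_index(a, b), 1)

  # 4-class fixture evaluated by direct arithmetic on the contingency table
  set.seed(17)
  p1 <- sample(rep(1:4, each = 5))
  p2 <- p1
  p2[sample(20, 6)] <- sample(1:4, 6, replace = TRUE)
  tab <- table(p1, p2)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expd <- ai * bj / choose(20, 2)
  expected <- (nij - expd) / ((ai + bj) / 2 - expd)
  expect_equal(adjusted_rand_index(p1, p2), expected, tolerance = 1e-12)

  # independent cross-check against mclust
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(p1, p2),
               mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
})

test_that("partition agreement recovers clean block structure", {
  # block-structured similarity: 3 families x 3 members
  ids <- paste0(rep(c("A", "B", "C"), each = 3), 1:3)
  fam <- setNames(rep(c("A", "B", "C"), each = 3), ids)
  v <- matrix(0.2, 9, 9, dimnames = list(ids, ids))
  for (f in c("A", "B", "C")) v[fam == f, fam == f] <- 0.8
  diag(v) <- 1
  sm <- structure(list(values = v, family = fam), class = "SimilarityMatrix")
  ag <- partition_agreement(sm)
  expect_equal(ag$block_count, 3L)
  expect_equal(ag$adjusted_rand_index, 1)
  expect_equal(ag$purity, 1)

  # same result when handed the tree instead of the matrix
  tr <- upgma(1 - v)
  ag2 <- partition_agreement(tr, labels = fam)
  expect_equal(ag2$block_count, 3L)
  expect_equal(ag2$adjusted_rand_index, 1)

  expect_error(partition_agreement(sm, labels = setNames(rep("A", 9), ids)),
               "at least 2")
})

test_that("nearest-family ranking uses mean cross-family similarity", {
  ids <- c("q1", "q2", "r1", "r2", "s1", "s2")
  fam <- setNames(rep(c("Q", "R", "S"), each = 2), ids)
  v <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
  v[fam == "Q", fam == "R"] <- 0.6
  v[fam == "R", fam == "Q"] <- 0.6
  diag(v) <- 1
  sm <- structure(list(values = v, family = fam), class = "SimilarityMatrix")
  nf <- nearest_family(sm, "Q")
  expect_equal(nf$family[1], "R")
  expect_equal(nf$mean_tm[1], 0.6)
  # symmetric planted relationship
  expect_equal(nearest_family(sm, "R")$family[1], "Q")

  two <- structure(list(values = v[1:4, 1:4], family = fam[1:4]),
                   class = "SimilarityMatrix")
  expect_equal(nrow(nearest_family(two, "Q")), 1L)
  expect_error(nearest_family(sm, "Z"), "unknown family")
})

test_that("nearest-family ranking is invariant under joint rigid motion", {
  ds <- small_family_dataset()
  fam <- setNames(ds$labels$family, ds$labels$id)
  subset <- ds$structures[c(1, 2, 4, 5, 7, 8)]
  sm1 <- similarity_matrix(subset, families = fam)
  moved <- lapply(subset, rigid_move, seed = 313)
  sm2 <- similarity_matrix(moved, families = fam)
  n1 <- nearest_family(sm1, "F1")
  n2 <- nearest_family(sm2, "F1")
  expect_identical(n1$family, n2$family)
  expect_equal(n1$mean_tm, n2$mean_tm, tolerance = 1e-5)
})
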