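test_that("the geometric alphabet encodes constructed angles correctly", {
  # theta = 92 (bin 1), tau = +50 (bin 2) -> state 4*1 + 2 = 6 -> 'G'
  p1 <- c(0, 0, 0)
  p2 <- c(3.8, 0, 0)
  th0 <- 92 * pi / 180
  p3 <- p2 + 3.8 * c(cos(pi - th0), sin(pi - th0), 0)
  p4 <- place_fourth(p1, p2, p3, 3.8, 92, 50)
  p5 <- place_fourth(p2, p3, p4, 3.8, 92, 50)
  s <- protein_structure("probe", rbind(p1, p2, p3, p4, p5))
  states <- strsplit(encode_structure(s)$states, "")[[1L]]
  expect_equal(states[1:2], c("X", "X"))
  expect_equal(states[5], "X")
  expect_equal(states[4], "G")

  # a long ideal helix is constant over its interior
  helix <- Reduce(function(pts, k)
    rbind(pts, place_fourth(pts[nrow(pts) - 2, ], pts[nrow(pts) - 1, ],
                            pts[nrow(pts), ], 3.8, 92, 50)),
    1:17, accumulate = FALSE, init = rbind(p1, p2, p3))
  hs <- encode_structure(protein_structure("hx", helix))$states
  inner <- substr(hs, 3, nchar(hs) - 1)
  expect_equal(unique(strsplit(inner, "")[[1L]]), "G")

  expect_error(encode_structure(protein_structure("tiny", rbind(p1, p2, p3))),
               "at least 4")
})

test_that("encoding is exactly invariant under rigid motion", {
  s <- make_scaffold(15, 50)
  e0 <- encode_structure(s)$states
  for (seed in c(5, 6)) {
    expect_identical(encode_structure(rigid_move(s, seed))$states, e0)
  }
})

test_that("progressive alignment reproduces pairwise expectations", {
  msa <- progressive_align(c(a = "GGGGG", b = "GGGGG", c = "GGGGG"))
  expect_true(all(!grepl("-", msa$aligned)))

  # single insertion: one gap opposite the inserted state
  m2 <- progressive_align(c(a = "GGGGG", b = "GGAGGG"))
  expect_equal(nchar(m2$aligned[1]), 6L)
  expect_equal(sum(strsplit(m2$aligned[1], "")[[1L]] == "-"), 1L)
  expect_false(grepl("-", m2$aligned[2]))
  gap_col <- which(strsplit(m2$aligned[m2$id == "a"], "")[[1L]] == "-")
  expect_equal(strsplit(m2$aligned[m2$id == "b"], "")[[1L]][gap_col], "A")

  # two identical rows stay mutually gap-free in a 3-row alignment
  m3 <- progressive_align(c(x = "GGGGGAAO", y = "GGGGGAAO", z = "GGPPGAA"))
  rx <- m3$aligned[m3$id == "x"]
  ry <- m3$aligned[m3$id == "y"]
  expect_identical(rx, ry)

  # degapping recovers inputs
  inputs <- c(a = "GGAGNOP", b = "GGGNOP", c = "AAGNOPG")
  m4 <- progressive_align(inputs)
  for (id in names(inputs)) {
    expect_identical(gsub("-", "", m4$aligned[m4$id == id]),
                     unname(inputs[id]))
  }
  expect_error(progressive_align(c(a = "GGG")), "at least 2")
})

test_that("UPGMA matches hand checks and stays ultrametric", {
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(d)
  expect_equal(tr$height, 2)
  expect_setequal(tree_leaves(tr), c("A", "B"))

  # an ultrametric input is reproduced exactly by the tree distances
  labs <- c("a", "b", "c", "d")
  du <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4, dimnames = list(labs, labs))
  tru <- upgma(du)
  expect_equal(tree_cophenetic(tru)[labs, labs], du, tolerance = 1e-12)

  asym <- d
  asym[1, 2] <- 4.1
  expect_error(upgma(asym), "symmetric")
})

test_that("UPGMA agrees with the brute-force agglomeration oracle", {
  set.seed(123)
  for (k in 1:50) {
    n <- sample(4:8, 1)
    labs <- paste0("t", seq_len(n))
    # coarse integer distances force frequent ties, exercising the tie rule
    m <- matrix(sample(1:5, n * n, replace = TRUE), n)
    m <- m + t(m)
    diag(m) <- 0
    dimnames(m) <- list(labs, labs)
    got <- upgma(m)
    expect_identical(tree_signature(got), tree_signature(oracle_upgma(m)),
                     label = paste("instance", k))
  }
})

test_that("bootstrap supports behave on degenerate and duplicated rows", {
  msa <- data.frame(
    id = c("a1", "a2", "b", "c", "d"),
    aligned = c("GGGGAAAACCCC", "GGGGAAAACCCC", "GGGGAAAACCCG",
                "GPGGAHAACBCC", "OPNNAHBACBDC"),
    stringsAsFactors = FALSE)
  tr <- bootstrap_tree(msa, n_reps = 50, seed = 1)
  # the duplicated pair joins at distance 0 in every replicate
  cherry_support <- NULL
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    if (setequal(tree_leaves(node), c("a1", "a2")))
      cherry_support <<- node$support
    for (ch in node$children) walk(ch)
  }
  walk(tr)
  expect_equal(cherry_support, 100)

  tr1 <- bootstrap_tree(msa, n_reps = 1, seed = 3)
  sups <- tree_heights(tr1)  # placeholder to ensure traversal works
  collect <- function(node) {
    if (is.null(node$children)) return(numeric(0))
    c(node$support, unlist(lapply(node$children, collect)))
  }
  expect_true(all(collect(tr1) %in% c(0, 100)))

  # rows with no comparable columns are an error
  bad <- data.frame(id = c("x", "y", "z"),
                    aligned = c("AA--", "--GG", "AAGG"),
                    stringsAsFactors = FALSE)
  expect_error(msa_pdistance(bad), "no comparable columns")
})

test_that("bootstrap supports are invariant to leaf input order", {
  ds <- small_family_dataset()
  enc <- lapply(ds$structures[1:6], encode_structure)
  msa <- progressive_align(enc, gap_open = 5)
  t1 <- bootstrap_tree(msa, n_reps = 30, seed = 9)
  t2 <- bootstrap_tree(msa[rev(seq_len(nrow(msa))), ], n_reps = 30, seed = 9)
  expect_identical(tree_signature(t1), tree_signature(t2))
  sup_of <- function(tr) {
    collect <- function(node) {
      if (is.null(node$children)) return(character(0))
      c(paste(paste(sort(tree_leaves(node)), collapse = ","), node$support),
        unlist(lapply(node$children, collect)))
    }
    sort(collect(tr))
  }
  expect_identical(sup_of(t1), sup_of(t2))
})

test_that("family clades get full support at moderate noise", {
  # 3 families x 3 members at sigma 0.3: the regime where the geometric
  # alphabet retains a clear family signal (see the methods vignette);
  # within-family clades are recovered with >= 95% support
  ds <- small_family_dataset()
  enc <- lapply(ds$structures, encode_structure)
  msa <- progressive_align(enc, gap_open = 5)
  tr <- bootstrap_tree(msa, n_reps = 200, seed = 42)
  labs <- setNames(ds$labels$family, ds$labels$id)
  supports <- numeric(0)
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    lv <- tree_leaves(node)
    if (length(lv) == 3L && length(unique(labs[lv])) == 1L)
      supports <<- c(supports, node$support)
    for (ch in node$children) walk(ch)
  }
  walk(tr)
  expect_length(supports, 3L)
  expect_true(all(supports >= 95))
})
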