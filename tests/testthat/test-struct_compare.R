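test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(13)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  sup0 <- kabsch_superpose(X, X)
  expect_lt(sup0$rmsd, 1e-9)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-8)

  R <- random_rotation_matrix(3)
  t_vec <- c(4, -7, 2)
  Y <- sweep(X %*% t(R), 2, -t_vec)
  sup <- kabsch_superpose(X, Y)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$rotation, R, tolerance = 1e-6)
  expect_equal(apply_superposition(sup, X), Y, tolerance = 1e-8)
  # proper rotation, orthonormal
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(sup$rotation), diag(3), tolerance = 1e-8)

  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch matches a numerical rigid-fit minimization oracle", {
  # fixed asymmetric 5-point configuration with a noisy partner
  X <- matrix(c(0, 0, 0, 3.8, 0, 0, 5.1, 3.2, 0.4, 2.2, 5.0, 2.9,
                -1.3, 2.4, 4.1), 5, 3, byrow = TRUE)
  set.seed(8)
  Y <- sweep(X %*% t(random_rotation_matrix(17)), 2, -c(1, 2, 3)) +
    matrix(rnorm(15, sd = 0.6), 5, 3)
  got <- kabsch_superpose(X, Y)$rmsd
  expect_equal(got, oracle_min_rmsd(X, Y), tolerance = 1e-3)
})

test_that("TM-score definition: self-comparison, d0 floor, norm choice", {
  s <- make_scaffold(21, 40)
  tm_self <- tm_score(s, s)
  expect_equal(as.numeric(tm_self), 1.0, tolerance = 1e-9)
  expect_equal(attr(tm_self, "rmsd"), 0, tolerance = 1e-9)

  # d0 at L_norm = 20: 1.24 * 5^(1/3) - 1.8 ~ 0.32, floored to 0.5
  s20 <- make_scaffold(22, 20)
  expect_equal(attr(tm_score(s20, s20), "d0"), 0.5, tolerance = 1e-12)
  # above the floor the printed formula applies
  s60 <- make_scaffold(23, 60)
  expect_equal(attr(tm_score(s60, s60), "d0"), 1.24 * 45^(1 / 3) - 1.8,
               tolerance = 1e-12)

  # norm = target vs shorter for unequal lengths
  a <- extract_domain(s60, 1, 40)
  corr <- cbind(1:40, 1:40)
  tm_t <- as.numeric(tm_score(a, s60, corr, norm = "target"))
  tm_s <- as.numeric(tm_score(a, s60, corr, norm = "shorter"))
  expect_lt(tm_t, tm_s)  # same distances, larger normalization length

  expect_error(tm_score(s, s, matrix(0, 0, 2)), "empty")
  expect_error(tm_score(s, s, cbind(c(1, 1, 2), c(1, 2, 3))),
               "strictly increasing")
})

test_that("TM-score is 0.5 when all aligned distances equal d0", {
  # Displace every point by exactly d0 along an isotropically random unit
  # direction: at the identity superposition every pair contributes
  # exactly 1/(1+1) = 1/2, and an isotropic field leaves almost no rigid
  # component for the optimizing superposition to exploit, so the score
  # stays close to (and never below) 0.5.
  L <- 40
  s <- make_scaffold(25, L)
  X <- s$ca
  d0 <- attr(tm_score(s, s), "d0")
  set.seed(5)
  U <- matrix(rnorm(3 * L), L, 3)
  U <- U / sqrt(rowSums(U^2))
  tm <- as.numeric(tm_score(X, X + d0 * U, cbind(1:L, 1:L)))
  expect_gte(tm, 0.5 - 1e-9)
  expect_lt(tm, 0.55)
})

test_that("structural alignment handles identity and rigid motion", {
  s <- make_scaffold(41, 50)
  sup <- align_structures(s, s)
  expect_equal(sup$tm_score, 1.0, tolerance = 1e-9)
  expect_equal(sup$correspondence, cbind(1:50, 1:50),
               ignore_attr = TRUE)

  moved <- rigid_move(s, 77)
  sup2 <- align_structures(moved, s)
  expect_equal(sup2$tm_score, 1.0, tolerance = 1e-6)
  expect_lt(sup2$rmsd, 1e-6)
})

test_that("TM-score and RMSD are invariant under rigid motion of inputs", {
  a <- perturb_member(make_scaffold(51, 40), sigma = 1, sub_rate = 0,
                      indel_rate = 0, seed = 5)$structure
  b <- make_scaffold(51, 40)
  ref <- align_structures(a, b)
  for (seed in c(101, 202)) {
    am <- rigid_move(a, seed)
    bm <- rigid_move(b, seed + 7)
    got <- align_structures(am, bm)
    expect_equal(got$tm_score, ref$tm_score, tolerance = 1e-6)
    expect_equal(got$rmsd, ref$rmsd, tolerance = 1e-5)
  }
})

test_that("alignment search matches the exhaustive oracle on tiny chains", {
  set.seed(61)
  for (k in 1:10) {
    la <- sample(4:6, 1)
    lb <- sample(4:6, 1)
    A <- matrix(rnorm(3 * la, sd = 3), la, 3)
    B <- matrix(rnorm(3 * lb, sd = 3), lb, 3)
    got <- align_structures(A, B)$tm_score
    oracle <- oracle_align_exhaustive(A, B)
    expect_equal(got, oracle, tolerance = 1e-9,
                 label = paste("pair", k))
  }
})

test_that("heuristic TM is at least the planted-correspondence TM", {
  tpl <- make_scaffold(71, 60)
  for (k in 1:5) {
    m <- perturb_member(tpl, sigma = 0.5, sub_rate = 0.3, indel_rate = 0,
                        seed = 500 + k)$structure
    planted <- as.numeric(tm_score(m, tpl, cbind(1:60, 1:60)))
    expect_gte(align_structures(m, tpl)$tm_score + 1e-9, planted)
  }
})

test_that("domain extraction follows 1-based inclusive spans", {
  s <- make_scaffold(81, 120)
  full <- extract_domain(s, 1, 120)
  expect_equal(full$ca, s$ca)
  dom <- extract_domain(s, 10, 20)
  expect_equal(length(dom), 11L)
  expect_equal(dom$resno, 1:11)
  expect_equal(dom$ca, s$ca[10:20, ])
  expect_equal(dom$plddt, s$plddt[10:20])
  expect_equal(align_structures(dom, dom)$tm_score, 1.0, tolerance = 1e-9)
  expect_error(extract_domain(s, 0, 10), "out of range")
  expect_error(extract_domain(s, 100, 130), "out of range")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  s <- make_scaffold(91, 40)
  twin <- protein_structure("twin", s$ca, aa = s$aa, plddt = s$plddt)
  sm <- similarity_matrix(list(s, twin))
  expect_equal(sm$values["scaffold91", "twin"], 1.0, tolerance = 1e-9)

  ds <- small_family_dataset()
  dom <- ds$structures[c(1, 2, 4, 5, 7, 8)]
  fam <- setNames(ds$labels$family, ds$labels$id)
  sm2 <- similarity_matrix(dom, families = fam)
  v <- sm2$values
  expect_equal(v, t(v), tolerance = 1e-9)
  expect_equal(unname(diag(v)), rep(1, 6))
  f <- sm2$family[rownames(v)]
  same <- outer(f, f, "==") & upper.tri(v)
  expect_gt(mean(v[same]), mean(v[!same & upper.tri(v)]))

  expect_error(similarity_matrix(list(s, s)), "duplicate")
})
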