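# Shared fixtures. Expensive objects are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small 3-family dataset at moderate noise: the regime where the structural
# alphabet retains family signal (see the methods vignette)
small_family_dataset <- function() {
  fixture("small_family", function() {
    make_family_dataset(family_config(
      n_families = 3L, members_per_family = 3L, chain_length = 80L,
      coord_noise_sigma = 0.3, seed = 777L))
  })
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal hand-written PDB with altloc duplicates on residue 2
pdb_altloc_fixture <- function(path) {
  lines <- c(
    "ATOM      1  CA  MET A   1       0.000   0.000   0.000  1.00 90.00           C",
    "ATOM      2  CA ALYS A   2       3.800   0.000   0.000  1.00 80.00           C",
    "ATOM      3  CA BLYS A   2       9.900   9.900   9.900  1.00 10.00           C",
    "ATOM      4  CA  VAL A   3       7.600   1.000   0.000  1.00 70.00           C",
    "END")
  writeLines(lines, path)
  path
}

# place a 4th CA at given internal coordinates after three collinear-free
# points; independent reimplementation used to build encode_structure probes
place_fourth <- function(p1, p2, p3, r, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180
  ta <- tau_deg * pi / 180
  bc <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  ab <- p2 - p1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ta), -r * sin(th) * sin(ta))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(s, seed) {
  R <- random_rotation_matrix(seed)
  set.seed(seed + 1L)
  t_vec <- runif(3, -30, 30)
  ca <- sweep(s$ca %*% t(R), 2, -t_vec)
  protein_structure(s$id, ca, aa = s$aa, resno = s$resno, plddt = s$plddt)
}
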