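# Independent oracles used to validate the package's algorithms. Each is a
# from-scratch implementation (different algorithmic route than the package)
# kept deliberately simple and slow.

# ---- global alignment (free terminal gaps) by exhaustive path enumeration --
# match +1, mismatch -1, an internal gap run of length k costs 5 + k;
# leading/trailing gap columns are free. Returns the optimal score and the
# (identity, coverage) statistics of every co-optimal alignment.
oracle_global_alignment <- function(a, b) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  na <- length(A)
  nb <- length(B)
  best <- list(score = -Inf, stats = list())
  score_cols <- function(ca, cb) {
    pairm <- ca != "-" & cb != "-"
    if (!any(pairm)) return(NULL)
    ncols <- length(ca)
    # free terminal gaps are single-sided: a maximal initial (final) run of
    # gap columns all lying in the same sequence costs nothing, exactly as
    # in ends-free Needleman-Wunsch; every other gap run is charged
    lead <- 0L
    if (ca[1L] == "-" || cb[1L] == "-") {
      gap_in_a <- ca[1L] == "-"
      while (lead < ncols &&
             ((gap_in_a && ca[lead + 1L] == "-") ||
                (!gap_in_a && cb[lead + 1L] == "-"))) lead <- lead + 1L
    }
    trail <- 0L
    if (ca[ncols] == "-" || cb[ncols] == "-") {
      gap_in_a <- ca[ncols] == "-"
      while (trail < ncols - lead &&
             ((gap_in_a && ca[ncols - trail] == "-") ||
                (!gap_in_a && cb[ncols - trail] == "-"))) trail <- trail + 1L
    }
    mid <- seq.int(lead + 1L, ncols - trail)
    sc <- 0
    run <- 0
    for (q in mid) {
      if (ca[q] == "-" || cb[q] == "-") {
        run <- run + 1
      } else {
        if (run > 0) sc <- sc - (5 + run)
        run <- 0
        sc <- sc + if (ca[q] == cb[q]) 1 else -1
      }
    }
    if (run > 0) sc <- sc - (5 + run)
    # statistics over the region between the first and last aligned pair
    first <- which(pairm)[1L]
    last <- max(which(pairm))
    ra <- ca[first:last]
    rb <- cb[first:last]
    list(score = sc,
         identity = sum(ra == rb & ra != "-") / length(ra),
         coverage_a = sum(ra != "-") / na,
         coverage_b = sum(rb != "-") / nb)
  }
  walk <- function(i, j, ca, cb) {
    if (i > na && j > nb) {
      st <- score_cols(ca, cb)
      if (is.null(st)) return(invisible())
      if (st$score > best$score + 1e-12) {
        best$score <<- st$score
        best$stats <<- list(st)
      } else if (abs(st$score - best$score) <= 1e-12) {
        best$stats[[length(best$stats) + 1L]] <<- st
      }
      return(invisible())
    }
    if (i <= na && j <= nb) walk(i + 1L, j + 1L, c(ca, A[i]), c(cb, B[j]))
    if (i <= na) walk(i + 1L, j, c(ca, A[i]), c(cb, "-"))
    if (j <= nb) walk(i, j + 1L, c(ca, "-"), c(cb, B[j]))
    invisible()
  }
  walk(1L, 1L, character(0), character(0))
  # the empty alignment (everything in free terminal gaps) always scores 0
  empty_stats <- list(score = 0, identity = NaN, coverage_a = 0,
                      coverage_b = 0)
  if (best$score < 0 - 1e-12) {
    best <- list(score = 0, stats = list(empty_stats))
  } else if (abs(best$score) <= 1e-12) {
    best$stats[[length(best$stats) + 1L]] <- empty_stats
  }
  best
}

# does the implementation's (identity, coverage) belong to a co-optimal
# alignment reported by the oracle? (NaN identity = empty alignment)
oracle_stats_match <- function(oracle, got) {
  any(vapply(oracle$stats, function(st) {
    if (is.nan(st$identity) || is.nan(got$identity))
      return(is.nan(st$identity) && is.nan(got$identity))
    abs(st$identity - got$identity) < 1e-9 &&
      abs(st$coverage_a - got$coverage_a) < 1e-9 &&
      abs(st$coverage_b - got$coverage_b) < 1e-9
  }, TRUE))
}

# ---- exhaustive monotone-correspondence structural alignment ---------------
oracle_align_exhaustive <- function(A, B, norm = "target") {
  ca <- if (inherits(A, "ProteinStructure")) A$ca else A
  cb <- if (inherits(B, "ProteinStructure")) B$ca else B
  la <- nrow(ca)
  lb <- nrow(cb)
  best <- -Inf
  for (k in 3:min(la, lb)) {
    ia_all <- utils::combn(la, k)
    ib_all <- utils::combn(lb, k)
    for (u in seq_len(ncol(ia_all))) {
      for (v in seq_len(ncol(ib_all))) {
        tm <- tm_score(ca, cb, cbind(ia_all[, u], ib_all[, v]), norm = norm)
        if (tm > best) best <- as.numeric(tm)
      }
    }
  }
  best
}

# ---- brute-force UPGMA: recompute all average linkages from scratch --------
oracle_upgma <- function(d) {
  labs <- rownames(d)
  clusters <- lapply(labs, function(l) l)     # leaf-label vectors
  nodes <- lapply(labs, function(l) list(height = 0, label = l,
                                         children = NULL))
  avg_link <- function(g1, g2) mean(d[g1, g2, drop = FALSE])
  while (length(clusters) > 1L) {
    bi <- bj <- NA_integer_
    bd <- Inf
    for (x in seq_along(clusters)) {
      for (y in seq_along(clusters)) {
        if (y <= x) next
        v <- avg_link(clusters[[x]], clusters[[y]])
        take <- FALSE
        if (is.na(bi) || v < bd - 1e-12) {
          take <- TRUE
        } else if (v <= bd + 1e-12) {
          cur <- sort(c(min(clusters[[x]]), min(clusters[[y]])))
          old <- sort(c(min(clusters[[bi]]), min(clusters[[bj]])))
          if (cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2]))
            take <- TRUE
        }
        if (take) {
          bd <- min(bd, v)
          bi <- x
          bj <- y
        }
      }
    }
    nodes[[bi]] <- list(height = bd / 2, label = NULL,
                        children = list(nodes[[bi]], nodes[[bj]]))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    nodes[[bj]] <- NULL
    clusters[[bj]] <- NULL
  }
  nodes[[1L]]
}

# clade/height signature for topology comparison, independent of child order
tree_signature <- function(node) {
  out <- character(0)
  leaves_of <- function(n) {
    if (is.null(n$children)) return(n$label)
    unlist(lapply(n$children, leaves_of))
  }
  walk <- function(n) {
    if (is.null(n$children)) return(invisible())
    out[[length(out) + 1L]] <<- paste0(paste(sort(leaves_of(n)),
                                             collapse = ","),
                                       "@", sprintf("%.9f", n$height))
    for (ch in n$children) walk(ch)
    invisible()
  }
  walk(node)
  sort(out)
}

# ---- folding oracles --------------------------------------------------------
.o_weight <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
  0
}

# general nested folding: Nussinov-style "pair j with k" decomposition
# (a different recursion than the package's drop-left/drop-right/bifurcate)
oracle_fold_general <- function(window, min_loop = 3L) {
  chars <- strsplit(toupper(window), "")[[1L]]
  n <- length(chars)
  memo <- array(NA_real_, dim = c(n + 1L, n + 1L))
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      w <- .o_weight(chars[k], chars[j])
      if (w > 0) {
        left <- if (k > i) rec(i, k - 1L) else 0
        best <- max(best, left + w + rec(k + 1L, j - 1L))
      }
    }
    memo[i, j] <<- best
    best
  }
  if (n < 2L) return(0)
  rec(1L, n)
}

# hairpin-topology folding by explicit enumeration of nested pair chains
oracle_fold_hairpin <- function(window, min_loop = 3L) {
  chars <- strsplit(toupper(window), "")[[1L]]
  n <- length(chars)
  best <- 0
  rec <- function(i, j, acc) {
    if (acc > best) best <<- acc
    if (j - i < min_loop + 1L) return(invisible())
    for (a in i:(j - min_loop - 1L)) {
      for (b in (a + min_loop + 1L):j) {
        w <- .o_weight(chars[a], chars[b])
        if (w > 0) rec(a + 1L, b - 1L, acc + w)
      }
    }
    invisible()
  }
  rec(1L, n, 0)
  best
}

# ---- inverted repeats by brute-force placement enumeration -----------------
oracle_find_irs <- function(seq, min_arm = 4L, max_spacer = 10L,
                            max_mismatch = 1L) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  cand <- list()
  for (arm in min_arm:(n %/% 2L)) {
    for (sp in 0:max_spacer) {
      span <- 2L * arm + sp
      if (span > n) next
      for (s in seq_len(n - span + 1L)) {
        l <- chars[s:(s + arm - 1L)]
        r <- chars[(s + arm + sp):(s + span - 1L)]
        mm <- sum(comp[l] != rev(r))
        if (mm <= max_mismatch) {
          cand[[length(cand) + 1L]] <-
            c(s, s + arm - 1L, s + arm + sp, s + span - 1L, arm, sp, mm)
        }
      }
    }
  }
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm = integer(), spacer_len = integer(),
                      mismatches = integer())
  if (length(cand) == 0L) return(empty)
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 5L], m[, 1L], m[, 3L]), , drop = FALSE]
  kept <- matrix(0L, 0L, 7L)
  for (k in seq_len(nrow(m))) {
    if (nrow(kept) == 0L ||
        !any(kept[, 1L] <= m[k, 1L] & kept[, 4L] >= m[k, 4L] &
               kept[, 5L] > m[k, 5L])) {
      kept <- rbind(kept, m[k, ])
    }
  }
  data.frame(left_start = kept[, 1L], left_end = kept[, 2L],
             right_start = kept[, 3L], right_end = kept[, 4L],
             arm = kept[, 5L], spacer_len = kept[, 6L],
             mismatches = kept[, 7L])
}

# ---- rigid-fit oracle: numerical minimization over Euler angles ------------
oracle_min_rmsd <- function(X, Y, n_starts = 12L) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Xc %*% t(rot(ang)) - Yc)^2)))
  set.seed(4242)
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    fit2 <- stats::optim(fit$par, obj, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, fit$value, fit2$value)
  }
  best
}
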