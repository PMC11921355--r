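# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (grid search, exhaustive path enumeration) and share no
# code with the implementation paths they check.

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cg <- cos(g); sg <- sin(g)
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

# Brute-force rotation search for the minimal superposition RMSD: coarse
# Euler-angle grid followed by nested local refinements. Translation is
# optimal for any fixed rotation when both sets are centred.
oracle_min_rmsd <- function(P, Q, coarse_step = 15, refine_levels = 3) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rmsd_at <- function(a, b, g) {
    R <- euler_rotation(a, b, g)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  step0 <- coarse_step * pi / 180
  cand <- list()
  for (a in seq(0, 2 * pi - step0 / 2, by = step0))
    for (b in seq(0, pi, by = step0))
      for (g in seq(0, 2 * pi - step0 / 2, by = step0))
        cand[[length(cand) + 1]] <- c(rmsd_at(a, b, g), a, b, g)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  # refine around each of the best coarse candidates (local basins can tie);
  # finish each with a derivative-free polish of the same objective so the
  # oracle is not limited by axis-aligned grid moves near gimbal lock
  best_val <- Inf
  for (ci in seq_len(min(5, nrow(cand)))) {
    best <- cand[ci, 2:4]
    val <- cand[ci, 1]
    step <- step0
    for (lev in seq_len(refine_levels)) {
      step <- step / 3
      grid <- seq(-3, 3) * step
      for (da in grid) for (db in grid) for (dg in grid) {
        v <- rmsd_at(best[1] + da, best[2] + db, best[3] + dg)
        if (v < val) { val <- v; best <- best + c(da, db, dg) }
      }
    }
    polish <- stats::optim(best, function(p) rmsd_at(p[1], p[2], p[3]),
                           method = "Nelder-Mead",
                           control = list(reltol = 1e-14, maxit = 2000))
    best_val <- min(best_val, val, polish$value)
  }
  best_val
}

# Exhaustive enumeration of all global alignment paths under affine gaps
# (a gap of length L costs open + L * extend), Needleman-Wunsch convention
# with penalised end gaps -- matches the scoring the package delegates to.
oracle_alignment_score <- function(a, b, S, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, sc, prev) {
    if (i == n && j == m) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, sc + S[av[i + 1], bv[j + 1]], "d")
    if (i < n)
      rec(i + 1, j, sc - extend - if (prev == "u") 0 else open, "u")
    if (j < m)
      rec(i, j + 1, sc - extend - if (prev == "l") 0 else open, "l")
  }
  rec(0, 0, 0, "d")
  best
}

random_point_set <- function(n, spread = 3) {
  matrix(stats::rnorm(n * 3, sd = spread), n, 3)
}

# convenience: measured His/Tyr distances of a synthetic complex, via the
# package's own perception + measurement stages
measure_synthetic <- function(model) {
  m <- measure_complex(model, his_res = 226, tyr_res = 280)
  c(his = m$distances$distance[m$distances$residue == "HIS"],
    tyr = m$distances$distance[m$distances$residue == "TYR"])
}
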