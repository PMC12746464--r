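# Shared fixtures. All built in code; seeds fixed so every run sees the same
# study conditions.

det_at <- function(space, i) {
  structure(list(alpha = space$alpha[i], beta = space$beta[i]),
            class = "determinant")
}

# Worked three-subspace model: 3 electrons, local {N_min = [0,0,1],
# N_max = [2,2,2]} over three 2-orbital subspaces.
table1_gas <- function() {
  gas_partition(list(1:2, 3:4, 5:6), n_min = c(0, 0, 1), n_max = c(2, 2, 2),
                n_elec_active = 3)
}

# SplitGAS study fixture: CAS(6,6)-sized random integrals, three 2-orbital
# subspaces, T unconstrained (= full CAS), MRCI-flavored P (hole count in G1
# <= 1, particles in G3 <= 1).
splitgas_fixture <- function(seed = 5) {
  ints <- make_random_integrals(6, 6, seed = seed, scale = 0.3)
  gas <- gas_partition(list(1:2, 3:4, 5:6), c(0, 0, 0), c(4, 4, 4), 6)
  tab <- enumerate_supergroups(gas)
  pgas <- gas_partition(list(1:2, 3:4, 5:6), c(3, 0, 0), c(4, 4, 1), 6)
  part <- build_ip_vector(tab, pgas)
  list(ints = ints, gas = gas, table = tab, part = part)
}

# CAS(4,4) SplitGAS fixture whose SD-basis ground vector is visibly
# spin-contaminated (needs >= 4 open shells; see methods vignette).
contamination_fixture <- function() {
  ints <- make_random_integrals(4, 4, seed = 31, scale = 0.5)
  gas <- gas_partition(list(1:2, 3:4), c(0, 0), c(4, 4), 4)
  tab <- enumerate_supergroups(gas)
  pgas <- gas_partition(list(1:2, 3:4), c(3, 0), c(4, 1), 4)
  part <- build_ip_vector(tab, pgas)
  list(ints = ints, gas = gas, table = tab, part = part)
}

# CAS(2,2) split: P = doubly occupied first orbital.
cas22_split <- function(ints) {
  gas <- gas_partition(list(1L, 2L), c(0, 0), c(2, 2), 2)
  tab <- enumerate_supergroups(gas)
  pgas <- gas_partition(list(1L, 2L), c(2, 0), c(2, 0), 2)
  part <- build_ip_vector(tab, pgas)
  space <- enumerate_space(ints, 1, 1, gas)
  list(gas = gas, table = tab, part = part, space = space)
}

# Random small GAS instance for property loops.
random_gas_instance <- function() {
  k <- sample(2:4, 1)
  sizes <- sample(1:3, k, replace = TRUE)
  orbs <- split(seq_len(sum(sizes)), rep(seq_len(k), sizes))
  N <- sample(1:min(6, 2 * sum(sizes) - 1), 1)
  cap <- 2L * sizes
  n_min <- pmin(cap, sapply(cap, function(cp) sample(0:min(cp, N), 1)))
  n_max <- pmin(cap, n_min + sapply(cap - n_min, function(r) sample(0:r, 1)))
  # keep feasible: require some composition to exist
  if (sum(n_min) > N || sum(n_max) < N) return(NULL)
  gas_partition(orbs, n_min, n_max, N)
}

# Distance from E to the nearest true root of the downfolded self-consistency
# f(E*) = E*. The raw gap |f(E) - E| is amplified by the slope of the
# downfolded eigenvalue (f' = -sum_a |<v|H|a>|^2 / (E - H_aa)^2), so the
# Newton-corrected distance |f(E) - E| / |f'(E) - 1| is the well-conditioned
# measure of how accurately E solves the equation.
downfold_root_distance <- function(H, in_p, E) {
  df <- splitgas::downfold(H, in_p, E)
  eg <- eigen(df$matrix, symmetric = TRUE)
  k <- which.min(abs(eg$values - E))
  f <- eg$values[k]
  v <- eg$vectors[, k]
  p <- which(in_p); q <- which(!in_p)
  fp <- 0
  if (length(q)) {
    Hpq <- as.matrix(H[p, q, drop = FALSE])
    cv <- as.numeric(crossprod(Hpq, v))
    fp <- -sum(cv^2 / (E - diag(as.matrix(H))[q])^2)
  }
  abs((f - E) / (fp - 1))
}

# Probability mass of rejected draws (zero-weight rows or occupied particle
# orbitals), enumerated exactly from the alias tables.
rejection_mass <- function(parent, sg, tabs) {
  M <- tabs$pm$M
  occ <- splitgas:::occ_spin_orbs(parent$alpha, parent$beta, M)
  N <- length(occ)
  pd <- tabs$p_dbl[sg]
  rej <- 0
  if (N >= 2) {
    prs <- utils::combn(occ, 2)
    for (cc in seq_len(ncol(prs))) {
      hp <- splitgas:::pair_index(prs[1, cc], prs[2, cc])
      r <- tabs$dbl_rowid[sg, hp]
      if (r == 0) { rej <- rej + pd / choose(N, 2); next }
      for (k in seq_len(tabs$dbl$K[r])) {
        pp <- tabs$dbl$support[r, k]
        if (splitgas:::so_occupied(parent, tabs$pm$lo[pp], M) ||
            splitgas:::so_occupied(parent, tabs$pm$hi[pp], M))
          rej <- rej + pd / choose(N, 2) * tabs$dbl$wnorm[r, k]
      }
    }
  }
  for (I in occ) {
    r <- tabs$sng_rowid[sg, (I - 1L) %% M + 1L]
    if (r == 0) { rej <- rej + (1 - pd) / N; next }
    for (k in seq_len(tabs$sng$K[r])) {
      A <- tabs$sng$support[r, k] + if (I > M) M else 0L
      if (splitgas:::so_occupied(parent, A, M))
        rej <- rej + (1 - pd) / N * tabs$sng$wnorm[r, k]
    }
  }
  rej
}

# Cumulative constraint set derived from local extremes (running sums of the
# feasible minima/maxima).
derive_cumulative <- function(gas) {
  N <- gas$n_elec_active
  k <- gas$k
  cmin <- cumsum(gas$n_min); cmax <- cumsum(gas$n_max)
  tail_max <- rev(cumsum(rev(gas$n_max))); tail_min <- rev(cumsum(rev(gas$n_min)))
  nmin <- pmax(cmin, N - c(tail_max[-1], 0))
  nmax <- pmin(cmax, N - c(tail_min[-1], 0))
  nmin[k] <- N; nmax[k] <- N
  gas_partition(gas$subspaces, nmin, nmax, N, flavor = "cumulative")
}
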