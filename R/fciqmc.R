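# Imaginary-time walker dynamics. The CI vector is carried as signed real
# walker weights over the enumerated (GAS-constrained) space; each step runs
# excitation generation (PCHB, supergroup-constrained), spawning with
# acceptance Delta_tau |K_ij| / p_gen, death/cloning with Delta_tau (K_jj -
# S), and annihilation by signed accumulation. All per-walker work is
# vectorized over spawn attempts. K = H - I * E_ref with E_ref the reference
# determinant's diagonal.

#' FCIQMC run configuration
#'
#' @param dtau Imaginary-time step (1/Hartree); `NULL` picks
#'   `0.5 / (max(K_jj) - min(K_jj))` and shrinks it during equilibration
#'   whenever a single spawn exceeds magnitude 1.
#' @param target_walkers Total walker weight at which shift control engages.
#' @param shift_damping Damping zeta of the shift update.
#' @param shift_period Steps A between shift updates.
#' @param initiator_threshold Walker weight n_add a parent needs before its
#'   spawns may open unoccupied determinants (core parents are exempt).
#' @param seed RNG seed; identical seeds give identical runs.
#' @param n_steps Number of imaginary-time steps.
#' @param burnin Steps discarded by summary estimators (default `n_steps / 4`).
#' @param core_size Semistochastic core size (0 disables).
#' @param mode `"full"`, `"gas"`, or `"splitgas"`.
#' @param init_walkers Initial weight on the reference determinant.
#' @return A `fciqmc_config` list.
#' @export
fciqmc_config <- function(dtau = NULL, target_walkers = 5e4,
                          shift_damping = 0.05, shift_period = 5L,
                          initiator_threshold = 3, seed = 1L,
                          n_steps = 2000L, burnin = NULL, core_size = 0L,
                          mode = c("full", "gas", "splitgas"),
                          init_walkers = 10) {
  mode <- match.arg(mode)
  stopifnot(is.null(dtau) || dtau > 0, target_walkers > 0,
            shift_period >= 1, initiator_threshold >= 0, n_steps >= 1)
  if (is.null(burnin)) burnin <- n_steps %/% 4L
  structure(list(dtau = dtau, target_walkers = target_walkers,
                 shift_damping = shift_damping,
                 shift_period = as.integer(shift_period),
                 initiator_threshold = initiator_threshold,
                 seed = as.integer(seed), n_steps = as.integer(n_steps),
                 burnin = as.integer(burnin), core_size = as.integer(core_size),
                 mode = mode, init_walkers = init_walkers),
            class = "fciqmc_config")
}

# Trivial one-subspace partition (full CI as a single GAS).
full_gas <- function(ints) {
  gas_partition(list(seq_len(ints$n_orb)), n_min = ints$n_elec,
                n_max = ints$n_elec, n_elec_active = ints$n_elec,
                flavor = "local")
}

#' Initialize FCIQMC state
#'
#' Enumerates the space, builds the supergroup-constrained PCHB tables and
#' semistochastic core, and places all initial walker weight on the
#' lowest-diagonal allowed determinant (restricted to P in SplitGAS mode); the
#' reference energy `E_ref` is fixed to that diagonal.
#'
#' @param ints An [integral_set()].
#' @param config A [fciqmc_config()].
#' @param gas A [gas_partition()] (required for modes `"gas"`/`"splitgas"`;
#'   a single all-orbital subspace is used for `"full"`).
#' @param part A `split_partitioning` (required for mode `"splitgas"`).
#' @return An opaque `fciqmc_state` list; advance it with [fciqmc_step()] or
#'   let [run_fciqmc()] drive the whole dynamics.
#' @export
init_fciqmc <- function(ints, config, gas = NULL, part = NULL) {
  if (config$mode == "full" && is.null(gas)) gas <- full_gas(ints)
  stopifnot(!is.null(gas))
  if (config$mode == "splitgas") stopifnot(inherits(part, "split_partitioning"))
  set.seed(config$seed)
  n_alpha <- (ints$n_elec + ints$ms2) %/% 2L
  n_beta <- ints$n_elec - n_alpha
  space <- enumerate_space(ints, n_alpha, n_beta, gas = gas)
  d <- space_size(space)
  diagv <- space_diagonal(space, ints)
  ip_det <- if (config$mode == "splitgas") part$ip[space$sg] else rep(TRUE, d)
  ref_pool <- if (config$mode == "splitgas") which(ip_det) else seq_len(d)
  ref <- ref_pool[which.min(diagv[ref_pool])]
  E_ref <- diagv[ref]
  dbl <- build_double_weights(ints)
  sng <- build_single_weights(ints)
  tables <- constrain_tables(dbl, sng, space$table, gas,
                             part = if (config$mode == "splitgas") part else NULL)
  # reference row of the (effective) Hamiltonian for the projected energy;
  # the reference sits in P, so effective and full couplings coincide
  hrow <- vapply(seq_len(d), function(j)
    if (j == ref) 0 else sc_element(space$alpha[ref], space$beta[ref],
                                    space$alpha[j], space$beta[j], ints),
    numeric(1))
  # occupied spin orbitals per determinant (all rows same length)
  M <- ints$n_orb
  N <- ints$n_elec
  OCC <- matrix(0L, d, N)
  for (i in seq_len(d))
    OCC[i, ] <- occ_spin_orbs(space$alpha[i], space$beta[i], M)
  is_core <- rep(FALSE, d)
  Hcore <- NULL; core_idx <- integer(0)
  if (config$core_size > 0L) {
    core_idx <- order(diagv)[seq_len(min(config$core_size, d))]
    is_core[core_idx] <- TRUE
    Hcore <- core_hamiltonian(space, ints, core_idx,
                              part = if (config$mode == "splitgas") part else NULL)
  }
  dtau <- config$dtau
  if (is.null(dtau)) dtau <- 0.5 / max(diff(range(diagv)), 1e-8)
  pop <- numeric(d)
  pop[ref] <- config$init_walkers
  list(space = space, ints = ints, config = config, gas = gas, part = part,
       bitv = bitwShiftL(1L, seq_len(M) - 1L),
       diag = diagv, Kdiag = diagv - E_ref, ref = ref, E_ref = E_ref,
       hrow = hrow, tables = tables, OCC = OCC, ip_det = ip_det,
       is_core = is_core, core_idx = core_idx, Hcore = Hcore,
       pop = pop, shift = 0, engaged = FALSE, step_i = 0L, dtau = dtau,
       nw_prev = config$init_walkers,
       audit = c(gas_violations = 0L, qq_spawns = 0L),
       stats = list())
}

# Core Hamiltonian: exact elements among core members, with the OR-gate mask
# in SplitGAS mode. Dense core_size x core_size.
core_hamiltonian <- function(space, ints, core_idx, part = NULL) {
  nc <- length(core_idx)
  H <- matrix(0, nc, nc)
  for (a in seq_len(nc)) {
    i <- core_idx[a]
    H[a, a] <- sc_diagonal(space$alpha[i], space$beta[i], ints)
    if (a < nc) for (b in (a + 1L):nc) {
      j <- core_idx[b]
      ok <- is.null(part) || or_gate(space$sg[j], space$sg[i], part)
      if (ok) {
        v <- sc_element(space$alpha[i], space$beta[i],
                        space$alpha[j], space$beta[j], ints)
        H[a, b] <- H[b, a] <- v
      }
    }
  }
  H
}

#' Shift (population-control) update
#'
#' `S <- S - zeta / (A dtau) * log(Nw_now / Nw_prev)`, applied every `A` steps
#' once the target walker number has been exceeded; before engagement the
#' shift is held at zero.
#'
#' @param shift Current shift (Hartree).
#' @param nw_now,nw_prev Total walker weight now and one period ago.
#' @param zeta Damping.
#' @param period Steps A between updates.
#' @param dtau Time step.
#' @return Updated shift.
#' @export
update_shift <- function(shift, nw_now, nw_prev, zeta, period, dtau) {
  shift - zeta / (period * dtau) * log(nw_now / max(nw_prev, .Machine$double.xmin))
}

#' Advance the walker population by one imaginary-time step
#'
#' Runs excitation generation, spawning, death/cloning and annihilation (plus
#' the deterministic core update when a semistochastic core is configured),
#' appends a per-step record, and updates the shift on schedule.
#'
#' @param st State from [init_fciqmc()].
#' @return The advanced state.
#' @export
fciqmc_step <- function(st) {
  cfg <- st$config
  dtau <- st$dtau
  pop <- st$pop
  d <- length(pop)
  M <- st$ints$n_orb
  N <- st$ints$n_elec
  tables <- st$tables
  occ_idx <- which(pop != 0)
  w <- pop[occ_idx]
  natt <- ceiling(abs(w))
  parents <- rep.int(occ_idx, natt)
  n_att_tot <- length(parents)
  pw <- rep.int(abs(w) / pmax(natt, 1L), natt)
  psign <- rep.int(sign(w), natt)
  sgp <- st$space$sg[parents]

  spawn_idx <- integer(0); spawn_val <- numeric(0)
  n_spawned <- 0L; max_spawn <- 0
  if (n_att_tot > 0L && N >= 1L) {
    # supergroups with no outgoing weight at all (isolated classes, e.g. a
    # purely diagonal Hamiltonian) simply never propose
    live <- !is.na(tables$p_dbl[sgp])
    parents <- parents[live]; pw <- pw[live]; psign <- psign[live]
    sgp <- sgp[live]
    n_live <- length(parents)
    is_dbl <- if (n_live) stats::runif(n_live) < tables$p_dbl[sgp] else logical(0)
    if (N < 2L) is_dbl[] <- FALSE

    res <- list()
    if (any(is_dbl))
      res$d <- propose_doubles(st, parents[is_dbl], sgp[is_dbl])
    if (any(!is_dbl))
      res$s <- propose_singles(st, parents[!is_dbl], sgp[!is_dbl])
    att <- list(
      parent = c(if (any(is_dbl)) parents[is_dbl], if (any(!is_dbl)) parents[!is_dbl]),
      pw = c(if (any(is_dbl)) pw[is_dbl], if (any(!is_dbl)) pw[!is_dbl]),
      psign = c(if (any(is_dbl)) psign[is_dbl], if (any(!is_dbl)) psign[!is_dbl]),
      child = c(res$d$child, res$s$child),
      pgen = c(res$d$pgen, res$s$pgen),
      K = c(res$d$K, res$s$K))
    st$audit["gas_violations"] <- st$audit["gas_violations"] +
      sum(res$d$viol, res$s$viol)
    ok <- !is.na(att$child)
    if (any(ok)) {
      child <- att$child[ok]
      # audit: every spawn target must satisfy T constraints (in-space by
      # construction) and must not couple two distinct Q determinants
      if (cfg$mode == "splitgas") {
        qq <- !st$ip_det[child] & !st$ip_det[att$parent[ok]]
        st$audit["qq_spawns"] <- st$audit["qq_spawns"] + sum(qq)
      }
      ws <- dtau * abs(att$K[ok]) / att$pgen[ok] * att$pw[ok]
      ssign <- -sign(att$K[ok]) * att$psign[ok]
      # suppress stochastic core-to-core events (handled deterministically)
      keep <- !(st$is_core[att$parent[ok]] & st$is_core[child])
      # initiator rule: spawns opening an unoccupied, non-core determinant
      # are kept only if the parent is populated beyond n_add (or is core)
      unocc <- pop[child] == 0 & !st$is_core[child]
      weak <- abs(pop[att$parent[ok]]) < cfg$initiator_threshold &
        !st$is_core[att$parent[ok]]
      keep <- keep & !(unocc & weak)
      if (any(keep)) {
        ws <- ws[keep]; ssign <- ssign[keep]; child <- child[keep]
        max_spawn <- max(ws)
        frac <- ws < 1
        u <- stats::runif(length(ws))
        ws[frac] <- (u[frac] < ws[frac]) * 1
        live <- ws > 0
        n_spawned <- sum(live)
        if (any(live)) {
          agg <- rowsum(ssign[live] * ws[live], child[live])
          spawn_idx <- as.integer(rownames(agg))
          spawn_val <- agg[, 1]
        }
      }
    }
  }

  # death / cloning (stochastic part; core handled deterministically)
  dpop <- numeric(d)
  stoch <- occ_idx[!st$is_core[occ_idx]]
  dpop[stoch] <- -dtau * (st$Kdiag[stoch] - st$shift) * pop[stoch]
  if (length(st$core_idx)) {
    nc <- pop[st$core_idx]
    dpop[st$core_idx] <- -dtau * (as.numeric(st$Hcore %*% nc) -
                                    (st$E_ref + st$shift) * nc)
  }
  n_died <- sum(abs(dpop[stoch]))

  # annihilation: signed accumulation
  pop <- pop + dpop
  if (length(spawn_idx)) pop[spawn_idx] <- pop[spawn_idx] + spawn_val
  # drop numerically dead entries, but never core members
  tiny <- abs(pop) < 1e-12 & !st$is_core
  pop[tiny] <- 0

  st$pop <- pop
  st$step_i <- st$step_i + 1L
  nw <- sum(abs(pop))
  if (!st$engaged && nw >= cfg$target_walkers) {
    st$engaged <- TRUE
    st$nw_prev <- nw
    # seed the shift at the instantaneous projected correlation energy so the
    # population settles near the target instead of overshooting while the
    # damped update catches up
    if (pop[st$ref] != 0) {
      e_inst <- sum(st$hrow * pop) / pop[st$ref]
      if (is.finite(e_inst) && e_inst < 0) st$shift <- e_inst
    }
  } else if (st$engaged && st$step_i %% cfg$shift_period == 0L) {
    st$shift <- update_shift(st$shift, nw, st$nw_prev, cfg$shift_damping,
                             cfg$shift_period, dtau)
    st$nw_prev <- nw
  }
  # equilibration-phase time-step control: genuine blooms (single spawns far
  # above unit weight) shrink the step; occasional spawns slightly above 1
  # are normal for real-weighted walkers and are left alone
  if (st$step_i <= cfg$burnin && is.null(cfg$dtau) && max_spawn > 3)
    st$dtau <- st$dtau * 0.95

  e_num <- sum(st$hrow * pop)
  e_den <- pop[st$ref]
  eproj <- if (e_den != 0) st$E_ref + e_num / e_den else NA_real_
  st$stats[[st$step_i]] <- c(
    step = st$step_i, shift = st$shift, engaged = as.numeric(st$engaged),
    e_proj = eproj, e_num = e_num, e_den = e_den, n_walkers = nw,
    n_attempts = n_att_tot, n_spawned = n_spawned,
    acceptance = if (n_att_tot > 0) n_spawned / n_att_tot else 0,
    n_died = n_died, dtau = st$dtau, ref_weight = pop[st$ref])
  st
}

# Vectorized PCHB double proposals. Returns child (space index or NA), pgen,
# and the signed Hamiltonian element K for accepted moves.
propose_doubles <- function(st, parents, sgp) {
  n <- length(parents)
  tables <- st$tables
  pm <- tables$pm
  M <- pm$M
  N <- ncol(st$OCC)
  k1 <- floor(stats::runif(n) * N) + 1L
  k2 <- floor(stats::runif(n) * (N - 1L)) + 1L
  k2 <- k2 + (k2 >= k1)
  I <- st$OCC[cbind(parents, k1)]
  J <- st$OCC[cbind(parents, k2)]
  lo <- pmin(I, J); hi <- pmax(I, J)
  hp <- pair_index(lo, hi)
  r <- tables$dbl_rowid[cbind(sgp, hp)]
  child <- rep(NA_integer_, n); pgen <- numeric(n); K <- numeric(n)
  ok <- r > 0L
  if (!any(ok)) return(list(child = child, pgen = pgen, K = K))
  rok <- r[ok]
  Kr <- tables$dbl$K[rok]
  cell <- floor(stats::runif(sum(ok)) * Kr) + 1L
  u2 <- stats::runif(sum(ok))
  rc <- cbind(rok, cell)
  take <- u2 <= tables$dbl$prob[rc]
  pos <- cell
  if (!all(take)) pos[!take] <- tables$dbl$alias[rc[!take, , drop = FALSE]]
  rp <- cbind(rok, pos)
  pp <- tables$dbl$support[rp]
  pg <- tables$p_dbl[sgp[ok]] / choose(N, 2) * tables$dbl$wnorm[rp]
  A <- pm$lo[pp]; B <- pm$hi[pp]
  av <- st$space$alpha[parents[ok]]; bv <- st$space$beta[parents[ok]]
  bitv <- st$bitv
  Abeta <- A > M; Bbeta <- B > M
  mA <- av; mA[Abeta] <- bv[Abeta]
  mB <- av; mB[Bbeta] <- bv[Bbeta]
  occA <- bitwAnd(mA, bitv[(A - 1L) %% M + 1L]) != 0L
  occB <- bitwAnd(mB, bitv[(B - 1L) %% M + 1L]) != 0L
  acc <- !occA & !occB
  pgen[ok] <- pg
  if (!any(acc)) return(list(child = child, pgen = pgen, K = K))
  sel <- which(ok)[acc]
  loA <- lo[sel]; hiA <- hi[sel]; Aa <- A[acc]; Ba <- B[acc]
  stype <- pm$stype[hp[sel]]
  # spatial hole/particle indices, flip masks, element types
  i1 <- (loA - 1L) %% M + 1L; i2 <- (hiA - 1L) %% M + 1L
  a1 <- (Aa - 1L) %% M + 1L; a2 <- (Ba - 1L) %% M + 1L
  typ <- c(3L, 4L, 5L)[stype]
  avs <- st$space$alpha[parents[sel]]; bvs <- st$space$beta[parents[sel]]
  Kv <- sc_elements_vec(avs, bvs, typ, i1, a1, i2, a2, st$ints)
  # child masks
  ca <- avs; cb <- bvs
  fa <- function(mask, p) bitwXor(mask, bitv[p])
  aa <- stype == 1L; bb <- stype == 2L; ab <- stype == 3L
  if (any(aa)) ca[aa] <- fa(fa(fa(fa(ca[aa], i1[aa]), i2[aa]), a1[aa]), a2[aa])
  if (any(bb)) cb[bb] <- fa(fa(fa(fa(cb[bb], i1[bb]), i2[bb]), a1[bb]), a2[bb])
  if (any(ab)) {
    ca[ab] <- fa(fa(ca[ab], i1[ab]), a1[ab])
    cb[ab] <- fa(fa(cb[ab], i2[ab]), a2[ab])
  }
  ci <- match(det_key(ca, cb), st$space$key)
  child[sel] <- ci
  K[sel] <- Kv
  list(child = child, pgen = pgen, K = K, viol = sum(is.na(ci)))
}

propose_singles <- function(st, parents, sgp) {
  n <- length(parents)
  tables <- st$tables
  M <- tables$pm$M
  N <- ncol(st$OCC)
  k1 <- floor(stats::runif(n) * N) + 1L
  I <- st$OCC[cbind(parents, k1)]
  i_sp <- (I - 1L) %% M + 1L
  r <- tables$sng_rowid[cbind(sgp, i_sp)]
  child <- rep(NA_integer_, n); pgen <- numeric(n); K <- numeric(n)
  ok <- r > 0L
  if (!any(ok)) return(list(child = child, pgen = pgen, K = K))
  rok <- r[ok]
  Kr <- tables$sng$K[rok]
  cell <- floor(stats::runif(sum(ok)) * Kr) + 1L
  u2 <- stats::runif(sum(ok))
  rc <- cbind(rok, cell)
  take <- u2 <= tables$sng$prob[rc]
  pos <- cell
  if (!all(take)) pos[!take] <- tables$sng$alias[rc[!take, , drop = FALSE]]
  rp <- cbind(rok, pos)
  a_sp <- tables$sng$support[rp]
  pg <- (1 - tables$p_dbl[sgp[ok]]) / N * tables$sng$wnorm[rp]
  beta_ch <- I[ok] > M
  av <- st$space$alpha[parents[ok]]; bv <- st$space$beta[parents[ok]]
  bitv <- st$bitv
  mch <- av; mch[beta_ch] <- bv[beta_ch]
  occA <- bitwAnd(mch, bitv[a_sp]) != 0L
  pgen[ok] <- pg
  acc <- !occA
  if (!any(acc)) return(list(child = child, pgen = pgen, K = K))
  sel <- which(ok)[acc]
  i_s <- i_sp[sel]; a_s <- a_sp[acc]
  typ <- c(1L, 2L)[(I[sel] > M) + 1L]
  avs <- st$space$alpha[parents[sel]]; bvs <- st$space$beta[parents[sel]]
  Kv <- sc_elements_vec(avs, bvs, typ, i_s, a_s, i_s, a_s, st$ints)
  fa <- function(mask, p) bitwXor(mask, bitv[p])
  ca <- avs; cb <- bvs
  isb <- typ == 2L
  if (any(!isb)) ca[!isb] <- fa(fa(ca[!isb], i_s[!isb]), a_s[!isb])
  if (any(isb)) cb[isb] <- fa(fa(cb[isb], i_s[isb]), a_s[isb])
  ci <- match(det_key(ca, cb), st$space$key)
  child[sel] <- ci
  K[sel] <- Kv
  list(child = child, pgen = pgen, K = K, viol = sum(is.na(ci)))
}

#' Projected-energy estimator
#'
#' `E_proj = H_ref,ref + sum_{j != ref} H_ref,j n_j / n_ref` over the current
#' walker population (effective-Hamiltonian couplings in SplitGAS mode, where
#' the reference lies in P so the two coincide).
#'
#' @param st An `fciqmc_state`.
#' @return Energy (Hartree); `NA` if the reference is unoccupied.
#' @export
projected_energy <- function(st) {
  if (st$pop[st$ref] == 0) return(NA_real_)
  st$E_ref + sum(st$hrow * st$pop) / st$pop[st$ref]
}

#' Run an FCIQMC dynamics end to end
#'
#' Initializes, advances `n_steps`, and summarizes: blocking-corrected means
#' of the projected energy and shift over the post-burn-in window.
#'
#' @inheritParams init_fciqmc
#' @return List: `stats` (one row per step), `summary` (energy estimators with
#'   blocking error bars), `pop` (final weights), `state`.
#' @export
run_fciqmc <- function(ints, config, gas = NULL, part = NULL) {
  st <- init_fciqmc(ints, config, gas = gas, part = part)
  for (i in seq_len(config$n_steps)) st <- fciqmc_step(st)
  stats_df <- as.data.frame(do.call(rbind, st$stats))
  list(stats = stats_df, summary = fciqmc_summary(stats_df, st$E_ref, config$burnin),
       pop = st$pop, state = st, audit = st$audit)
}

#' Summarize an FCIQMC statistics table
#'
#' The projected energy is the ratio of time averages,
#' `E_ref + sum(num) / sum(den)` with `num = <ref|H|Psi> - E_ref n_ref` and
#' `den = n_ref`, which (unlike averaging per-step ratios) is free of
#' ratio-estimator bias; its error bar comes from blocking the linearized
#' series `(num_t - Ebar den_t) / mean(den)`. The shift is averaged directly
#' over its engaged window.
#'
#' @param stats_df Per-step statistics from [run_fciqmc()].
#' @param e_ref Reference energy added back to shift and projection.
#' @param burnin Steps discarded from the front.
#' @return List with `e_proj_mean`, `e_proj_se`, `shift_mean`, `shift_se`
#'   (empty if fewer than 32 usable steps).
#' @export
fciqmc_summary <- function(stats_df, e_ref, burnin = 0L) {
  keep <- stats_df$step > burnin & is.finite(stats_df$e_num) &
    stats_df$e_den != 0
  if (sum(keep) < 32) return(list())
  num <- stats_df$e_num[keep]; den <- stats_df$e_den[keep]
  ebar <- sum(num) / sum(den)
  z <- (num - ebar * den) / mean(den)
  bz <- blocking_analysis(z)
  out <- list(e_proj_mean = e_ref + ebar, e_proj_se = bz$plateau_estimate)
  keep_s <- keep & stats_df$engaged > 0
  if (sum(keep_s) >= 32) {
    sser <- stats_df$shift[keep_s] + e_ref
    bs <- blocking_analysis(sser)
    out$shift_mean <- mean(sser)
    out$shift_se <- bs$plateau_estimate
  }
  out
}

#' Deterministic (all-core) imaginary-time propagation
#'
#' With the core spanning the whole space the dynamics is exact power
#' iteration on `1 - dtau (H - E I)`; provided as the zero-noise limit of the
#' semistochastic propagation for validation.
#'
#' @param H Hamiltonian matrix (full or effective).
#' @param dtau Time step.
#' @param n_steps Iterations.
#' @param v0 Start vector (default: unit weight on the lowest diagonal).
#' @return List: `vector` (normalized), `energy` (Rayleigh quotient).
#' @export
power_iteration_ground <- function(H, dtau = NULL, n_steps = 2000L, v0 = NULL) {
  d <- nrow(H)
  dg <- if (inherits(H, "sparseMatrix")) Matrix::diag(H) else diag(H)
  if (is.null(dtau)) dtau <- 1.5 / max(diff(range(dg)), 1e-8)
  v <- if (is.null(v0)) { z <- numeric(d); z[which.min(dg)] <- 1; z } else v0
  E0 <- dg[which.min(dg)]
  for (i in seq_len(n_steps)) {
    v <- v - dtau * (as.numeric(H %*% v) - E0 * v)
    v <- v / sqrt(sum(v^2))
  }
  list(vector = fix_sign(v), energy = sum(v * as.numeric(H %*% v)))
}
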