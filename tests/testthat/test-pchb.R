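test_that("double weights carry the heat-bath magnitudes and symmetries", {
  # Hubbard dimer: only on-site opposite-spin pair moves carry weight U
  ints <- make_hubbard(2, 1, 4)
  W <- build_double_weights(ints)
  pm <- attr(W, "pair_meta")
  nz <- which(W > 0, arr.ind = TRUE)
  expect_true(all(pm$stype[nz[, 1]] == 3L))           # opposite spin only
  expect_true(all(W[nz] == 4))
  # hole pair on one site, particle pair on the other
  expect_true(all(pm$sp_lo[nz[, 1]] == pm$sp_hi[nz[, 1]]))
  expect_true(all(pm$sp_lo[nz[, 2]] == pm$sp_hi[nz[, 2]]))

  # generic set: entry magnitude equals |g_AIBJ - g_AJBI| / |g_AIBJ|
  ri <- make_random_integrals(4, 4, seed = 6, scale = 0.3)
  Wr <- build_double_weights(ri, truncation = 0)
  pmr <- attr(Wr, "pair_meta")
  hp <- splitgas:::pair_index(1L, 2L)                 # alpha-alpha holes 1,2
  pp <- splitgas:::pair_index(3L, 4L)                 # alpha-alpha particles 3,4
  expect_equal(Wr[hp, pp], abs(ri$g[3, 1, 4, 2] - ri$g[3, 2, 4, 1]))
  hp2 <- splitgas:::pair_index(1L, 4L + 2L)           # alpha 1, beta 2
  pp2 <- splitgas:::pair_index(3L, 4L + 4L)           # alpha 3, beta 4
  expect_equal(Wr[hp2, pp2], abs(ri$g[3, 1, 4, 2]))
  # collisions zeroed
  expect_equal(Wr[hp, splitgas:::pair_index(1L, 3L)], 0)

  # all-zero g: every double weight vanishes
  hz <- matrix(0.1, 2, 2); diag(hz) <- c(0, 1)
  only_h <- integral_set(2, 2, h = hz)
  expect_true(all(build_double_weights(only_h) == 0))
})

test_that("single weights follow the |h| + sum |g - g| surrogate", {
  diag_only <- make_random_integrals(4, 4, seed = 1, sparsity = 1)
  expect_true(all(build_single_weights(diag_only) == 0))

  h <- matrix(0, 2, 2); h[1, 2] <- h[2, 1] <- 0.3
  two <- integral_set(2, 2, h = h)
  S <- build_single_weights(two)
  expect_equal(S[1, 2], 0.3)
  expect_equal(diag(S), c(0, 0))

  ri <- make_random_integrals(5, 4, seed = 9, scale = 0.3)
  S <- build_single_weights(ri, truncation = 0)
  for (i in 1:5) for (a in 1:5) {
    if (i == a) next
    ref <- abs(ri$h[a, i])
    for (r in 1:5) ref <- ref + abs(ri$g[a, i, r, r] - ri$g[a, r, r, i])
    expect_equal(S[i, a], ref, tolerance = 1e-14)
  }
})

test_that("supergroup zeroing is exact: weight > 0 iff move allowed", {
  fx <- splitgas_fixture()
  ints <- fx$ints; gas <- fx$gas; tab <- fx$table
  dbl <- build_double_weights(ints); sng <- build_single_weights(ints)
  pm <- attr(dbl, "pair_meta")
  sub_of <- integer(pm$M)
  for (s in seq_along(gas$subspaces)) sub_of[gas$subspaces[[s]]] <- s
  hole_subs <- cbind(sub_of[pm$sp_lo], sub_of[pm$sp_hi])
  for (part in list(NULL, fx$part)) {
    tabs <- constrain_tables(dbl, sng, tab, gas, part = part)
    for (sg in seq_len(nrow(tab$supergroups))) {
      # independent re-derivation of the allowed mask via composition arithmetic
      ok_pair <- matrix(FALSE, pm$n_pair, pm$n_pair)
      for (hp in seq_len(pm$n_pair)) {
        tgt_cache <- new.env(parent = emptyenv())
        for (pp in which(dbl[hp, ] > 0)) {
          key <- paste(hole_subs[pp, ], collapse = "_")
          tgt <- tgt_cache[[key]]
          if (is.null(tgt)) {
            tgt <- classify_excitation(sg, hole_subs[hp, ], hole_subs[pp, ], tab)
            if (is.na(tgt)) tgt <- -1L
            tgt_cache[[key]] <- tgt
          }
          if (identical(tgt, -1L)) next
          if (tgt > 0 && (is.null(part) || or_gate(tgt, sg, part)))
            ok_pair[hp, pp] <- TRUE
        }
      }
      expect_identical(tabs$weights[[sg]]$dbl > 0, (dbl > 0) & ok_pair)
      # singles: one-electron moves between subspaces
      ok_s <- matrix(FALSE, pm$M, pm$M)
      for (i in seq_len(pm$M)) for (a in seq_len(pm$M)) {
        tgt <- classify_excitation(sg, sub_of[i], sub_of[a], tab)
        ok_s[i, a] <- !is.na(tgt) && (is.null(part) || or_gate(tgt, sg, part))
      }
      expect_identical(tabs$weights[[sg]]$sng > 0, (sng > 0) & ok_s)
    }
  }
})

test_that("worked GAS example: third electron into G1 is never proposed from [1,1,1]", {
  gas <- table1_gas()
  tab <- enumerate_supergroups(gas)
  ints <- make_random_integrals(6, 3, seed = 17, scale = 0.5, ms2 = 1L)
  dbl <- build_double_weights(ints); sng <- build_single_weights(ints)
  tabs <- constrain_tables(dbl, sng, tab, gas)
  pm <- tabs$pm
  sg_111 <- supergroup_of(c(1, 1, 1), tab)
  sg_012 <- supergroup_of(c(0, 1, 2), tab)
  # double moves with both particles in G1 (orbitals 1:2) from holes in G2, G3
  hole_pairs <- which(pm$sp_lo %in% 3:4 & pm$sp_hi %in% 5:6)
  part_pairs <- which(pm$sp_lo %in% 1:2 & pm$sp_hi %in% 1:2)
  expect_true(all(tabs$weights[[sg_111]]$dbl[hole_pairs, part_pairs] == 0))
  w_012 <- tabs$weights[[sg_012]]$dbl[hole_pairs, part_pairs]
  raw <- dbl[hole_pairs, part_pairs]
  expect_equal(w_012, raw)            # allowed: survives with its raw value
  expect_gt(sum(w_012), 0)
})

test_that("SplitGAS zeroing empties double rows that only reach Q from Q", {
  fx <- contamination_fixture()
  dbl <- build_double_weights(fx$ints); sng <- build_single_weights(fx$ints)
  tabs <- constrain_tables(dbl, sng, fx$table, fx$gas, part = fx$part)
  # masking oracle over all (supergroup, move) pairs
  pm <- tabs$pm
  for (sg in which(!fx$part$ip)) {
    Wm <- tabs$weights[[sg]]$dbl
    for (hp in seq_len(pm$n_pair)) {
      nz <- which(Wm[hp, ] > 0)
      for (pp in nz) {
        tgt <- classify_excitation(
          sg, tabs$sub_of[c(pm$sp_lo[hp], pm$sp_hi[hp])],
          tabs$sub_of[c(pm$sp_lo[pp], pm$sp_hi[pp])], fx$table)
        expect_true(or_gate(tgt, sg, fx$part))
      }
    }
  }
})

test_that("alias tables reconstruct their weight vectors exactly", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    w <- stats::rexp(n) * (stats::runif(n) > 0.3)   # some exact zeros
    if (sum(w) == 0) next
    al <- splitgas:::build_alias(w)
    K <- length(al$support)
    p_implied <- numeric(length(w))
    for (k in seq_len(K)) {
      p_implied[al$support[k]] <- p_implied[al$support[k]] + al$prob[k] / K
      p_implied[al$support[al$alias[k]]] <-
        p_implied[al$support[al$alias[k]]] + (1 - al$prob[k]) / K
    }
    expect_equal(p_implied, w / sum(w), tolerance = 1e-12)
  }
})

test_that("proposal probabilities plus rejection mass sum to one exactly", {
  ints <- make_random_integrals(6, 4, seed = 3, scale = 0.3)
  gas <- gas_partition(list(1:2, 3:4, 5:6), c(0, 0, 0), c(4, 4, 4), 4)
  sp <- enumerate_space(ints, 2, 2, gas)
  dbl <- build_double_weights(ints); sng <- build_single_weights(ints)
  tabs <- constrain_tables(dbl, sng, sp$table, gas)
  M <- 6L
  for (pid in c(1L, 60L, 150L)) {
    parent <- det_at(sp, pid)
    sg <- sp$sg[pid]
    mass <- 0
    for (j in seq_len(space_size(sp)))
      if (j != pid) mass <- mass + p_gen_of(parent, det_at(sp, j), sg, tabs)
    occ <- splitgas:::occ_spin_orbs(parent$alpha, parent$beta, M)
    N <- length(occ)
    pd <- tabs$p_dbl[sg]
    rej <- 0
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
    for (I in occ) {
      r <- tabs$sng_rowid[sg, (I - 1L) %% M + 1L]
      if (r == 0) { rej <- rej + (1 - pd) / N; next }
      for (k in seq_len(tabs$sng$K[r])) {
        A <- tabs$sng$support[r, k] + if (I > M) M else 0L
        if (splitgas:::so_occupied(parent, A, M))
          rej <- rej + (1 - pd) / N * tabs$sng$wnorm[r, k]
      }
    }
    expect_equal(mass + rej, 1, tolerance = 1e-12)
  }
})

test_that("sampled moves follow p_gen and respect constraints", {
  fx <- contamination_fixture()
  sp <- enumerate_space(fx$ints, 2, 2, fx$gas)
  dbl <- build_double_weights(fx$ints); sng <- build_single_weights(fx$ints)
  tabs <- constrain_tables(dbl, sng, fx$table, fx$gas, part = fx$part)
  pid <- 3L
  parent <- det_at(sp, pid); sg <- sp$sg[pid]
  set.seed(99)
  n_draw <- 20000L
  counts <- new.env(parent = emptyenv())
  for (s in seq_len(n_draw)) {
    mv <- sample_excitation(parent, sg, tabs)
    if (mv$rejected) next
    # every accepted target satisfies the GAS and OR-gate constraints
    key <- sprintf("%d_%d", mv$target$alpha, mv$target$beta)
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  keys <- ls(counts)
  idx <- match(keys, sprintf("%d_%d", sp$alpha, sp$beta))
  expect_false(anyNA(idx))             # all targets inside the T space
  for (j in idx)
    expect_true(or_gate(sp$sg[j], sg, fx$part))
  th <- vapply(idx, function(j) p_gen_of(parent, det_at(sp, j), sg, tabs),
               numeric(1))
  emp <- vapply(keys, function(k) counts[[k]], integer(1)) / n_draw
  z <- abs(emp - th) / sqrt(th * (1 - th) / n_draw)
  expect_lt(max(z), 4.5)
})

test_that("degenerate systems are handled: no-move cases and isolation flags", {
  # single orbital: no excitation is ever possible
  one <- make_hubbard(1, 1, 4, n_elec = 2)
  gas1 <- gas_partition(list(1L), 2, 2, 2)
  tab1 <- enumerate_supergroups(gas1)
  tabs1 <- constrain_tables(build_double_weights(one), build_single_weights(one),
                            tab1, gas1)
  expect_equal(tabs1$isolated, 1L)
  parent <- determinant(1, 1)
  expect_error(sample_excitation(parent, 1L, tabs1), "isolated")
})

test_that("dense and sparse storage give bit-identical sampling streams", {
  fx <- splitgas_fixture()
  sp <- enumerate_space(fx$ints, 3, 3, fx$gas)
  dbl <- build_double_weights(fx$ints); sng <- build_single_weights(fx$ints)
  td <- constrain_tables(dbl, sng, fx$table, fx$gas, storage_mode = "dense")
  ts <- constrain_tables(dbl, sng, fx$table, fx$gas, storage_mode = "sparse")
  parent <- det_at(sp, 10L); sg <- sp$sg[10L]
  set.seed(7); stream_d <- replicate(500, {
    mv <- sample_excitation(parent, sg, td)
    if (mv$rejected) -1 else mv$target$alpha + 65536 * mv$target$beta
  })
  set.seed(7); stream_s <- replicate(500, {
    mv <- sample_excitation(parent, sg, ts)
    if (mv$rejected) -1 else mv$target$alpha + 65536 * mv$target$beta
  })
  expect_identical(stream_d, stream_s)
  # and p_gen agrees between storage modes on a connected pair
  j <- which(stream_d > 0)[1]
  tgt <- det_at(sp, match(stream_d[j], sp$alpha + 65536 * sp$beta))
  expect_identical(p_gen_of(parent, tgt, sg, td), p_gen_of(parent, tgt, sg, ts))
})
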