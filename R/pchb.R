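# Precomputed heat-bath (PCHB) excitation generation. Double excitations
# AB <- IJ between Slater determinants have |<i|H|j>| = |g_AIBJ - g_AJBI|
# (same spin) or |g_AIBJ| (opposite spin), independent of the determinants
# involved, so a weight table keyed by (hole pair, particle pair) can be
# precomputed once and sampled in O(1) with alias tables. Singles use the
# robust determinant-independent surrogate S_I^A = |h_AI| + sum_R |g_AIRR -
# g_ARRI|. GAS and SplitGAS constraints are folded in per supergroup: a
# weight is zeroed iff the subspace move is GAS-forbidden from that
# supergroup, or (SplitGAS) the OR-gate marks it as a QQ off-diagonal.
#
# Spin orbitals are numbered 1..M (alpha) and M+1..2M (beta); unordered pairs
# I < J get index (J-1)(J-2)/2 + I.

pair_index <- function(I, J) {
  lo <- pmin(I, J); hi <- pmax(I, J)
  ((hi - 1L) * (hi - 2L)) %/% 2L + lo
}

# Metadata for all spin-orbital pairs of an M-orbital system.
pair_meta <- function(M) {
  n_so <- 2L * M
  hi <- rep(2:n_so, times = 1:(n_so - 1L))
  lo <- unlist(lapply(2:n_so, function(j) seq_len(j - 1L)))
  sp_lo <- (lo - 1L) %% M + 1L
  sp_hi <- (hi - 1L) %% M + 1L
  beta_lo <- lo > M; beta_hi <- hi > M
  stype <- ifelse(!beta_lo & !beta_hi, 1L, ifelse(beta_lo & beta_hi, 2L, 3L))
  list(n_pair = length(lo), lo = lo, hi = hi, sp_lo = sp_lo, sp_hi = sp_hi,
       stype = stype, M = M, n_so = n_so)
}

#' Raw heat-bath double-excitation weights
#'
#' The determinant-independent magnitude of the Hamiltonian element for every
#' (hole pair, particle pair) combination of compatible spin signature:
#' `|g[a,i,b,j] - g[a,j,b,i]|` for same-spin pairs, `|g[a,i,b,j]|` for
#' opposite-spin pairs (alpha hole paired with alpha particle). Entries where
#' a particle collides with a hole are zero, as are magnitudes below
#' `truncation`.
#'
#' @param ints An [integral_set()].
#' @param truncation Weights below this are zeroed (default 1e-8).
#' @return A `n_pair` x `n_pair` matrix (holes by particles) with pair
#'   metadata attached.
#' @export
build_double_weights <- function(ints, truncation = 1e-8) {
  pm <- pair_meta(ints$n_orb)
  W <- matrix(0, pm$n_pair, pm$n_pair)
  g <- ints$g
  for (hp in seq_len(pm$n_pair)) {
    st <- pm$stype[hp]
    i <- pm$sp_lo[hp]; j <- pm$sp_hi[hp]
    pp <- which(pm$stype == st)
    a <- pm$sp_lo[pp]; b <- pm$sp_hi[pp]
    if (st == 3L) {
      w <- abs(g[cbind(a, i, b, j)])
      w[a == i | b == j] <- 0
    } else {
      w <- abs(g[cbind(a, i, b, j)] - g[cbind(a, j, b, i)])
      w[a == i | a == j | b == i | b == j] <- 0
    }
    W[hp, pp] <- w
  }
  W[W < truncation] <- 0
  attr(W, "pair_meta") <- pm
  W
}

#' Raw heat-bath single-excitation weights
#'
#' `S[i, a] = |h[a, i]| + sum_R |g[a,i,R,R] - g[a,R,R,i]|` over all spatial
#' orbitals R; `S[i, i] = 0`. The weight is spin-independent (spatial).
#'
#' @inheritParams build_double_weights
#' @return An `n_orb` x `n_orb` matrix (hole by particle, spatial).
#' @export
build_single_weights <- function(ints, truncation = 1e-8) {
  n <- ints$n_orb
  S <- abs(t(ints$h))
  for (r in seq_len(n)) {
    S <- S + abs(t(ints$g[, , r, r]) - ints$g[r, , , r])
  }
  diag(S) <- 0
  S[S < truncation] <- 0
  S
}

# Walker alias table over the positive support of w: O(1) categorical draws.
build_alias <- function(w) {
  sup <- which(w > 0)
  K <- length(sup)
  if (K == 0L) return(list(support = integer(0), prob = numeric(0),
                           alias = integer(0), total = 0, wnorm = numeric(0)))
  p <- w[sup] / sum(w[sup])
  scaled <- p * K
  small <- which(scaled < 1); large <- which(scaled >= 1)
  prob <- numeric(K); alias <- seq_len(K)
  while (length(small) && length(large)) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]; large <- large[-length(large)]
    prob[s] <- scaled[s]; alias[s] <- l
    scaled[l] <- scaled[l] + scaled[s] - 1
    if (scaled[l] < 1) small <- c(small, l) else large <- c(large, l)
  }
  prob[c(small, large)] <- 1
  list(support = sup, prob = prob, alias = alias, total = sum(w[sup]), wnorm = p)
}

#' Supergroup-constrained PCHB tables
#'
#' Applies the GAS constraint test and (optionally) the SplitGAS OR-gate to the
#' raw heat-bath weights, per supergroup: an entry survives iff moving the
#' holes/particles between subspaces maps the supergroup to another allowed
#' supergroup, and -- when `part` is given -- source or target lies in P.
#' Alias tables are rebuilt per (supergroup, hole pair) and per (supergroup,
#' hole orbital); the single/double branch probability is proportional to the
#' summed surviving weights, floored at 0.05 per branch when both are nonzero.
#'
#' @param dbl_raw Output of [build_double_weights()].
#' @param sng_raw Output of [build_single_weights()].
#' @param table_T `supergroup_table` of the total space.
#' @param gas The [gas_partition()] behind `table_T`.
#' @param part Optional `split_partitioning` (SplitGAS mode).
#' @param storage_mode `"dense"` (full weight matrices per supergroup) or
#'   `"sparse"` (only nonzero rows kept); sampling streams are identical.
#' @return A `pchb_tables` object.
#' @export
constrain_tables <- function(dbl_raw, sng_raw, table_T, gas, part = NULL,
                             storage_mode = c("dense", "sparse")) {
  storage_mode <- match.arg(storage_mode)
  pm <- attr(dbl_raw, "pair_meta")
  stopifnot(!is.null(pm),
            setequal(unlist(gas$subspaces), seq_len(pm$M)))
  n_sg <- nrow(table_T$supergroups)
  sub_of <- integer(pm$M)
  for (s in seq_along(gas$subspaces)) sub_of[gas$subspaces[[s]]] <- s

  # subspace-combo id of every pair (unordered subspace pair with repetition)
  combo_of <- function(s1, s2) {
    lo <- pmin(s1, s2); hi <- pmax(s1, s2)
    ((hi - 1L) * hi) %/% 2L + lo
  }
  hole_combo <- combo_of(sub_of[pm$sp_lo], sub_of[pm$sp_hi])
  n_combo <- (gas$k * (gas$k + 1L)) %/% 2L
  combo_subs <- matrix(0L, n_combo, 2L)
  for (s1 in seq_len(gas$k)) for (s2 in s1:gas$k)
    combo_subs[combo_of(s1, s2), ] <- c(s1, s2)

  # allowed[sg, hole_combo, particle_combo] by exact composition arithmetic
  allowed_d <- array(FALSE, c(n_sg, n_combo, n_combo))
  target_d <- array(NA_integer_, c(n_sg, n_combo, n_combo))
  for (sg in seq_len(n_sg)) for (hc in seq_len(n_combo)) for (pc in seq_len(n_combo)) {
    tg <- classify_excitation(sg, combo_subs[hc, ], combo_subs[pc, ], table_T)
    if (!is.na(tg) && (is.null(part) || or_gate(tg, sg, part))) {
      allowed_d[sg, hc, pc] <- TRUE
      target_d[sg, hc, pc] <- tg
    }
  }
  allowed_s1 <- array(FALSE, c(n_sg, gas$k, gas$k))
  for (sg in seq_len(n_sg)) for (si in seq_len(gas$k)) for (sa in seq_len(gas$k)) {
    tg <- classify_excitation(sg, si, sa, table_T)
    if (!is.na(tg) && (is.null(part) || or_gate(tg, sg, part)))
      allowed_s1[sg, si, sa] <- TRUE
  }

  n_pair <- pm$n_pair
  M <- pm$M
  part_combo <- hole_combo  # same metadata indexes particle pairs
  dbl_rowid <- matrix(0L, n_sg, n_pair)
  sng_rowid <- matrix(0L, n_sg, M)
  dbl_alias <- list(); sng_alias <- list()
  weights <- vector("list", n_sg)
  dbl_total <- numeric(n_sg); sng_total <- numeric(n_sg)
  sng_mask_all <- array(FALSE, c(n_sg, M, M))

  for (sg in seq_len(n_sg)) {
    Wm <- dbl_raw
    keep <- allowed_d[sg, hole_combo, , drop = FALSE]  # n_pair x n_combo
    keep <- matrix(keep, n_pair, n_combo)
    Wm <- Wm * keep[, part_combo]
    Sm <- sng_raw * allowed_s1[sg, sub_of, sub_of]
    sng_mask_all[sg, , ] <- allowed_s1[sg, sub_of, sub_of]
    dbl_total[sg] <- sum(Wm); sng_total[sg] <- sum(Sm)
    for (hp in seq_len(n_pair)) {
      if (any(Wm[hp, ] > 0)) {
        dbl_alias[[length(dbl_alias) + 1L]] <- build_alias(Wm[hp, ])
        dbl_rowid[sg, hp] <- length(dbl_alias)
      }
    }
    for (i in seq_len(M)) {
      if (any(Sm[i, ] > 0)) {
        sng_alias[[length(sng_alias) + 1L]] <- build_alias(Sm[i, ])
        sng_rowid[sg, i] <- length(sng_alias)
      }
    }
    weights[[sg]] <- if (storage_mode == "dense") {
      list(dbl = Wm, sng = Sm)
    } else {
      nzr <- which(rowSums(Wm) > 0)
      list(dbl = lapply(stats::setNames(as.list(nzr), nzr), function(r) {
             sup <- which(Wm[r, ] > 0); list(support = sup, w = Wm[r, sup])
           }),
           sng = {
             nzs <- which(rowSums(Sm) > 0)
             lapply(stats::setNames(as.list(nzs), nzs), function(r) {
               sup <- which(Sm[r, ] > 0); list(support = sup, w = Sm[r, sup])
             })
           })
    }
  }
  p_dbl <- ifelse(dbl_total + sng_total == 0, NA_real_,
                  dbl_total / (dbl_total + sng_total))
  both <- dbl_total > 0 & sng_total > 0
  p_dbl[both] <- pmin(0.95, pmax(0.05, p_dbl[both]))
  isolated <- which(dbl_total + sng_total == 0)

  # flatten alias lists into matrices for vectorized draws
  flat <- function(lst, n_cat) {
    nr <- length(lst)
    K <- vapply(lst, function(a) length(a$support), integer(1))
    Kmax <- max(1L, K)
    Sup <- matrix(1L, nr, Kmax); Pr <- matrix(1, nr, Kmax)
    Al <- matrix(1L, nr, Kmax); Wn <- matrix(0, nr, Kmax)
    for (r in seq_len(nr)) {
      k <- K[r]
      if (k > 0) {
        Sup[r, 1:k] <- lst[[r]]$support; Pr[r, 1:k] <- lst[[r]]$prob
        Al[r, 1:k] <- lst[[r]]$alias; Wn[r, 1:k] <- lst[[r]]$wnorm
      }
    }
    list(K = K, support = Sup, prob = Pr, alias = Al, wnorm = Wn,
         total = vapply(lst, function(a) a$total, numeric(1)))
  }
  structure(list(
    pm = pm, gas = gas, table = table_T, part = part, sub_of = sub_of,
    storage_mode = storage_mode, weights = weights,
    dbl_rowid = dbl_rowid, sng_rowid = sng_rowid,
    dbl = if (length(dbl_alias)) flat(dbl_alias, pm$n_pair) else NULL,
    sng = if (length(sng_alias)) flat(sng_alias, M) else NULL,
    p_dbl = p_dbl, dbl_total = dbl_total, sng_total = sng_total,
    isolated = isolated,
    sng_mask = sng_mask_all),
    class = "pchb_tables")
}

#' @export
print.pchb_tables <- function(x, ...) {
  nz <- function(W) if (is.matrix(W)) mean(W == 0) else NA
  zf <- if (x$storage_mode == "dense")
    mean(vapply(x$weights, function(w) mean(w$dbl == 0), numeric(1))) else NA
  cat(sprintf("<pchb_tables> %d supergroups, %d hole pairs, storage %s%s\n",
              nrow(x$dbl_rowid), ncol(x$dbl_rowid), x$storage_mode,
              if (!is.na(zf)) sprintf(", double-table zero fraction %.1f%%", 100 * zf)
              else ""))
  invisible(x)
}

# Weight of a constrained double (hole pair hp -> particle pair pp) and the
# row normalizer, any storage mode.
dbl_weight_of <- function(tables, sg, hp, pp) {
  r <- tables$dbl_rowid[sg, hp]
  if (r == 0L) return(c(0, 0))
  if (tables$storage_mode == "dense") {
    w <- tables$weights[[sg]]$dbl[hp, pp]
  } else {
    ent <- tables$weights[[sg]]$dbl[[as.character(hp)]]
    pos <- match(pp, ent$support)
    w <- if (is.na(pos)) 0 else ent$w[pos]
  }
  c(w, tables$dbl$total[r])
}

sng_weight_of <- function(tables, sg, i, a) {
  r <- tables$sng_rowid[sg, i]
  if (r == 0L) return(c(0, 0))
  if (tables$storage_mode == "dense") {
    w <- tables$weights[[sg]]$sng[i, a]
  } else {
    ent <- tables$weights[[sg]]$sng[[as.character(i)]]
    pos <- match(a, ent$support)
    w <- if (is.na(pos)) 0 else ent$w[pos]
  }
  c(w, tables$sng$total[r])
}

# Occupied spin orbitals of a determinant (alpha 1..M, beta M+1..2M).
occ_spin_orbs <- function(alpha, beta, M) {
  c(occ_orbs(alpha, M), occ_orbs(beta, M) + M)
}

#' Sample one excitation from a parent determinant
#'
#' Draws single-vs-double by the supergroup's branch probability, the holes
#' uniformly among the parent's occupied spin orbitals (pairs for doubles),
#' and the particles from the supergroup's alias table. Draws whose particle
#' orbital is already occupied in the parent -- a consequence of the
#' determinant-independent weight approximation -- are returned as explicit
#' rejections, not resampled, so `p_gen` stays exactly the categorical
#' probability. Uses R's global random number generator.
#'
#' @param parent A `determinant`.
#' @param i_sg The parent's supergroup index.
#' @param tables A `pchb_tables`.
#' @return List with `kind` (`"single"`/`"double"`), `target` (a `determinant`
#'   or `NULL`), `p_gen`, and for rejections `rejected = TRUE` plus a
#'   `reason`.
#' @export
sample_excitation <- function(parent, i_sg, tables) {
  M <- tables$pm$M
  occ <- occ_spin_orbs(parent$alpha, parent$beta, M)
  N <- length(occ)
  pd <- tables$p_dbl[i_sg]
  if (is.na(pd)) stop("sample_excitation: supergroup ", i_sg,
                      " has no outgoing weight (isolated configuration class)")
  if (N == 0L) return(list(kind = "none", target = NULL, p_gen = 0,
                           rejected = TRUE, reason = "no electrons"))
  if (N < 2L) pd <- 0
  if (stats::runif(1) < pd) {
    k1 <- sample.int(N, 1L); k2 <- sample.int(N - 1L, 1L)
    if (k2 >= k1) k2 <- k2 + 1L
    I <- occ[min(k1, k2)]; J <- occ[max(k1, k2)]
    hp <- pair_index(I, J)
    p_pair <- 1 / choose(N, 2)
    r <- tables$dbl_rowid[i_sg, hp]
    if (r == 0L)
      return(list(kind = "double", target = NULL, p_gen = pd * p_pair,
                  rejected = TRUE, reason = "no allowed particle pair"))
    K <- tables$dbl$K[r]
    k <- sample.int(K, 1L)
    pos <- if (stats::runif(1) <= tables$dbl$prob[r, k]) k else tables$dbl$alias[r, k]
    pp <- tables$dbl$support[r, pos]
    p_gen <- pd * p_pair * tables$dbl$wnorm[r, pos]
    A <- tables$pm$lo[pp]; B <- tables$pm$hi[pp]
    if (so_occupied(parent, A, M) || so_occupied(parent, B, M))
      return(list(kind = "double", target = NULL, p_gen = p_gen,
                  rejected = TRUE, reason = "particle orbital occupied"))
    list(kind = "double", target = apply_double(parent, I, J, A, B, M),
         p_gen = p_gen, rejected = FALSE)
  } else {
    k1 <- sample.int(N, 1L)
    I <- occ[k1]
    i_sp <- (I - 1L) %% M + 1L
    r <- tables$sng_rowid[i_sg, i_sp]
    if (r == 0L)
      return(list(kind = "single", target = NULL, p_gen = (1 - pd) / N,
                  rejected = TRUE, reason = "no allowed particle"))
    K <- tables$sng$K[r]
    k <- sample.int(K, 1L)
    pos <- if (stats::runif(1) <= tables$sng$prob[r, k]) k else tables$sng$alias[r, k]
    a_sp <- tables$sng$support[r, pos]
    p_gen <- (1 - pd) / N * tables$sng$wnorm[r, pos]
    A <- a_sp + if (I > M) M else 0L
    if (so_occupied(parent, A, M))
      return(list(kind = "single", target = NULL, p_gen = p_gen,
                  rejected = TRUE, reason = "particle orbital occupied"))
    list(kind = "single", target = apply_single(parent, I, A, M),
         p_gen = p_gen, rejected = FALSE)
  }
}

so_occupied <- function(det, SO, M) {
  if (SO > M) bitwAnd(det$beta, bit_of(SO - M)) != 0L
  else bitwAnd(det$alpha, bit_of(SO)) != 0L
}

apply_single <- function(det, I, A, M) {
  a <- det$alpha; b <- det$beta
  if (I > M) b <- bitwXor(b, bit_of(I - M)) else a <- bitwXor(a, bit_of(I))
  if (A > M) b <- bitwXor(b, bit_of(A - M)) else a <- bitwXor(a, bit_of(A))
  structure(list(alpha = a, beta = b), class = "determinant")
}

apply_double <- function(det, I, J, A, B, M) {
  apply_single(apply_single(det, I, A, M), J, B, M)
}

#' Exact generation probability of a realized move
#'
#' The probability that [sample_excitation()] proposes `target` from `parent`,
#' summing branch, uniform-hole and alias-category factors. Zero for pairs not
#' connected by a rank-1 or rank-2 excitation, or forbidden by the tables.
#'
#' @inheritParams sample_excitation
#' @param target A `determinant`.
#' @return Probability in `[0, 1]`.
#' @export
p_gen_of <- function(parent, target, i_sg, tables) {
  M <- tables$pm$M
  xa <- bitwXor(parent$alpha, target$alpha)
  xb <- bitwXor(parent$beta, target$beta)
  ra <- popcount(xa); rb <- popcount(xb)
  occ <- occ_spin_orbs(parent$alpha, parent$beta, M)
  N <- length(occ)
  pd <- tables$p_dbl[i_sg]
  if (is.na(pd)) return(0)
  if (N < 2L) pd <- 0
  if (ra + rb == 2L) {                       # single
    if (ra == 2L) {
      I <- occ_orbs(bitwAnd(xa, parent$alpha), M)
      A <- occ_orbs(bitwAnd(xa, target$alpha), M)
      i_sp <- I; a_sp <- A
      ISO <- I
    } else {
      I <- occ_orbs(bitwAnd(xb, parent$beta), M)
      A <- occ_orbs(bitwAnd(xb, target$beta), M)
      i_sp <- I; a_sp <- A
      ISO <- I + M
    }
    wt <- sng_weight_of(tables, i_sg, i_sp, a_sp)
    if (wt[1] == 0) return(0)
    (1 - pd) / N * wt[1] / wt[2]
  } else if (ra + rb == 4L && ra %in% c(0L, 2L, 4L)) {  # double
    holes <- c(occ_orbs(bitwAnd(xa, parent$alpha), M),
               occ_orbs(bitwAnd(xb, parent$beta), M) + M)
    parts <- c(occ_orbs(bitwAnd(xa, target$alpha), M),
               occ_orbs(bitwAnd(xb, target$beta), M) + M)
    if (length(holes) != 2L || length(parts) != 2L) return(0)
    hp <- pair_index(holes[1], holes[2])
    pp <- pair_index(parts[1], parts[2])
    wt <- dbl_weight_of(tables, i_sg, hp, pp)
    if (wt[1] == 0) return(0)
    pd / choose(N, 2) * wt[1] / wt[2]
  } else 0
}
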