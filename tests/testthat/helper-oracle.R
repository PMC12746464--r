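# Independent second-quantized Hamiltonian oracle. Builds <D_i|H|D_j> by
# literal application of creation/annihilation operators on occupation
# bitstrings over 2M spin orbitals (alpha block 1..M then beta block M+1..2M,
# matching the package's canonical ordering), with explicit sign tracking:
#   H = sum_{pq,s} h[p,q] a+_{ps} a_{qs}
#     + 1/2 sum_{pqrs,s,t} g[p,q,r,s] a+_{ps} a+_{rt} a_{st} a_{qs}
# (chemist's notation). No Slater-Condon shortcuts anywhere.

oracle_state <- function(alpha, beta, M) {
  occ <- integer(2L * M)
  occ[splitgas:::occ_orbs(alpha, M)] <- 1L
  occ[splitgas:::occ_orbs(beta, M) + M] <- 1L
  occ
}

oracle_annihilate <- function(occ, P) {
  if (occ[P] == 0L) return(NULL)
  sign <- if (sum(occ[seq_len(P - 1L)]) %% 2L == 0L) 1 else -1
  occ[P] <- 0L
  list(occ = occ, sign = sign)
}

oracle_create <- function(occ, P) {
  if (occ[P] == 1L) return(NULL)
  sign <- if (sum(occ[seq_len(P - 1L)]) %% 2L == 0L) 1 else -1
  occ[P] <- 1L
  list(occ = occ, sign = sign)
}

# <bra| a+_P a_Q |ket>, both occupation vectors; returns signed 0/1.
oracle_1body <- function(bra, ket, P, Q) {
  s1 <- oracle_annihilate(ket, Q)
  if (is.null(s1)) return(0)
  s2 <- oracle_create(s1$occ, P)
  if (is.null(s2)) return(0)
  if (all(s2$occ == bra)) s1$sign * s2$sign else 0
}

# <bra| a+_P a+_R a_S a_Q |ket>
oracle_2body <- function(bra, ket, P, Q, R, S) {
  s1 <- oracle_annihilate(ket, Q)
  if (is.null(s1)) return(0)
  s2 <- oracle_annihilate(s1$occ, S)
  if (is.null(s2)) return(0)
  s3 <- oracle_create(s2$occ, R)
  if (is.null(s3)) return(0)
  s4 <- oracle_create(s3$occ, P)
  if (is.null(s4)) return(0)
  if (all(s4$occ == bra)) s1$sign * s2$sign * s3$sign * s4$sign else 0
}

oracle_element <- function(bra, ket, ints) {
  M <- ints$n_orb
  val <- if (all(bra == ket)) ints$e_core else 0
  for (p in seq_len(M)) for (q in seq_len(M)) {
    if (ints$h[p, q] != 0) {
      for (s in c(0L, M)) {
        val <- val + ints$h[p, q] * oracle_1body(bra, ket, p + s, q + s)
      }
    }
    for (r in seq_len(M)) for (s2 in seq_len(M)) {
      gv <- ints$g[p, q, r, s2]
      if (gv == 0) next
      for (sig in c(0L, M)) for (tau in c(0L, M)) {
        t2 <- oracle_2body(bra, ket, p + sig, q + sig, r + tau, s2 + tau)
        if (t2 != 0) val <- val + 0.5 * gv * t2
      }
    }
  }
  val
}

oracle_hamiltonian <- function(space, ints) {
  d <- splitgas::space_size(space)
  M <- ints$n_orb
  states <- lapply(seq_len(d), function(i)
    oracle_state(space$alpha[i], space$beta[i], M))
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in i:d) {
    v <- oracle_element(states[[i]], states[[j]], ints)
    H[i, j] <- H[j, i] <- v
  }
  H
}
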