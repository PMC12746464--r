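# Slater-Condon rules on bit-encoded determinants. Signs come from the parity
# of occupied orbitals crossed when lining excitations up in the canonical
# (ascending alpha, then ascending beta) order; same-spin doubles are applied
# sequentially so the two single-excitation parities compose correctly.

#' Hamiltonian matrix element between two determinants
#'
#' Standard Slater-Condon value `<d_i|H|d_j>`, including the fermionic
#' permutation sign and the core energy on the diagonal. Zero whenever the
#' excitation rank exceeds 2.
#'
#' @param d_i,d_j `determinant` objects over the same orbital set.
#' @param ints An [integral_set()].
#' @return Energy in Hartree.
#' @export
slater_condon_element <- function(d_i, d_j, ints) {
  sc_element(d_i$alpha, d_i$beta, d_j$alpha, d_j$beta, ints)
}

sc_element <- function(ai, bi, aj, bj, ints) {
  n <- ints$n_orb
  xa <- bitwXor(ai, aj); xb <- bitwXor(bi, bj)
  ra <- popcount(xa); rb <- popcount(xb)
  rank2 <- ra + rb                       # twice the excitation rank
  if (rank2 > 4L) return(0)
  h <- ints$h; g <- ints$g
  if (rank2 == 0L) return(sc_diagonal(ai, bi, ints))
  if (rank2 == 2L) {
    # single excitation in one channel
    if (ra == 2L) { m <- ai; mo <- aj; same <- ai; occ_other <- bi; ch_a <- TRUE }
    else { m <- bi; mo <- bj; same <- bi; occ_other <- ai; ch_a <- FALSE }
    i <- occ_orbs(bitwAnd(bitwXor(m, mo), m), n)   # hole (in d_i only)
    a <- occ_orbs(bitwAnd(bitwXor(m, mo), mo), n)  # particle (in d_j only)
    s <- 1 - 2 * (popcount(bitwAnd(m, between_mask(i, a))) %% 2L)
    occ_same <- occ_orbs(same, n)
    occ_oth <- occ_orbs(occ_other, n)
    val <- h[a, i]
    for (r in occ_same) val <- val + g[a, i, r, r] - g[a, r, r, i]
    for (r in occ_oth) val <- val + g[a, i, r, r]
    return(s * val)
  }
  # doubles
  if (ra == 2L && rb == 2L) {            # opposite-spin double
    i <- occ_orbs(bitwAnd(xa, ai), n); a <- occ_orbs(bitwAnd(xa, aj), n)
    j <- occ_orbs(bitwAnd(xb, bi), n); b <- occ_orbs(bitwAnd(xb, bj), n)
    s <- (1 - 2 * (popcount(bitwAnd(ai, between_mask(i, a))) %% 2L)) *
         (1 - 2 * (popcount(bitwAnd(bi, between_mask(j, b))) %% 2L))
    return(s * g[a, i, b, j])
  }
  if (ra == 4L || rb == 4L) {            # same-spin double
    m <- if (ra == 4L) ai else bi
    mo <- if (ra == 4L) aj else bj
    x <- bitwXor(m, mo)
    ij <- sort(occ_orbs(bitwAnd(x, m), n))
    ab <- sort(occ_orbs(bitwAnd(x, mo), n))
    s1 <- 1 - 2 * (popcount(bitwAnd(m, between_mask(ij[1], ab[1]))) %% 2L)
    m2 <- bitwXor(m, bitwOr(bit_of(ij[1]), bit_of(ab[1])))
    s2 <- 1 - 2 * (popcount(bitwAnd(m2, between_mask(ij[2], ab[2]))) %% 2L)
    return(s1 * s2 * (g[ab[1], ij[1], ab[2], ij[2]] - g[ab[1], ij[2], ab[2], ij[1]]))
  }
  0  # one single in each channel plus more -- cannot happen below rank check
}

# Diagonal <D|H|D>.
sc_diagonal <- function(alpha, beta, ints) {
  n <- ints$n_orb; h <- ints$h; g <- ints$g
  A <- occ_orbs(alpha, n); B <- occ_orbs(beta, n)
  val <- ints$e_core + sum(h[cbind(A, A)]) + sum(h[cbind(B, B)])
  coul <- function(P, Q) {
    if (length(P) == 0L || length(Q) == 0L) return(0)
    sum(g[cbind(rep(P, each = length(Q)), rep(P, each = length(Q)),
                rep(Q, length(P)), rep(Q, length(P)))])
  }
  # full P x P grid: the p = q term cancels the same-spin self-Coulomb
  exch <- function(P) {
    if (length(P) == 0L) return(0)
    idx <- expand.grid(p = P, q = P)
    sum(g[cbind(idx$p, idx$q, idx$q, idx$p)])
  }
  val + 0.5 * (coul(A, A) + coul(B, B) + 2 * coul(A, B)) -
    0.5 * (exch(A) + exch(B))
}

# Diagonal for every determinant of a space (vector).
space_diagonal <- function(space, ints) {
  vapply(seq_along(space$alpha),
         function(i) sc_diagonal(space$alpha[i], space$beta[i], ints),
         numeric(1))
}

#' Dense or sparse Hamiltonian over an enumerated space
#'
#' Builds the full symmetric Hamiltonian matrix of a `ci_space` by applying the
#' Slater-Condon rules to every determinant pair of excitation rank <= 2.
#'
#' @param space A `ci_space`.
#' @param ints An [integral_set()].
#' @param sparse Return a `Matrix::sparseMatrix` (default for dim > 400)?
#' @return A symmetric matrix of dimension `space_size(space)`.
#' @export
build_hamiltonian <- function(space, ints, sparse = space_size(space) > 400L) {
  d <- space_size(space)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diagv <- space_diagonal(space, ints)
  al <- space$alpha; be <- space$beta
  for (i in seq_len(d)) {
    if (i == d) break
    js <- (i + 1L):d
    rank2 <- popcount(bitwXor(al[i], al[js])) + popcount(bitwXor(be[i], be[js]))
    js <- js[rank2 <= 4L]
    if (length(js) == 0L) next
    v <- vapply(js, function(j) sc_element(al[i], be[i], al[j], be[j], ints),
                numeric(1))
    nz <- v != 0
    ii <- c(ii, rep.int(i, sum(nz))); jj <- c(jj, js[nz]); vv <- c(vv, v[nz])
  }
  if (sparse) {
    Matrix::sparseMatrix(i = c(ii, jj, seq_len(d)), j = c(jj, ii, seq_len(d)),
                         x = c(vv, vv, diagv), dims = c(d, d))
  } else {
    H <- matrix(0, d, d)
    H[cbind(ii, jj)] <- vv
    H[cbind(jj, ii)] <- vv
    diag(H) <- diagv
    H
  }
}

# Vectorized off-diagonal elements for batches of proposed moves.
# Parents given by mask vectors (av, bv); moves by type and spatial indices:
#   type 1: alpha single i1 -> a1     type 2: beta single i1 -> a1
#   type 3: alpha-alpha double {i1<i2} -> {a1<a2}
#   type 4: beta-beta double likewise
#   type 5: alpha i1 -> a1 with beta i2 -> a2
# Returns the signed Slater-Condon value per move.
sc_elements_vec <- function(av, bv, type, i1, a1, i2, a2, ints) {
  n <- ints$n_orb
  out <- numeric(length(type))
  sgn <- function(mask, p, q)
    1 - 2 * (popcount(bitwAnd(mask, between_mask(p, q))) %% 2L)
  gflat <- function(a, b, cc, dd)
    ints$g[(a - 1L) + n * (b - 1L) + n * n * (cc - 1L) + n^3 * (dd - 1L) + 1L]

  sing <- which(type <= 2L)
  if (length(sing)) {
    ch_mask <- ifelse(type[sing] == 1L, av[sing], bv[sing])
    oth_mask <- ifelse(type[sing] == 1L, bv[sing], av[sing])
    i <- i1[sing]; a <- a1[sing]
    s <- sgn(ch_mask, i, a)
    val <- ints$h[cbind(a, i)]
    # Coulomb over all occupied spin orbitals; exchange over same channel.
    for (p in seq_len(n)) {
      occ_same <- bitwAnd(ch_mask, bit_of(p)) != 0L
      occ_oth <- bitwAnd(oth_mask, bit_of(p)) != 0L
      val <- val + (occ_same + occ_oth) * gflat(a, i, p, p) -
        occ_same * gflat(a, p, p, i)
    }
    out[sing] <- s * val
  }
  ss <- which(type == 3L | type == 4L)
  if (length(ss)) {
    m <- ifelse(type[ss] == 3L, av[ss], bv[ss])
    s1 <- sgn(m, i1[ss], a1[ss])
    m2 <- bitwXor(m, bitwOr(bit_of(i1[ss]), bit_of(a1[ss])))
    s2 <- sgn(m2, i2[ss], a2[ss])
    out[ss] <- s1 * s2 * (gflat(a1[ss], i1[ss], a2[ss], i2[ss]) -
                          gflat(a1[ss], i2[ss], a2[ss], i1[ss]))
  }
  os <- which(type == 5L)
  if (length(os)) {
    s <- sgn(av[os], i1[os], a1[os]) * sgn(bv[os], i2[os], a2[os])
    out[os] <- s * gflat(a1[os], i1[os], a2[os], i2[os])
  }
  out
}
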