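# Bit-set determinant machinery. A determinant is a pair of integer bitmasks
# (alpha, beta); bit p-1 set <=> spatial orbital p occupied in that spin
# channel. Orbital indices are 1-based throughout the package; canonical
# ordering inside a determinant is alpha orbitals ascending, then beta
# orbitals ascending, which fixes all fermionic signs.

.sg_env <- new.env(parent = emptyenv())

.bitcnt_table <- function() {
  if (is.null(.sg_env$bitcnt)) {
    b <- integer(65536L)
    for (k in 0:15) b <- b + bitwAnd(bitwShiftR(0:65535, k), 1L)
    .sg_env$bitcnt <- b
  }
  .sg_env$bitcnt
}

# Vectorized popcount for non-negative 32-bit integers.
popcount <- function(x) {
  b <- .bitcnt_table()
  b[bitwAnd(x, 65535L) + 1L] + b[bitwShiftR(x, 16L) + 1L]
}

bit_of <- function(p) bitwShiftL(1L, p - 1L)

# Bitmask of orbitals strictly between p and q (any order). Vectorized.
between_mask <- function(p, q) {
  lo <- pmin(p, q); hi <- pmax(p, q)
  # bits lo..hi-2 (0-based): ((1 << (hi-1)) - 1) & ~((1 << lo) - 1)
  full <- bitwShiftL(1L, hi - 1L) - 1L
  below <- bitwShiftL(1L, lo) - 1L
  bitwAnd(full, bitwNot(below))
}

# Occupied orbital list of one mask (ascending).
occ_orbs <- function(mask, n_orb) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_orb) - 1L)) != 0L)
}

mask_of <- function(orbs) {
  if (length(orbs) == 0L) return(0L)
  Reduce(bitwOr, bitwShiftL(1L, as.integer(orbs) - 1L))
}

#' Construct a Slater determinant
#'
#' @param alpha_occ Integer vector of spatial orbitals occupied spin-up.
#' @param beta_occ Integer vector of spatial orbitals occupied spin-down.
#' @return A `determinant` object (alpha/beta bitmask pair).
#' @export
determinant <- function(alpha_occ, beta_occ) {
  stopifnot(!anyDuplicated(alpha_occ), !anyDuplicated(beta_occ),
            all(alpha_occ >= 1), all(beta_occ >= 1))
  structure(list(alpha = mask_of(alpha_occ), beta = mask_of(beta_occ)),
            class = "determinant")
}

#' @export
print.determinant <- function(x, ...) {
  n <- max(1L, ceiling(log2(max(x$alpha, x$beta, 1) + 1)))
  cat("|", det_string(x$alpha, x$beta, n), ">\n", sep = "")
  invisible(x)
}

# Compact occupation string: 2 / a / b / 0 per orbital.
det_string <- function(alpha, beta, n_orb) {
  ch <- character(n_orb)
  for (p in seq_len(n_orb)) {
    a <- bitwAnd(alpha, bit_of(p)) != 0L
    b <- bitwAnd(beta, bit_of(p)) != 0L
    ch[p] <- if (a && b) "2" else if (a) "a" else if (b) "b" else "0"
  }
  paste(ch, collapse = "")
}

# Numeric key unique per determinant (exact for n_orb <= 16).
det_key <- function(alpha, beta) as.numeric(alpha) + as.numeric(beta) * 2^16

#' Enumerate a configuration-interaction space
#'
#' Lists every determinant with `n_alpha` spin-up and `n_beta` spin-down
#' electrons in `ints$n_orb` orbitals whose per-subspace occupation vector is an
#' allowed supergroup of `gas` (all determinants if `gas` is `NULL`). Ordering
#' is deterministic: ascending in the (alpha, beta) bit encoding.
#'
#' @param ints An [integral_set()] (supplies the orbital count).
#' @param n_alpha,n_beta Electron counts per spin channel.
#' @param gas Optional [gas_partition()] restricting the space.
#' @return A `ci_space` object: parallel `alpha`/`beta` mask vectors, numeric
#'   lookup keys, and (when `gas` is given) the supergroup index of each
#'   determinant.
#' @export
enumerate_space <- function(ints, n_alpha, n_beta, gas = NULL) {
  n_orb <- ints$n_orb
  stopifnot(n_alpha + n_beta == ints$n_elec, n_alpha <= n_orb, n_beta <= n_orb)
  amask <- combn_masks(n_orb, n_alpha)
  bmask <- combn_masks(n_orb, n_beta)
  alpha <- rep(amask, each = length(bmask))
  beta <- rep(bmask, times = length(amask))
  sg <- NULL
  table <- NULL
  if (!is.null(gas)) {
    table <- enumerate_supergroups(gas)
    occ <- subspace_occupations(alpha, beta, gas)
    sg <- supergroup_index_of(occ, table)
    keep <- !is.na(sg)
    if (!any(keep)) stop("enumerate_space: GAS constraints admit no determinant")
    alpha <- alpha[keep]; beta <- beta[keep]; sg <- sg[keep]
  }
  ord <- order(det_key(alpha, beta))
  alpha <- alpha[ord]; beta <- beta[ord]
  if (!is.null(sg)) sg <- sg[ord]
  structure(list(n_orb = n_orb, n_alpha = as.integer(n_alpha),
                 n_beta = as.integer(n_beta),
                 alpha = alpha, beta = beta, key = det_key(alpha, beta),
                 gas = gas, table = table, sg = sg),
            class = "ci_space")
}

#' @export
print.ci_space <- function(x, ...) {
  cat(sprintf("<ci_space> %d determinants, %d orbitals, (%d alpha, %d beta)%s\n",
              length(x$alpha), x$n_orb, x$n_alpha, x$n_beta,
              if (is.null(x$gas)) "" else ", GAS-constrained"))
  invisible(x)
}

#' Number of determinants in a CI space
#' @param space A `ci_space`.
#' @return Integer count.
#' @export
space_size <- function(space) length(space$alpha)

# All C(n, k) occupation bitmasks, ascending numeric order.
combn_masks <- function(n, k) {
  if (k == 0L) return(0L)
  cols <- utils::combn(n, k)
  masks <- integer(ncol(cols))
  for (j in seq_len(ncol(cols))) masks[j] <- mask_of(cols[, j])
  sort(masks)
}

# Position of determinants (mask vectors) in a space; NA if absent.
space_lookup <- function(space, alpha, beta) {
  match(det_key(alpha, beta), space$key)
}

# Per-subspace electron counts for vectors of masks: matrix [n_det, k].
subspace_occupations <- function(alpha, beta, gas) {
  k <- length(gas$subspaces)
  out <- matrix(0L, length(alpha), k)
  for (s in seq_len(k)) {
    m <- mask_of(gas$subspaces[[s]])
    out[, s] <- popcount(bitwAnd(alpha, m)) + popcount(bitwAnd(beta, m))
  }
  out
}
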