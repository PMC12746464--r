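# Total-spin machinery. S^2 = S-S+ + Sz(Sz+1) is applied determinant-wise;
# since S- is the adjoint of S+, matrix elements within a spatial-occupation
# block reduce to the Gram matrix of the S+ images, which keeps everything
# exact without any genealogical (GUGA) coupling machinery.

# Images of S+|D> = sum_p a+_{p,alpha} a_{p,beta} |D>: one image per orbital
# singly occupied with a beta electron. Canonical ordering (alpha block then
# beta block, each ascending) fixes the sign.
splus_images <- function(alpha, beta, n_orb) {
  ps <- occ_orbs(bitwAnd(beta, bitwNot(alpha)), n_orb)
  if (length(ps) == 0L)
    return(list(alpha = integer(0), beta = integer(0), sign = numeric(0)))
  n_alpha <- popcount(alpha)
  a2 <- integer(length(ps)); b2 <- integer(length(ps)); sg <- numeric(length(ps))
  for (k in seq_along(ps)) {
    p <- ps[k]
    below <- bit_of(p) - 1L
    perm <- n_alpha + popcount(bitwAnd(beta, below)) + popcount(bitwAnd(alpha, below))
    sg[k] <- 1 - 2 * (perm %% 2L)
    a2[k] <- bitwOr(alpha, bit_of(p))
    b2[k] <- bitwAnd(beta, bitwNot(bit_of(p)))
  }
  list(alpha = a2, beta = b2, sign = sg)
}

#' Expectation value of total spin
#'
#' Evaluates `<Psi|S^2|Psi>` for a coefficient vector over a determinant space,
#' using `S^2 = S-S+ + Sz(Sz+1)`; the first term is the squared norm of
#' `S+|Psi>`. The vector is normalized defensively.
#'
#' @param coeffs Numeric coefficient vector, one entry per determinant.
#' @param space A `ci_space`.
#' @return The scalar `<S^2>` (0 for a closed-shell determinant, `S(S+1)` for
#'   a pure spin-S state).
#' @export
s_squared_expectation <- function(coeffs, space) {
  stopifnot(length(coeffs) == space_size(space))
  nrm <- sqrt(sum(coeffs^2))
  if (nrm == 0) stop("s_squared_expectation: zero coefficient vector")
  c_ <- coeffs / nrm
  ms <- (space$n_alpha - space$n_beta) / 2
  # accumulate S+|Psi> keyed by raised determinant
  acc <- new.env(parent = emptyenv(), hash = TRUE)
  nz <- which(c_ != 0)
  for (i in nz) {
    im <- splus_images(space$alpha[i], space$beta[i], space$n_orb)
    for (k in seq_along(im$sign)) {
      key <- sprintf("%d_%d", im$alpha[k], im$beta[k])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        im$sign[k] * c_[i]
    }
  }
  amps <- unlist(as.list(acc), use.names = FALSE)
  sum(amps^2) + ms * (ms + 1)
}

#' Spin-adapted sub-basis of a determinant space
#'
#' Partitions the space by spatial occupation and, within each block,
#' diagonalizes `S^2` to extract the orthonormal eigenvectors with total spin
#' `s_target` (eigenvalue `s_target * (s_target + 1)`). Blocks contributing no
#' such eigenvector are omitted. Within a degenerate eigenvalue the vectors
#' are ordered by (and sign-fixed positive on) their coefficient on the
#' lexicographically smallest determinant of the block, so the transform is
#' reproducible.
#'
#' @param space A `ci_space` with `Ms <= s_target`.
#' @param s_target Total spin S of the configuration state functions (CSFs).
#' @return List of blocks, each with `det_idx` (positions in `space`),
#'   `transform` (determinants x CSFs coefficient matrix), `s_value`, and the
#'   spatial occupation string.
#' @export
spin_adapted_basis <- function(space, s_target) {
  ms <- (space$n_alpha - space$n_beta) / 2
  stopifnot(abs(ms) <= s_target + 1e-12)
  docc <- bitwAnd(space$alpha, space$beta)
  somo <- bitwXor(space$alpha, space$beta)
  grp <- det_key(docc, somo)
  blocks <- list()
  target <- s_target * (s_target + 1)
  for (key in unique(grp)) {
    idx <- which(grp == key)
    nb <- length(idx)
    # Gram matrix of S+ images gives <D'|S-S+|D>
    imgs <- lapply(idx, function(i)
      splus_images(space$alpha[i], space$beta[i], space$n_orb))
    allk <- unique(unlist(lapply(imgs, function(im) det_key(im$alpha, im$beta))))
    M <- matrix(0, length(allk), nb)
    for (jcol in seq_len(nb)) {
      im <- imgs[[jcol]]
      if (length(im$sign))
        M[match(det_key(im$alpha, im$beta), allk), jcol] <- im$sign
    }
    S2 <- crossprod(M) + diag(ms * (ms + 1), nb)
    eg <- eigen(S2, symmetric = TRUE)
    sel <- which(abs(eg$values - target) < 1e-8)
    if (length(sel) == 0L) next
    V <- eg$vectors[, sel, drop = FALSE]
    lead <- which.min(space$key[idx])       # lexicographically smallest det
    ord <- order(-abs(V[lead, ]))
    V <- V[, ord, drop = FALSE]
    for (j in seq_len(ncol(V))) {
      piv <- if (abs(V[lead, j]) > 1e-12) V[lead, j] else V[which.max(abs(V[, j])), j]
      if (piv < 0) V[, j] <- -V[, j]
    }
    blocks[[length(blocks) + 1L]] <- list(
      det_idx = idx, transform = V, s_value = s_target,
      occupation = det_string(space$alpha[idx[1]], space$beta[idx[1]], space$n_orb))
  }
  blocks
}

#' Assemble a spin-adapted basis into one transformation matrix
#'
#' Stacks the per-block transforms of [spin_adapted_basis()] into a sparse
#' determinants-by-CSFs matrix `U` with orthonormal columns, suitable for
#' conjugating the Hamiltonian (`t(U) %*% H %*% U`).
#'
#' @param space A `ci_space`.
#' @param blocks Result of [spin_adapted_basis()].
#' @return List: `U` (sparse dgCMatrix), `block_of` (block index per CSF
#'   column), `sg` (supergroup index per CSF, when the space is
#'   GAS-constrained, else `NULL`).
#' @export
csf_transform <- function(space, blocks) {
  d <- space_size(space)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  col <- 0L
  block_of <- integer(0)
  sgv <- integer(0)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    for (j in seq_len(ncol(blk$transform))) {
      col <- col + 1L
      ii <- c(ii, blk$det_idx)
      jj <- c(jj, rep.int(col, length(blk$det_idx)))
      xx <- c(xx, blk$transform[, j])
      block_of <- c(block_of, b)
      sgv <- c(sgv, if (is.null(space$sg)) NA_integer_ else space$sg[blk$det_idx[1]])
    }
  }
  U <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d, col))
  list(U = U, block_of = block_of,
       sg = if (is.null(space$sg)) NULL else sgv)
}
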