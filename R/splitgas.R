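# P/Q partitioning over supergroups and the second-order Loewdin machinery.
# The perturber block enters only through its diagonal: the "effective"
# Hamiltonian keeps PP, PQ, QP intact and zeroes QQ off-diagonals, which is
# exactly equivalent (on states with nonzero P projection) to the downfolded
# matrix H~_ij(E) = H_ij + sum_a H_ia H_aj / (E - H_aa) solved
# self-consistently in E.

#' Build the P/Q split of a supergroup table
#'
#' Designates as principal (P) the supergroups of `table_T` that satisfy a
#' second, tighter constraint set over the same subspaces (or an explicit
#' supergroup-index list), and records the logical membership vector `iP`.
#'
#' @param table_T `supergroup_table` of the total space T.
#' @param p_constraints A [gas_partition()] over the same subspaces whose
#'   satisfying supergroups define P, or `NULL` when `p_supergroups` is given.
#' @param p_supergroups Optional explicit integer vector of T supergroup
#'   indices forming P (overrides `p_constraints`).
#' @return A `split_partitioning`: the table, logical `ip` per T supergroup,
#'   and the P supergroup indices.
#' @export
build_ip_vector <- function(table_T, p_constraints = NULL, p_supergroups = NULL) {
  if (is.null(p_supergroups)) {
    stopifnot(inherits(p_constraints, "gas_partition"))
    okP <- composition_allowed(table_T$compositions, p_constraints)
    okT <- !is.na(table_T$isg_of_ic)
    if (any(okP & !okT)) {
      bad <- which(okP & !okT)
      stop("build_ip_vector: P constraints admit compositions outside T (i_C = ",
           paste(bad, collapse = ", "), ")")
    }
    p_supergroups <- table_T$isg_of_ic[okP & okT]
  }
  p_supergroups <- sort(unique(as.integer(p_supergroups)))
  n_sg <- nrow(table_T$supergroups)
  if (length(p_supergroups) == 0L) stop("build_ip_vector: P is empty")
  if (any(p_supergroups < 1L | p_supergroups > n_sg))
    stop("build_ip_vector: P supergroup index outside T")
  ip <- rep(FALSE, n_sg)
  ip[p_supergroups] <- TRUE
  structure(list(table = table_T, ip = ip, p_supergroups = p_supergroups,
                 p_constraints = p_constraints),
            class = "split_partitioning")
}

#' @export
print.split_partitioning <- function(x, ...) {
  cat(sprintf("<split_partitioning> %d T supergroups: %d in P, %d in Q\n",
              length(x$ip), sum(x$ip), sum(!x$ip)))
  invisible(x)
}

#' OR-gate spawn classification
#'
#' A spawn between supergroups is permitted unless both source and target lie
#' in Q: the allowed flag is `iP(target) | iP(source)`. This is what zeroes
#' every off-diagonal QQ coupling while keeping PP, PQ and QP intact.
#'
#' @param i_sg_target,i_sg_source T supergroup indices (vectorized).
#' @param part A `split_partitioning`.
#' @return Logical vector.
#' @export
or_gate <- function(i_sg_target, i_sg_source, part) {
  part$ip[i_sg_target] | part$ip[i_sg_source]
}

# Zero the QQ off-diagonals of a plain symmetric matrix given P membership.
mask_qq_offdiag <- function(H, in_p) {
  q <- which(!in_p)
  if (length(q) > 1L) {
    if (inherits(H, "sparseMatrix")) {
      Hq <- H[q, q, drop = FALSE]
      H[q, q] <- Matrix::Diagonal(length(q), Matrix::diag(Hq))
    } else {
      dq <- diag(H)[q]
      H[q, q] <- 0
      H[cbind(q, q)] <- dq
    }
  }
  H
}

#' Effective SplitGAS Hamiltonian over a determinant space
#'
#' Builds the Hamiltonian of a GAS-enumerated space and zeroes every
#' off-diagonal entry whose two determinants both belong to Q supergroups
#' (the OR-gate rule); all diagonals are kept.
#'
#' @param space A `ci_space` enumerated under the T constraints (carries the
#'   supergroup index of each determinant).
#' @param ints An [integral_set()].
#' @param part A `split_partitioning` over the space's supergroup table.
#' @param sparse Passed to [build_hamiltonian()].
#' @return An `effective_hamiltonian`: `matrix`, logical `in_p` per
#'   determinant, `p_idx`, `q_idx`, and the inputs.
#' @export
build_effective_hamiltonian <- function(space, ints, part,
                                        sparse = space_size(space) > 400L) {
  stopifnot(!is.null(space$sg))
  H <- build_hamiltonian(space, ints, sparse = sparse)
  in_p <- part$ip[space$sg]
  Heff <- mask_qq_offdiag(H, in_p)
  structure(list(matrix = Heff, in_p = in_p, p_idx = which(in_p),
                 q_idx = which(!in_p), space = space, part = part),
            class = "effective_hamiltonian")
}

#' Second-order Loewdin downfolding
#'
#' Folds a Hamiltonian onto its P block at trial energy `E`:
#' `H~_ij(E) = H_ij + sum_{a in Q} H_ia H_aj / (E - H_aa)`. Only the QQ
#' diagonal enters, so the result is identical whether `H` is the full or the
#' effective (QQ-masked) matrix.
#'
#' @param H Symmetric matrix over P + Q (dense or sparse), or an
#'   `effective_hamiltonian`.
#' @param in_p Logical vector marking P members (ignored when `H` is an
#'   `effective_hamiltonian`).
#' @param E Trial energy (Hartree).
#' @param denom_tol Error if some `|E - H_aa|` falls below this.
#' @return A `downfolded_hamiltonian`: dense `matrix` of dimension `sum(in_p)`
#'   and the `trial_energy`.
#' @export
downfold <- function(H, in_p = NULL, E, denom_tol = 1e-10) {
  if (inherits(H, "effective_hamiltonian")) { in_p <- H$in_p; H <- H$matrix }
  p <- which(in_p); q <- which(!in_p)
  Hpp <- as.matrix(H[p, p, drop = FALSE])
  if (length(q) > 0L) {
    dq <- if (inherits(H, "sparseMatrix")) Matrix::diag(H)[q] else diag(H)[q]
    den <- E - dq
    if (any(abs(den) < denom_tol))
      stop(sprintf("downfold: singular denominator at Q configuration %d (|E - H_aa| = %.3g)",
                   q[which.min(abs(den))], min(abs(den))))
    Hpq <- as.matrix(H[p, q, drop = FALSE])
    Hpp <- Hpp + Hpq %*% (t(Hpq) / den)
  }
  structure(list(matrix = (Hpp + t(Hpp)) / 2, trial_energy = E),
            class = "downfolded_hamiltonian")
}

#' Self-consistent solution of the downfolded eigenproblem
#'
#' Iterates `E <- ` selected eigenvalue of `H~(E)` to its fixed point,
#' starting from the chosen eigenvalue of the bare P block. The followed root
#' is the eigenvector of maximal overlap with the previous iterate (not the
#' raw index), which prevents root flipping; 0.5 damping engages if the
#' iteration oscillates.
#'
#' @inheritParams downfold
#' @param root Index (1 = lowest) of the P-block eigenvalue to start from.
#' @param tol Convergence threshold on `|dE|` (Hartree).
#' @param max_iter Iteration cap.
#' @return List: `energy` (the fixed point E*), `vector` (P-space eigenvector),
#'   `iterations`, and the energy `trace`.
#' @export
solve_self_consistent_downfold <- function(H, in_p = NULL, root = 1L,
                                           tol = 1e-9, max_iter = 100L,
                                           denom_tol = 1e-10) {
  if (inherits(H, "effective_hamiltonian")) { in_p <- H$in_p; H <- H$matrix }
  p <- which(in_p)
  Hpp <- as.matrix(H[p, p, drop = FALSE])
  eg0 <- eigen((Hpp + t(Hpp)) / 2, symmetric = TRUE)
  ord0 <- order(eg0$values)
  E <- eg0$values[ord0[root]]
  v_prev <- eg0$vectors[, ord0[root]]
  if (all(in_p)) {
    return(list(energy = E, vector = fix_sign(v_prev), iterations = 1L, trace = E))
  }
  trace <- E
  damping <- 1
  for (it in seq_len(max_iter)) {
    df <- downfold(H, in_p, E, denom_tol = denom_tol)
    eg <- eigen(df$matrix, symmetric = TRUE)
    ov <- abs(crossprod(eg$vectors, v_prev))
    pick <- which.max(ov)
    E_new <- eg$values[pick]
    v_prev <- eg$vectors[, pick]
    dE <- E_new - E
    if (length(trace) >= 2L) {
      prev_step <- trace[length(trace)] - trace[length(trace) - 1L]
      if (prev_step * dE < 0) damping <- 0.5   # oscillation detected
    }
    E <- E + damping * dE
    trace <- c(trace, E)
    if (abs(dE) < tol)
      return(list(energy = E, vector = fix_sign(v_prev), iterations = it,
                  trace = trace))
  }
  stop("solve_self_consistent_downfold: no convergence in ", max_iter,
       " iterations; trace: ", paste(sprintf("%.8f", trace), collapse = " -> "))
}

fix_sign <- function(v) {
  k <- which.max(abs(v))
  if (v[k] < 0) -v else v
}

#' Lowest eigenpairs of a (sparse) symmetric matrix
#'
#' Dense diagonalization up to dimension 2000; above that, a Lanczos iteration
#' with full reorthogonalization (guarded at dimension 2e5). Eigenvectors are
#' normalized with the largest-magnitude entry fixed positive.
#'
#' @param H Symmetric matrix (base or `Matrix`), or an `effective_hamiltonian`.
#' @param n_roots Number of lowest eigenpairs.
#' @return List: `values` (ascending), `vectors` (columns).
#' @export
solve_exact <- function(H, n_roots = 1L) {
  if (inherits(H, "effective_hamiltonian")) H <- H$matrix
  d <- nrow(H)
  if (d > 2e5) stop("solve_exact: dimension ", d, " exceeds the 2e5 guard")
  if (d <= 2000L) {
    eg <- eigen(as.matrix((H + Matrix::t(H)) / 2), symmetric = TRUE)
    ord <- order(eg$values)[seq_len(min(n_roots, d))]
    vals <- eg$values[ord]
    vecs <- eg$vectors[, ord, drop = FALSE]
  } else {
    res <- lanczos_lowest(H, n_roots)
    vals <- res$values; vecs <- res$vectors
  }
  for (j in seq_len(ncol(vecs))) vecs[, j] <- fix_sign(vecs[, j])
  list(values = vals, vectors = vecs)
}

# Plain Lanczos with full reorthogonalization; adequate for the lowest few
# roots of the sparse desk-scale matrices this package builds.
lanczos_lowest <- function(H, n_roots, max_krylov = 200L, tol = 1e-10) {
  d <- nrow(H)
  set_len <- min(max_krylov, d)
  V <- matrix(0, d, set_len)
  v <- stats::rnorm(d); v <- v / sqrt(sum(v^2))
  V[, 1] <- v
  alpha <- numeric(set_len); beta <- numeric(set_len)
  prev_vals <- NULL
  for (k in seq_len(set_len)) {
    w <- as.numeric(H %*% V[, k])
    alpha[k] <- sum(w * V[, k])
    w <- w - alpha[k] * V[, k] - if (k > 1) beta[k - 1] * V[, k - 1] else 0
    w <- w - V[, seq_len(k), drop = FALSE] %*% crossprod(V[, seq_len(k), drop = FALSE], w)
    nb <- sqrt(sum(w^2))
    Tk <- diag(alpha[seq_len(k)], k)
    if (k > 1) {
      idx <- seq_len(k - 1)
      Tk[cbind(idx, idx + 1)] <- beta[idx]
      Tk[cbind(idx + 1, idx)] <- beta[idx]
    }
    eg <- eigen(Tk, symmetric = TRUE)
    vals <- sort(eg$values)[seq_len(min(n_roots, k))]
    if (!is.null(prev_vals) && length(prev_vals) == n_roots &&
        length(vals) == n_roots && max(abs(vals - prev_vals)) < tol) {
      ord <- order(eg$values)[seq_len(n_roots)]
      vecs <- V[, seq_len(k), drop = FALSE] %*% eg$vectors[, ord, drop = FALSE]
      return(list(values = eg$values[ord], vectors = vecs))
    }
    prev_vals <- vals
    if (nb < 1e-14 || k == set_len) {
      ord <- order(eg$values)[seq_len(min(n_roots, k))]
      vecs <- V[, seq_len(k), drop = FALSE] %*% eg$vectors[, ord, drop = FALSE]
      return(list(values = eg$values[ord], vectors = vecs))
    }
    beta[k] <- nb
    V[, k + 1] <- w / nb
  }
}
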