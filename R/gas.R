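#' Generalized active space (GAS) partition
#'
#' Splits the active orbitals into `k` disjoint subspaces G1..Gk with
#' user-chosen occupation constraints. Intra-subspace excitations are free;
#' inter-subspace excitations are restricted either by *local* bounds
#' `n_min[i] <= x_i <= n_max[i]` on each subspace occupation `x_i`, or by
#' *cumulative* bounds on the running sums `sum(x[1:i])`.
#'
#' @param subspaces List of disjoint integer vectors of orbital indices.
#' @param n_min,n_max Integer vectors of length `k`: occupation bounds (local
#'   flavor) or cumulative bounds (cumulative flavor).
#' @param n_elec_active Total electron count in the partitioned orbitals.
#' @param flavor `"local"` or `"cumulative"`.
#' @return A `gas_partition` object.
#' @export
gas_partition <- function(subspaces, n_min, n_max, n_elec_active,
                          flavor = c("local", "cumulative")) {
  flavor <- match.arg(flavor)
  subspaces <- lapply(subspaces, as.integer)
  k <- length(subspaces)
  all_orbs <- unlist(subspaces)
  if (anyDuplicated(all_orbs)) stop("gas_partition: subspaces are not disjoint")
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  n_elec_active <- as.integer(n_elec_active)
  stopifnot(length(n_min) == k, length(n_max) == k)
  cap <- 2L * lengths(subspaces)
  if (flavor == "local") {
    if (any(n_min < 0L) || any(n_min > n_max) || any(n_max > cap))
      stop("gas_partition: local bounds must satisfy 0 <= n_min <= n_max <= 2|G_i|")
  } else {
    if (any(diff(n_min) < 0L) || any(diff(n_max) < 0L))
      stop("gas_partition: cumulative bounds must be non-decreasing")
    if (n_min[k] != n_elec_active || n_max[k] != n_elec_active)
      stop("gas_partition: final cumulative bound must equal n_elec_active")
  }
  structure(list(subspaces = subspaces, n_min = n_min, n_max = n_max,
                 flavor = flavor, n_elec_active = n_elec_active, k = k,
                 capacity = cap),
            class = "gas_partition")
}

#' @export
print.gas_partition <- function(x, ...) {
  cat(sprintf("<gas_partition> %d subspaces, %d electrons, %s constraints\n",
              x$k, x$n_elec_active, x$flavor))
  for (i in seq_len(x$k))
    cat(sprintf("  G%d: orbitals {%s}, bounds [%d, %d]\n", i,
                paste(x$subspaces[[i]], collapse = ","), x$n_min[i], x$n_max[i]))
  invisible(x)
}

#' Enumerate compositions of N electrons over k subspaces
#'
#' All vectors `x` with nonnegative integer entries summing to `N`, listed in
#' decreasing lexicographic order; the row number is the composition index
#' `i_C` (starting at 1). The count is `choose(N + k - 1, k - 1)`.
#'
#' @param N Electron count (>= 0).
#' @param k Subspace count (>= 1).
#' @return Integer matrix with k columns, one composition per row.
#' @export
enumerate_compositions <- function(N, k) {
  N <- as.integer(N); k <- as.integer(k)
  stopifnot(N >= 0L, k >= 1L)
  if (k == 1L) return(matrix(N, 1L, 1L))
  rows <- vector("list", 0L)
  rec <- function(prefix, rem, slots) {
    if (slots == 1L) return(matrix(c(prefix, rem), nrow = 1L))
    do.call(rbind, lapply(rem:0L, function(x) rec(c(prefix, x), rem - x, slots - 1L)))
  }
  rec(integer(0), N, k)
}

# Constraint test for a composition matrix (rows) under a gas_partition.
composition_allowed <- function(comp, gas) {
  ok <- rep(TRUE, nrow(comp))
  cap <- gas$capacity
  for (i in seq_len(gas$k)) ok <- ok & comp[, i] <= cap[i]
  if (gas$flavor == "local") {
    for (i in seq_len(gas$k))
      ok <- ok & comp[, i] >= gas$n_min[i] & comp[, i] <= gas$n_max[i]
  } else {
    run <- t(apply(comp, 1L, cumsum))
    if (nrow(comp) == 1L) run <- matrix(cumsum(comp[1L, ]), 1L)
    for (i in seq_len(gas$k))
      ok <- ok & run[, i] >= gas$n_min[i] & run[, i] <= gas$n_max[i]
  }
  ok
}

#' Enumerate supergroups of a GAS partition
#'
#' Filters the compositions of `n_elec_active` electrons over the `k` subspaces
#' down to those satisfying the partition's constraints (the *supergroups*),
#' keeping the decreasing lexicographic order. Supergroups are re-indexed
#' `i_sg = 1, 2, ...` in that order.
#'
#' @param gas A [gas_partition()].
#' @return A `supergroup_table`: `compositions` matrix with index `i_C`,
#'   `supergroups` matrix with index `i_sg`, and maps between the two.
#' @export
enumerate_supergroups <- function(gas) {
  comp <- enumerate_compositions(gas$n_elec_active, gas$k)
  ok <- composition_allowed(comp, gas)
  if (!any(ok))
    stop("enumerate_supergroups: constraints admit no supergroup (infeasible model)")
  sg <- comp[ok, , drop = FALSE]
  ic_of_sg <- which(ok)
  isg_of_ic <- rep(NA_integer_, nrow(comp))
  isg_of_ic[ok] <- seq_len(nrow(sg))
  structure(list(compositions = comp, supergroups = sg,
                 ic_of_sg = ic_of_sg, isg_of_ic = isg_of_ic,
                 key = comp_key(sg, gas$n_elec_active),
                 N = gas$n_elec_active, k = gas$k, gas = gas),
            class = "supergroup_table")
}

#' @export
print.supergroup_table <- function(x, ...) {
  cat(sprintf("<supergroup_table> %d supergroups of %d compositions (N=%d, k=%d)\n",
              nrow(x$supergroups), nrow(x$compositions), x$N, x$k))
  invisible(x)
}

# Base-(N+1) key of composition rows for O(1)-ish lookup via match().
comp_key <- function(comp, N) {
  base <- N + 1
  as.numeric(comp %*% base^(seq_len(ncol(comp)) - 1))
}

#' Supergroup index of an occupation vector
#'
#' @param occupations Integer vector (one composition) or matrix of rows.
#' @param table A `supergroup_table`.
#' @return Integer `i_sg` per row; `NA` where the composition violates the
#'   constraints. Errors if a row does not sum to N.
#' @export
supergroup_of <- function(occupations, table) {
  occ <- if (is.matrix(occupations)) occupations else matrix(occupations, 1L)
  if (any(rowSums(occ) != table$N))
    stop("supergroup_of: occupations must sum to ", table$N)
  idx <- supergroup_index_of(occ, table)
  if (is.matrix(occupations)) idx else idx[1L]
}

# No sum validation (internal hot path); NA for non-supergroups.
supergroup_index_of <- function(occ, table) {
  match(comp_key(occ, table$N), table$key)
}

#' Classify a one- or two-electron inter-subspace move
#'
#' Applies composition arithmetic to the source supergroup: remove one electron
#' per entry of `holes`, add one per entry of `particles`, then look the result
#' up. A move whose target composition is negative, exceeds a subspace
#' capacity, or fails the constraints is *forbidden* (returned as `NA`), not an
#' error.
#'
#' @param i_sg Source supergroup index.
#' @param holes,particles Subspace indices the electrons leave / enter
#'   (length 1 or 2, equal lengths).
#' @param table A `supergroup_table`.
#' @return Target `i_sg`, or `NA` if the excitation is GAS-forbidden.
#' @export
classify_excitation <- function(i_sg, holes, particles, table) {
  stopifnot(length(holes) == length(particles), length(holes) %in% 1:2)
  x <- table$supergroups[i_sg, ]
  for (s in holes) x[s] <- x[s] - 1L
  for (s in particles) x[s] <- x[s] + 1L
  if (any(x < 0L) || any(x > table$gas$capacity)) return(NA_integer_)
  supergroup_index_of(matrix(x, 1L), table)
}

#' Supergroups of a difference-dedicated CI (DDCI) space
#'
#' Encodes the DDCI hierarchy over three subspaces -- GAS1 (`n_o` inactive
#' doubly occupied orbitals), GAS2 (`n_a` active orbitals, `N_a` electrons),
#' GAS3 (`n_v` virtuals) -- as the supergroup set
#' `[2 n_o - n_h, N_a + n_h - m_p, m_p]` over hole/particle class counts
#' `(n_h, m_p)`. Level 1 (DDCI1 / CAS+S) keeps classes with `n_h + m_p <= 1`
#' plus `1h+1p`; level 2 adds `2h` and `2p`; level 3 (DDCI) adds `1h+2p` and
#' `2h+1p` -- every class in `{0,1,2}^2` except the pure `2h+2p` doubles.
#'
#' @param n_o,n_a,N_a,n_v Orbital/electron counts of the three subspaces.
#' @param level DDCI truncation level, 1, 2 or 3.
#' @return A `supergroup_table` over `N = 2 n_o + N_a` electrons, k = 3.
#' @export
ddci_supergroups <- function(n_o, n_a, N_a, n_v, level = 3L) {
  stopifnot(n_o >= 0, n_a >= 0, N_a >= 0, n_v >= 0, level %in% 1:3)
  classes <- switch(level,
    `1` = list(c(0L,0L), c(1L,0L), c(0L,1L), c(1L,1L)),
    `2` = list(c(0L,0L), c(1L,0L), c(0L,1L), c(1L,1L), c(2L,0L), c(0L,2L)),
    `3` = list(c(0L,0L), c(1L,0L), c(0L,1L), c(1L,1L), c(2L,0L), c(0L,2L),
               c(1L,2L), c(2L,1L)))
  N <- 2L * n_o + N_a
  cap <- c(2L * n_o, 2L * n_a, 2L * n_v)
  rows <- unique(do.call(rbind, lapply(classes, function(cl) {
    nh <- cl[1]; mp <- cl[2]
    c(2L * n_o - nh, N_a + nh - mp, mp)
  })))
  rows <- rows[apply(rows, 1L, function(x) all(x >= 0L & x <= cap)), , drop = FALSE]
  gas <- gas_partition(
    subspaces = list(seq_len(n_o),
                     n_o + seq_len(n_a),
                     n_o + n_a + seq_len(n_v)),
    n_min = c(0L, 0L, 0L), n_max = cap, n_elec_active = N, flavor = "local")
  comp <- enumerate_compositions(N, 3L)
  key <- comp_key(comp, N)
  ok <- key %in% comp_key(rows, N)
  sg <- comp[ok, , drop = FALSE]
  isg_of_ic <- rep(NA_integer_, nrow(comp))
  isg_of_ic[ok] <- seq_len(nrow(sg))
  structure(list(compositions = comp, supergroups = sg,
                 ic_of_sg = which(ok), isg_of_ic = isg_of_ic,
                 key = comp_key(sg, N), N = N, k = 3L, gas = gas),
            class = "supergroup_table")
}
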