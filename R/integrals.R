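#' Molecular integral container
#'
#' Holds the electronic-structure Hamiltonian in second-quantized form: a scalar
#' core energy, the one-electron matrix `h[i, j]` and the two-electron tensor
#' `g[i, j, k, l]` in chemist's notation (ij|kl), all in Hartree. `h` is
#' symmetric and `g` carries the 8-fold permutational symmetry
#' (i<->j), (k<->l), (ij<->kl).
#'
#' @param n_orb Number of spatial orbitals.
#' @param n_elec Number of electrons.
#' @param ms2 Twice the spin projection (2*Ms).
#' @param e_core Scalar energy offset (Hartree).
#' @param h `n_orb` x `n_orb` symmetric matrix of one-electron integrals.
#' @param g Four-index array of two-electron integrals, chemist's notation.
#' @return An object of class `integral_set`.
#' @export
integral_set <- function(n_orb, n_elec, ms2 = 0L, e_core = 0,
                         h = matrix(0, n_orb, n_orb),
                         g = array(0, rep(n_orb, 4))) {
  n_orb <- as.integer(n_orb)
  n_elec <- as.integer(n_elec)
  stopifnot(n_orb >= 1L, n_elec >= 0L, n_elec <= 2L * n_orb)
  h <- as.matrix(h)
  stopifnot(identical(dim(h), c(n_orb, n_orb)), identical(dim(g), rep(n_orb, 4L)))
  if (!all(is.finite(h)) || !all(is.finite(g)) || !is.finite(e_core))
    stop("integral_set: non-finite values")
  if (max(abs(h - t(h))) > 1e-12)
    stop("integral_set: h is not symmetric")
  obj <- structure(
    list(n_orb = n_orb, n_elec = n_elec, ms2 = as.integer(ms2),
         e_core = as.numeric(e_core), h = h, g = g),
    class = "integral_set")
  chk <- check_g_symmetry(obj)
  if (chk > 1e-12)
    stop(sprintf("integral_set: g violates 8-fold permutation symmetry (max dev %.3g)", chk))
  obj
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("<integral_set> %d orbitals, %d electrons, 2Ms = %d\n",
              x$n_orb, x$n_elec, x$ms2))
  cat(sprintf("  e_core = %.10f Ha, %d nonzero h, %d nonzero g entries\n",
              x$e_core, sum(x$h != 0), sum(x$g != 0)))
  invisible(x)
}

# Max deviation of g from its 8-fold symmetry group.
check_g_symmetry <- function(ints) {
  g <- ints$g
  max(max(abs(g - aperm(g, c(2, 1, 3, 4)))),
      max(abs(g - aperm(g, c(1, 2, 4, 3)))),
      max(abs(g - aperm(g, c(3, 4, 1, 2)))))
}

# Assign value to all 8 permutation-equivalent g slots (in place, returns g).
g_set_sym <- function(g, i, j, k, l, val) {
  g[i, j, k, l] <- val; g[j, i, k, l] <- val
  g[i, j, l, k] <- val; g[j, i, l, k] <- val
  g[k, l, i, j] <- val; g[l, k, i, j] <- val
  g[k, l, j, i] <- val; g[l, k, j, i] <- val
  g
}

#' Read an FCIDUMP integral file
#'
#' Parses the standard FCIDUMP text interchange format: a namelist-style header
#' declaring at least `NORB`, `NELEC` and `MS2`, terminated by `&END` or `/`,
#' followed by `value i j k l` records with 1-based orbital indices. Records
#' with `k = l = 0` carry one-electron integrals `h[i, j]`; the record with all
#' four indices zero carries the core energy. All 8 permutations of each
#' two-electron record are populated; unlisted entries are zero. `ORBSYM`/`ISYM`
#' fields are accepted and ignored (C1 symmetry throughout).
#'
#' @param path Path to an FCIDUMP file.
#' @return An [integral_set()].
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("read_fcidump: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # header: everything up to the &END or / terminator (possibly multi-line)
  end_line <- grep("(&END|^\\s*/\\s*$|[^&]/\\s*$)", toupper(lines))[1]
  if (is.na(end_line)) stop("read_fcidump: malformed header (no &END or / terminator)")
  header <- paste(lines[seq_len(end_line)], collapse = " ")
  get_field <- function(name) {
    m <- regmatches(header, regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header,
                                    ignore.case = TRUE))
    if (length(m) == 0) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  n_orb <- get_field("NORB"); n_elec <- get_field("NELEC"); ms2 <- get_field("MS2")
  if (is.na(n_orb) || is.na(n_elec))
    stop("read_fcidump: malformed header (need NORB and NELEC)")
  if (is.na(ms2)) ms2 <- 0L

  h <- matrix(0, n_orb, n_orb)
  g <- array(0, rep(n_orb, 4L))
  e_core <- 0
  body <- lines[-seq_len(end_line)]
  for (li in seq_along(body)) {
    ln <- trimws(body[li])
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) != 5L)
      stop(sprintf("read_fcidump: line %d: expected 'value i j k l', got '%s'",
                   end_line + li, ln))
    val <- suppressWarnings(as.numeric(sub("[dD]", "e", toks[1])))
    idx <- suppressWarnings(as.integer(toks[2:5]))
    if (is.na(val) || anyNA(idx))
      stop(sprintf("read_fcidump: line %d: non-numeric field", end_line + li))
    if (any(idx < 0L) || any(idx > n_orb))
      stop(sprintf("read_fcidump: line %d: orbital index out of [0, %d]",
                   end_line + li, n_orb))
    i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
    if (i == 0L && j == 0L && k == 0L && l == 0L) {
      e_core <- val
    } else if (k == 0L && l == 0L) {
      if (i == 0L || j == 0L)
        stop(sprintf("read_fcidump: line %d: bad one-electron indices", end_line + li))
      h[i, j] <- val; h[j, i] <- val
    } else {
      if (any(idx == 0L))
        stop(sprintf("read_fcidump: line %d: bad two-electron indices", end_line + li))
      g <- g_set_sym(g, i, j, k, l, val)
    }
  }
  integral_set(n_orb, n_elec, ms2, e_core, h, g)
}

#' Write an FCIDUMP integral file
#'
#' Emits one canonical representative per 8-fold permutation class (i >= j,
#' k >= l, composite index ij >= kl), skipping entries whose magnitude is below
#' `threshold`, then one-electron records (i >= j), then the core-energy record.
#'
#' @param ints An [integral_set()].
#' @param path Output file path.
#' @param threshold Entries with magnitude below this are omitted (default 1e-12).
#' @export
write_fcidump <- function(ints, path, threshold = 1e-12) {
  stopifnot(inherits(ints, "integral_set"))
  n <- ints$n_orb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, ints$n_elec, ints$ms2),
               sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")),
               " ISYM=1,", "&END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%.16E %4d %4d %4d %4d", v, i, j, k, l)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ij <- i * (i - 1L) / 2L + j
    for (k in seq_len(i)) for (l in seq_len(k)) {
      kl <- k * (k - 1L) / 2L + l
      if (kl > ij) next
      v <- ints$g[i, j, k, l]
      if (abs(v) >= threshold) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i))
    if (abs(ints$h[i, j]) >= threshold) out <- c(out, fmt(ints$h[i, j], i, j, 0L, 0L))
  out <- c(out, fmt(ints$e_core, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Hubbard-chain integral set
#'
#' One-band Hubbard model at half filling: hopping `-t` between neighboring
#' sites (wrapping around if `periodic`) and on-site repulsion `U` as the only
#' two-electron integral, `g[i,i,i,i] = U`. Known exact solutions at small size
#' make this the standard correctness fixture; the dimer singlet ground state
#' has energy `(U - sqrt(U^2 + 16 t^2)) / 2`.
#'
#' @param n_sites Number of sites (>= 1).
#' @param t Hopping amplitude (Hartree).
#' @param U On-site repulsion (Hartree).
#' @param periodic Wrap the chain into a ring?
#' @param n_elec Electron count (default half filling, `n_sites`).
#' @return An [integral_set()] with `ms2 = n_elec %% 2`.
#' @export
make_hubbard <- function(n_sites, t = 1, U = 4, periodic = FALSE,
                         n_elec = n_sites) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("make_hubbard: n_sites must be >= 1")
  h <- matrix(0, n_sites, n_sites)
  g <- array(0, rep(n_sites, 4L))
  if (n_sites >= 2L) {
    for (i in seq_len(n_sites - 1L)) h[i, i + 1L] <- h[i + 1L, i] <- -t
    if (periodic && n_sites > 2L) h[1L, n_sites] <- h[n_sites, 1L] <- -t
  }
  for (i in seq_len(n_sites)) g[i, i, i, i] <- U
  integral_set(n_sites, n_elec, ms2 = n_elec %% 2L, e_core = 0, h = h, g = g)
}

#' Random Hermitian integral set
#'
#' Draws a reproducible random integral set whose symmetry invariants hold by
#' construction. The one-electron diagonal is spread (orbital i sits at
#' `(i - 1) * diag_spread`), so the spectrum is bounded and the aufbau
#' Hartree-product reference dominates the ground state, as in a typical
#' molecular problem near equilibrium. `sparsity` is the probability that an
#' off-diagonal canonical integral class is zeroed; at `sparsity = 1` only the
#' diagonal `h[i,i]` and `g[i,i,i,i]` survive.
#'
#' @param n_orb,n_elec Orbital and electron counts.
#' @param seed Integer seed; same seed gives an identical set.
#' @param scale Standard deviation of off-diagonal integrals (Hartree).
#' @param sparsity Fraction in `[0, 1]` of off-diagonal classes zeroed.
#' @param diag_spread Spacing of the one-electron diagonal (Hartree).
#' @param ms2 Twice the spin projection.
#' @return An [integral_set()].
#' @export
make_random_integrals <- function(n_orb, n_elec, seed = 1L, scale = 0.1,
                                  sparsity = 0, diag_spread = 1, ms2 = 0L) {
  stopifnot(sparsity >= 0, sparsity <= 1)
  n <- as.integer(n_orb)
  h <- matrix(0, n, n)
  g <- array(0, rep(n, 4L))
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    h[i, i] <- (i - 1) * diag_spread + 0.05 * scale * stats::rnorm(1)
    g[i, i, i, i] <- abs(stats::rnorm(1, mean = 2 * scale, sd = scale))
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ij <- i * (i - 1L) / 2L + j
    for (k in seq_len(i)) for (l in seq_len(k)) {
      kl <- k * (k - 1L) / 2L + l
      if (kl > ij) next
      if (i == j && j == k && k == l) next  # diagonal handled above
      v <- scale * stats::rnorm(1)
      keep <- stats::runif(1) >= sparsity
      if (keep) g <- g_set_sym(g, i, j, k, l, v)
    }
    if (i != j) {
      v <- 0.5 * scale * stats::rnorm(1)
      if (stats::runif(1) >= sparsity) h[i, j] <- h[j, i] <- v
    }
  }
  integral_set(n, n_elec, ms2 = ms2, e_core = 0, h = h, g = g)
}
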