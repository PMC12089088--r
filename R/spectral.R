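# Hueckel adjacency-spectrum energetics.  All quantities are in beta
# (resonance-integral) units: the eigenvalue lambda enters the orbital
# energy as alpha + lambda beta, so the occupied orbitals are the p/2
# largest eigenvalues for a p-atom closed-shell system.

#' Adjacency spectrum
#'
#' @param g a nonempty [MolecularGraph-class]
#' @return numeric vector of all adjacency eigenvalues, ascending.  For
#'   bipartite graphs the spectrum is symmetric about zero
#'   (Coulson-Rushbrooke pairing).
#' @export
adjacencySpectrum <- function(g) {
  if (nAtoms(g) == 0L) stop("empty graph has no spectrum")
  A <- adjacencyMatrix(g)
  sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

#' Total pi-electron energy
#'
#' Twice the sum of the occupied (largest p/2) eigenvalues for even atom
#' count p; for odd p the singly occupied middle level contributes once.
#'
#' @param spectrum full adjacency spectrum (any order)
#' @param p atom count; must equal \code{length(spectrum)}
#' @return energy in beta units
#' @export
totalPiEnergy <- function(spectrum, p = length(spectrum)) {
  stopifnot(length(spectrum) == p)
  dsc <- sort(spectrum, decreasing = TRUE)
  if (p %% 2L == 0L) {
    2 * sum(dsc[seq_len(p / 2)])
  } else {
    h <- (p - 1L) / 2L
    dsc[h + 1L] + 2 * sum(dsc[seq_len(h)])
  }
}

#' HOMO-LUMO gap
#'
#' Frontier levels are selected by rank: with the spectrum sorted
#' descending, HOMO is the eigenvalue at rank p/2 and LUMO at rank
#' p/2 + 1 (rank selection avoids sign-threshold failures near zero
#' eigenvalues).  For bipartite systems the gap equals 2 HOMO.
#'
#' @inheritParams totalPiEnergy
#' @return named numeric vector \code{c(homo, lumo, gap)} in beta units
#' @export
homoLumoGap <- function(spectrum, p = length(spectrum)) {
  stopifnot(length(spectrum) == p, p >= 2)
  dsc <- sort(spectrum, decreasing = TRUE)
  if (p %% 2L == 1L)
    warning("odd atom count: frontier levels flank the singly occupied level")
  h <- floor(p / 2)
  c(homo = dsc[h], lumo = dsc[h + 1L], gap = dsc[h] - dsc[h + 1L])
}

#' Spectral diameter
#'
#' @param spectrum nonempty eigenvalue vector
#' @return lambda_max - lambda_min in beta units
#' @export
spectralDiameter <- function(spectrum) {
  stopifnot(length(spectrum) >= 1)
  max(spectrum) - min(spectrum)
}

#' Per-atom energies
#'
#' The published energetics table divides by the vertex count; the energy
#' per atom is E_pi / p and the delocalization energy per atom is
#' (E_pi - p) / p (each of the p carbons contributes one localized
#' pi electron of energy beta).
#'
#' @param ePi total pi-electron energy
#' @param p atom count
#' @return named numeric vector \code{c(ePiPerAtom, delocPerAtom)}
#' @export
perAtomEnergies <- function(ePi, p) {
  stopifnot(p > 0)
  c(ePiPerAtom = ePi / p, delocPerAtom = (ePi - p) / p)
}

# biadjacency matrix of a bipartite graph with equal colour classes
.biadjacency <- function(g) {
  cls <- bipartiteClasses(g)
  A <- matrix(0L, nAtoms(g), nAtoms(g))
  A[g@bonds] <- 1L; A[g@bonds[, c(2, 1)]] <- 1L
  A[cls == 0L, cls == 1L, drop = FALSE]
}

# fraction-free (Bareiss) determinant over the integers, carried in double
# precision; every intermediate is a minor of the input, so for a 0/1
# matrix with row norms <= sqrt(3) all values stay below 3^(n/2).  The
# guard refuses inputs where exactness is no longer certain.
.bareiss_det <- function(M) {
  n <- nrow(M)
  M <- M * 1.0
  if (n == 0L) return(1)
  sign <- 1; prev <- 1
  for (k in seq_len(n - 1L)) {
    if (M[k, k] == 0) {
      j <- which(M[k:n, k] != 0)[1]
      if (is.na(j)) return(0)
      j <- j + k - 1L
      tmp <- M[k, ]; M[k, ] <- M[j, ]; M[j, ] <- tmp
      sign <- -sign
    }
    rows <- (k + 1L):n; cols <- (k + 1L):n
    M[rows, cols] <- (M[k, k] * M[rows, cols] -
                      outer(M[rows, k], M[k, cols])) / prev
    M[rows, k] <- 0
    if (max(abs(M[rows, cols])) >= 2^53)
      stop("matrix too large for exact integer elimination")
    prev <- M[k, k]
  }
  sign * M[n, n]
}

# determinant modulo a prime (double-precision safe for p < 2^26)
.det_mod <- function(M, p) {
  n <- nrow(M)
  M <- M %% p
  det <- 1
  inv_mod <- function(a, p) {   # Fermat, p prime
    r <- 1; b <- a %% p; e <- p - 2
    while (e > 0) {
      if (e %% 2 == 1) r <- (r * b) %% p
      b <- (b * b) %% p
      e <- e %/% 2
    }
    r
  }
  for (k in seq_len(n)) {
    piv <- which(M[k:n, k] != 0)[1]
    if (is.na(piv)) return(0)
    piv <- piv + k - 1L
    if (piv != k) {
      tmp <- M[k, ]; M[k, ] <- M[piv, ]; M[piv, ] <- tmp
      det <- (p - det) %% p
    }
    det <- (det * M[k, k]) %% p
    if (k < n) {
      inv <- inv_mod(M[k, k], p)
      rows <- (k + 1L):n
      fac <- (M[rows, k] * inv) %% p
      M[rows, ] <- (M[rows, , drop = FALSE] -
                    outer(fac, M[k, ])) %% p
    }
  }
  det
}

#' Kekule structure count
#'
#' For a bipartite benzenoid the number of Kekule (perfect-matching)
#' resonance structures is the square root of the absolute constant term
#' of the characteristic polynomial, i.e. sqrt(|det A|).  With a bipartite
#' two-colouring, |det A| = det(B)^2 for the biadjacency matrix B, so the
#' count is obtained as |det B| by exact fraction-free integer elimination
#' and verified against det A modulo two large primes.  For graphs beyond
#' the exact-arithmetic range (about 132 atoms for degree-3 skeletons) the
#' natural log of the count is still available through
#' \code{method = "logdet"} (LU in floating point, accurate to ~1e-12
#' relative), which is what the resonance energy needs.
#'
#' @param g a bipartite [MolecularGraph-class] with even atom count
#' @param method \code{"auto"} (exact when feasible, else logdet),
#'   \code{"exact"} or \code{"logdet"}
#' @return list with \code{count} (exact integer as numeric, or NA for
#'   logdet-only results) and \code{logCount} (natural log, always)
#' @examples
#' kekuleCount(coroneneUnit())$count   # 20
#' @export
kekuleCount <- function(g, method = c("auto", "exact", "logdet")) {
  method <- match.arg(method)
  if (nAtoms(g) %% 2L != 0L)
    stop("odd atom count: no perfect matching exists")
  B <- .biadjacency(g)
  if (nrow(B) != ncol(B)) return(list(count = 0, logCount = -Inf))
  if (method == "auto")
    method <- if (nrow(B) <= 66L) "exact" else "logdet"
  if (method == "exact") {
    detB <- .bareiss_det(B)
    kc <- abs(detB)
    if (kc != round(kc)) stop("non-integer determinant (internal error)")
    # verify KC^2 = |det A| via the characteristic-polynomial route,
    # modulo primes (|det A| itself overflows doubles long before KC does)
    A <- adjacencyMatrix(g)
    for (p in c(33554393, 33550337)) {
      lhs <- .det_mod(A, p)
      rhs <- ((kc %% p) * (kc %% p)) %% p
      if (lhs != rhs && lhs != (p - rhs) %% p)
        stop("Kekule count check failed: det A is not the square of det B")
    }
    list(count = kc, logCount = if (kc > 0) log(kc) else -Inf)
  } else {
    d <- determinant(B * 1.0, logarithm = TRUE)
    list(count = NA_real_, logCount = as.numeric(d$modulus))
  }
}

#' Herndon resonance energy per atom
#'
#' @param kc Kekule count (>= 1), or alternatively supply \code{logKc}
#' @param p atom count
#' @param logKc natural log of the Kekule count, for counts beyond exact
#'   range
#' @return 1.185 ln(KC) / p in beta units
#' @export
resonancePerAtom <- function(kc = NULL, p, logKc = NULL) {
  if (is.null(logKc)) {
    if (is.null(kc) || is.na(kc) || kc < 1)
      stop("Kekule count must be a positive integer (or supply logKc)")
    logKc <- log(kc)
  }
  1.185 * logKc / p
}

#' Full spectral report
#'
#' Diagonalizes the adjacency matrix and assembles every energetic
#' descriptor of the published table: total pi-electron energy, frontier
#' levels and gap, spectral diameter, per-atom energies, Kekule count and
#' Herndon resonance energy.
#'
#' @param g a [MolecularGraph-class]
#' @param kekule \code{"auto"} (default), \code{"exact"}, \code{"logdet"}
#'   or \code{"none"} to skip the determinant work
#' @return a [SpectralReport-class]
#' @export
spectralReport <- function(g, kekule = c("auto", "exact", "logdet", "none")) {
  kekule <- match.arg(kekule)
  p <- nAtoms(g)
  ev <- adjacencySpectrum(g)
  ePi <- totalPiEnergy(ev, p)
  hl <- homoLumoGap(ev, p)
  pa <- perAtomEnergies(ePi, p)
  if (kekule == "none") {
    kc <- NA_real_; lkc <- NA_real_; re <- NA_real_
  } else {
    k <- kekuleCount(g, method = kekule)
    kc <- k$count; lkc <- k$logCount
    re <- resonancePerAtom(p = p, logKc = lkc)
  }
  new("SpectralReport", eigenvalues = ev, ePi = ePi,
      homo = unname(hl["homo"]), lumo = unname(hl["lumo"]),
      gap = unname(hl["gap"]), spectralDiameter = spectralDiameter(ev),
      ePiPerAtom = unname(pa["ePiPerAtom"]),
      delocPerAtom = unname(pa["delocPerAtom"]),
      kekuleCount = kc, kekuleLog = lkc, resonancePerAtom = re)
}

setMethod("show", "SpectralReport", function(object) {
  p <- length(object@eigenvalues)
  cat(sprintf("SpectralReport (%d atoms)\n", p))
  cat(sprintf("  E_pi               %12.4f beta\n", object@ePi))
  cat(sprintf("  HOMO-LUMO gap      %12.5f beta\n", object@gap))
  cat(sprintf("  E_pi per atom      %12.4f beta\n", object@ePiPerAtom))
  cat(sprintf("  deloc per atom     %12.6f beta\n", object@delocPerAtom))
  if (!is.na(object@kekuleLog))
    cat(sprintf("  Kekule count       %s (ln = %.4f)\n",
                if (is.na(object@kekuleCount)) "(beyond exact range)"
                else format(object@kekuleCount, big.mark = ","),
                object@kekuleLog))
  if (!is.na(object@resonancePerAtom))
    cat(sprintf("  resonance per atom %12.6f beta\n", object@resonancePerAtom))
  cat(sprintf("  spectral diameter  %12.5f beta\n", object@spectralDiameter))
})

#' Energetics table for a set of fractals
#'
#' One row per structure with the columns of the published energetics
#' table.  Kekule counts switch to the floating log-determinant beyond the
#' exact-arithmetic range, which only affects the resonance-energy column
#' at the 1e-12 relative level.
#'
#' @param specs list of [FractalSpec-class] objects
#' @return data.frame with one row per spec
#' @export
spectralTable <- function(specs) {
  rows <- lapply(specs, function(sp) {
    g <- generateFractal(sp)
    r <- spectralReport(g)
    data.frame(structure = .spec_label(sp), nAtoms = nAtoms(g),
               ePi = r@ePi, gap = r@gap, ePiPerAtom = r@ePiPerAtom,
               delocPerAtom = r@delocPerAtom,
               resonancePerAtom = r@resonancePerAtom,
               spectralDiameter = r@spectralDiameter)
  })
  do.call(rbind, rows)
}
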