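#' @import methods
NULL

#' MolecularGraph: a simple molecular graph
#'
#' Carbon-skeleton graph used throughout the package: a simple undirected
#' graph whose vertices are atoms and whose edges are sigma bonds.  Atom ids
#' are dense integers \code{1..nAtoms(x)}.  Generated fractals additionally
#' carry 2D coordinates in bond-length units and a family tag.
#'
#' @slot bonds integer matrix with two columns; each row one bond, endpoint
#'   ids sorted ascending within the row, no duplicate rows, no self loops.
#' @slot nAtoms number of atoms; every id appearing in \code{bonds} is in
#'   \code{1..nAtoms}.
#' @slot coords numeric matrix (nAtoms x 2) of 2D positions in bond-length
#'   units, or a 0-row matrix when coordinates are absent.
#' @slot familyTag optional provenance label such as \code{"ZHCF(2)"};
#'   \code{NA} for graphs read from files.
#'
#' @seealso [molecularGraph()], [edgePartition()], [adjacencyMatrix()]
#' @export
setClass("MolecularGraph",
  slots = c(bonds = "matrix", nAtoms = "integer",
            coords = "matrix", familyTag = "character"),
  prototype = prototype(
    bonds = matrix(integer(0), 0, 2), nAtoms = 0L,
    coords = matrix(numeric(0), 0, 2), familyTag = NA_character_))

setValidity("MolecularGraph", function(object) {
  b <- object@bonds
  msg <- character(0)
  if (ncol(b) != 2L) msg <- c(msg, "bonds must have two columns")
  if (nrow(b) > 0) {
    if (!is.integer(b)) msg <- c(msg, "bond endpoints must be integers")
    if (any(b[, 1] == b[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (any(b[, 1] > b[, 2])) msg <- c(msg, "bond rows must be sorted ascending")
    if (anyDuplicated(paste(b[, 1], b[, 2]))) msg <- c(msg, "duplicate bonds")
    if (min(b) < 1L || max(b) > object@nAtoms)
      msg <- c(msg, "bond endpoint outside 1..nAtoms")
  }
  if (nrow(object@coords) > 0 && nrow(object@coords) != object@nAtoms)
    msg <- c(msg, "coords must have one row per atom")
  if (length(msg)) msg else TRUE
})

#' FractalSpec: family and size of a coronene fractal
#'
#' Identifies one member of the three coronene-fractal families:
#' \describe{
#'   \item{ZHCF(n)}{zigzag hexagonal: coronene units on the zigzag hexagonal
#'     benzenoid series (benzene, coronene, circumcoronene, ...).}
#'   \item{AHCF(n)}{armchair hexagonal: units on the armchair series
#'     (benzene, hexabenzocoronene, ...).}
#'   \item{RCF(m,n)}{rectangular: units on n stacked rows of m linearly
#'     fused hexagons joined by perylene-type junctions.}
#' }
#' \code{m} is only meaningful for RCF and is ignored (stored as \code{NA})
#' for the hexagonal families.
#'
#' @slot family one of \code{"ZHCF"}, \code{"AHCF"}, \code{"RCF"}.
#' @slot n positive integer size (rows for RCF).
#' @slot m positive integer, hexagons per row (RCF only).
#' @seealso [fractalSpec()], [generateFractal()], [closedFormCounts()]
#' @export
setClass("FractalSpec",
  slots = c(family = "character", n = "integer", m = "integer"))

setValidity("FractalSpec", function(object) {
  msg <- character(0)
  if (!object@family %in% c("ZHCF", "AHCF", "RCF"))
    msg <- c(msg, "family must be one of ZHCF, AHCF, RCF")
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "n must be a positive integer")
  if (object@family == "RCF" &&
      (length(object@m) != 1L || is.na(object@m) || object@m < 1L))
    msg <- c(msg, "m must be a positive integer for RCF")
  if (length(msg)) msg else TRUE
})

#' EntropyReport: index-weighted graph entropy of one molecular graph
#'
#' Holds the topological index value TI, the edge-weighted Shannon entropy
#' in bits, the maximum entropy log2(TI), log2 of the bond count, and the
#' two normalized complexity measures SIC (entropy / log2 TI) and BIC
#' (entropy / log2 |E|).
#'
#' @slot indexName name of the index in the catalog (e.g. \code{"M1"}).
#' @slot k shift parameter of the modified reverse degree.
#' @slot tiValue the index value TI.
#' @slot entropyBits entropy in bits.
#' @slot maxEntropyBits log2(TI).
#' @slot log2Edges log2 of the bond count.
#' @slot nEdges bond count.
#' @seealso [graphEntropy()], [sic()], [bic()]
#' @export
setClass("EntropyReport",
  slots = c(indexName = "character", k = "integer", tiValue = "numeric",
            entropyBits = "numeric", maxEntropyBits = "numeric",
            log2Edges = "numeric", nEdges = "numeric"))

setValidity("EntropyReport", function(object) {
  msg <- character(0)
  if (object@entropyBits < 0) msg <- c(msg, "entropy must be non-negative")
  if (object@entropyBits > object@log2Edges + 1e-9)
    msg <- c(msg, "entropy exceeds log2 of the bond count")
  if (length(msg)) msg else TRUE
})

#' SpectralReport: Hueckel adjacency-spectrum energetics
#'
#' All quantities are in beta (Hueckel resonance-integral) units and derive
#' from the eigenvalues of the 0/1 adjacency matrix.
#'
#' @slot eigenvalues full adjacency spectrum, ascending.
#' @slot ePi total pi-electron energy, twice the sum of the occupied
#'   (largest p/2) eigenvalues for even atom count p.
#' @slot homo,lumo frontier eigenvalues at ranks p/2 and p/2 + 1 from the
#'   top of the spectrum.
#' @slot gap HOMO-LUMO gap \code{homo - lumo} (>= 0).
#' @slot spectralDiameter lambda_max - lambda_min.
#' @slot ePiPerAtom ePi / p (the per-bond column of the energetics table).
#' @slot delocPerAtom (ePi - p) / p, delocalization energy per atom.
#' @slot kekuleCount exact number of Kekule structures, sqrt of |det A|;
#'   \code{NA} when the graph is too large for exact integer elimination.
#' @slot kekuleLog natural log of the Kekule count (always available).
#' @slot resonancePerAtom Herndon resonance energy 1.185 ln(KC) / p.
#' @seealso [spectralReport()], [kekuleCount()]
#' @export
setClass("SpectralReport",
  slots = c(eigenvalues = "numeric", ePi = "numeric", homo = "numeric",
            lumo = "numeric", gap = "numeric", spectralDiameter = "numeric",
            ePiPerAtom = "numeric", delocPerAtom = "numeric",
            kekuleCount = "numeric", kekuleLog = "numeric",
            resonancePerAtom = "numeric"))

setValidity("SpectralReport", function(object) {
  msg <- character(0)
  if (abs(sum(object@eigenvalues)) > 1e-6 * max(1, length(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must sum to zero (trace of A)")
  if (object@gap < -1e-9) msg <- c(msg, "gap must be non-negative")
  if (object@spectralDiameter < object@gap - 1e-9)
    msg <- c(msg, "spectral diameter cannot be below the gap")
  if (length(msg)) msg else TRUE
})

#' RegressionModel: univariate linear structure-property model
#'
#' Ordinary least squares fit P = R x + c of a spectral property P against
#' a single index or entropy descriptor x, with the usual summary
#' statistics.
#'
#' @slot slope,intercept coefficients R and c.
#' @slot r2,adjR2 coefficient of determination and its small-sample
#'   adjustment 1 - (1 - r2)(n - 1)/(n - 2).
#' @slot se residual standard error sqrt(RSS / (n - 2)).
#' @slot fStat F statistic r2 (n - 2) / (1 - r2).
#' @slot nObs number of observations.
#' @slot property,descriptor names of the response and the descriptor.
#' @slot xRange descriptor range seen during fitting (used to flag
#'   extrapolation in [predictProperty()]).
#' @seealso [fitLinear()], [predictProperty()]
#' @export
setClass("RegressionModel",
  slots = c(slope = "numeric", intercept = "numeric", r2 = "numeric",
            adjR2 = "numeric", se = "numeric", fStat = "numeric",
            nObs = "integer", property = "character",
            descriptor = "character", xRange = "numeric"))

setValidity("RegressionModel", function(object) {
  msg <- character(0)
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (object@adjR2 > object@r2 + 1e-12) msg <- c(msg, "adjusted r2 exceeds r2")
  if (object@fStat < 0) msg <- c(msg, "F statistic must be non-negative")
  if (length(msg)) msg else TRUE
})
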