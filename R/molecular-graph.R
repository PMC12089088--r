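#' Create a MolecularGraph
#'
#' @param bonds two-column matrix (or data.frame) of atom-id pairs, one bond
#'   per row.  Endpoints may be given in either order; rows are normalized
#'   to ascending order and deduplicated order is \emph{not} applied -- a
#'   duplicate bond is an error.
#' @param nAtoms number of atoms; defaults to the largest id referenced.
#'   Isolated atoms beyond the bonded set are allowed.
#' @param coords optional numeric matrix (nAtoms x 2) of 2D coordinates in
#'   bond-length units.
#' @param familyTag optional provenance label.
#' @return a [MolecularGraph-class] object.
#' @examples
#' benzene <- molecularGraph(cbind(1:6, c(2:6, 1)))
#' nBonds(benzene)
#' @export
molecularGraph <- function(bonds, nAtoms = NULL, coords = NULL,
                           familyTag = NA_character_) {
  bonds <- as.matrix(bonds)
  if (length(bonds) == 0L) bonds <- matrix(integer(0), 0, 2)
  storage.mode(bonds) <- "integer"
  if (nrow(bonds) > 0) {
    if (any(is.na(bonds)) || any(bonds < 1L))
      stop("bond endpoints must be positive integers")
    bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  }
  if (is.null(nAtoms)) nAtoms <- if (nrow(bonds)) max(bonds) else 0L
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 2)
  coords <- as.matrix(coords)
  new("MolecularGraph", bonds = bonds, nAtoms = as.integer(nAtoms),
      coords = coords, familyTag = as.character(familyTag))
}

#' @describeIn molecularGraph number of atoms
#' @param x a MolecularGraph
#' @export
nAtoms <- function(x) x@nAtoms

#' @describeIn molecularGraph number of bonds
#' @export
nBonds <- function(x) nrow(x@bonds)

#' @describeIn molecularGraph two-column bond matrix
#' @export
bonds <- function(x) x@bonds

#' @describeIn molecularGraph coordinate matrix (0 rows when absent)
#' @export
atomCoords <- function(x) x@coords

#' @describeIn molecularGraph TRUE when 2D coordinates are present
#' @export
hasCoords <- function(x) nrow(x@coords) > 0

#' @describeIn molecularGraph provenance label (NA when untagged)
#' @export
familyTag <- function(x) x@familyTag

#' Vertex degrees
#'
#' @param g a [MolecularGraph-class]
#' @return integer vector of atom degrees, indexed by atom id.
#' @export
atomDegrees <- function(g) {
  tabulate(c(g@bonds[, 1], g@bonds[, 2]), g@nAtoms)
}

#' Maximum degree Delta(G)
#' @param g a [MolecularGraph-class]
#' @export
maxDegree <- function(g) {
  if (nBonds(g) == 0L) stop("graph has no bonds")
  max(atomDegrees(g))
}

setMethod("show", "MolecularGraph", function(object) {
  tag <- if (is.na(object@familyTag)) "" else paste0(" [", object@familyTag, "]")
  cat(sprintf("MolecularGraph%s: %d atoms, %d bonds%s\n", tag,
              object@nAtoms, nrow(object@bonds),
              if (hasCoords(object)) ", 2D coords" else ""))
  if (nrow(object@bonds)) {
    p <- edgePartition(object)
    cat("  edge partition:",
        paste(sprintf("(%s): %d", names(p), p), collapse = ", "), "\n")
  }
})

#' Degree-based edge partition
#'
#' Splits the bond set into classes by the unordered pair of endpoint
#' degrees (d(a), d(b)).  For the three coronene-fractal families the
#' partition has exactly the classes (2,2), (2,3) and (3,3) with counts
#' given by closed-form polynomials in the size parameters (see
#' [closedFormCounts()]).
#'
#' @param g a nonempty [MolecularGraph-class]
#' @return named integer vector; names are \code{"dA-dB"} with dA <= dB,
#'   values the class counts.  Counts sum to \code{nBonds(g)}.
#' @examples
#' edgePartition(coroneneUnit())   # (2-2): 6, (2-3): 12, (3-3): 12
#' @export
edgePartition <- function(g) {
  if (nBonds(g) == 0L) stop("cannot partition the edges of an empty graph")
  deg <- atomDegrees(g)
  da <- deg[g@bonds[, 1]]; db <- deg[g@bonds[, 2]]
  key <- paste(pmin(da, db), pmax(da, db), sep = "-")
  tab <- table(key)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' Adjacency matrix with canonical atom ordering
#'
#' Returns the symmetric 0/1 adjacency matrix.  When the graph carries 2D
#' coordinates the atoms are first put in a canonical order (lexicographic
#' by rounded x then y) so that exported matrices and spectra are
#' reproducible across runs regardless of generation order.
#'
#' @param g a [MolecularGraph-class]
#' @param canonical reorder atoms by coordinates when available (default).
#' @return integer matrix, zero diagonal; the chosen atom ordering is
#'   attached as attribute \code{"ordering"} (old id of each row).
#' @export
adjacencyMatrix <- function(g, canonical = TRUE) {
  p <- g@nAtoms
  ord <- seq_len(p)
  if (canonical && hasCoords(g)) {
    xy <- round(g@coords, 6)
    ord <- order(xy[, 1], xy[, 2])
  }
  rnk <- integer(p); rnk[ord] <- seq_len(p)
  A <- matrix(0L, p, p)
  if (nBonds(g)) {
    i <- rnk[g@bonds[, 1]]; j <- rnk[g@bonds[, 2]]
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  attr(A, "ordering") <- ord
  A
}

#' @rdname connectivity
#' @name connectivity
#' @title Connectivity, bipartiteness and planarity helpers
#' @description Thin wrappers over igraph used to check the structural
#'   invariants of generated fractals: connectedness, bipartite
#'   two-colorability, and maximum degree 3.
#' @param g a [MolecularGraph-class]
#' @return \code{isConnected}/\code{isBipartite}: logical.
#'   \code{bipartiteClasses}: integer vector of 0/1 colors, or an error for
#'   non-bipartite input.
NULL

.as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g@nAtoms, directed = FALSE)
  if (nBonds(g)) ig <- igraph::add_edges(ig, t(g@bonds))
  ig
}

#' @rdname connectivity
#' @export
isConnected <- function(g) {
  igraph::components(.as_igraph(g))$no == 1L
}

#' @rdname connectivity
#' @export
isBipartite <- function(g) {
  igraph::bipartite_mapping(.as_igraph(g))$res
}

#' @rdname connectivity
#' @export
bipartiteClasses <- function(g) {
  bm <- igraph::bipartite_mapping(.as_igraph(g))
  if (!bm$res) stop("graph is not bipartite")
  as.integer(bm$type)
}
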