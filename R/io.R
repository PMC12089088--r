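#' Read a molecular graph from a plain edge list
#'
#' Format: one bond per line, two whitespace-separated positive integer
#' atom ids (1-based).  Blank lines and lines starting with \code{#} are
#' ignored.  Self-loops, duplicate bonds and malformed lines raise an
#' error naming the offending line.
#'
#' @param path file to read
#' @return a [MolecularGraph-class]
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  pairs <- matrix(integer(0), 0, 2)
  for (i in keep) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    ids <- suppressWarnings(as.integer(toks))
    if (length(ids) != 2L || any(is.na(ids)) || any(ids < 1L))
      stop(sprintf("line %d: expected two positive integer atom ids, got '%s'",
                   i, lines[i]))
    if (ids[1] == ids[2])
      stop(sprintf("line %d: self-loop on atom %d", i, ids[1]))
    pairs <- rbind(pairs, sort(ids))
  }
  if (anyDuplicated(paste(pairs[, 1], pairs[, 2]))) {
    d <- which(duplicated(paste(pairs[, 1], pairs[, 2])))[1]
    stop(sprintf("line %d: duplicate bond %d-%d",
                 keep[d], pairs[d, 1], pairs[d, 2]))
  }
  molecularGraph(pairs)
}

#' Write a molecular graph as a plain edge list
#'
#' Writes 1-based, whitespace-separated bonds, one per line, after the
#' canonical atom reordering of [adjacencyMatrix()] so that write-then-read
#' reproduces the graph exactly when coordinates are present (and up to
#' relabeling otherwise).
#'
#' @param g a [MolecularGraph-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeEdgeList <- function(g, path) {
  A <- adjacencyMatrix(g)
  ord <- attr(A, "ordering")
  rnk <- integer(g@nAtoms); rnk[ord] <- seq_len(g@nAtoms)
  b <- cbind(rnk[g@bonds[, 1]], rnk[g@bonds[, 2]])
  b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  writeLines(c(sprintf("# %d atoms, %d bonds", g@nAtoms, nrow(b)),
               sprintf("%d %d", b[, 1], b[, 2])), path)
  invisible(path)
}

#' Write an XYZ file (all atoms carbon, z = 0)
#'
#' @param g a [MolecularGraph-class] with coordinates
#' @param path output file
#' @param bondLength physical bond length in Angstrom used to scale the
#'   unit-bond-length coordinates; 1.42 is the aromatic C-C distance.
#' @return invisibly, the path
#' @export
writeXYZ <- function(g, path, bondLength = 1.42) {
  if (!hasCoords(g)) stop("graph has no coordinates; cannot write XYZ")
  xy <- g@coords[attr(adjacencyMatrix(g), "ordering"), , drop = FALSE] *
    bondLength
  writeLines(c(as.character(g@nAtoms),
               sprintf("%s bond length %.3f A",
                       if (is.na(g@familyTag)) "coronene fractal" else g@familyTag,
                       bondLength),
               sprintf("C %12.6f %12.6f %12.6f", xy[, 1], xy[, 2], 0)), path)
  invisible(path)
}

#' Write a minimal MOL (V2000) file
#'
#' 2D coordinates, every atom carbon, every bond order 1 (aromaticity
#' perception is out of scope).  Useful for viewing generated fractals in
#' standard chemistry tools.
#'
#' @inheritParams writeXYZ
#' @return invisibly, the path
#' @export
writeSDF <- function(g, path, bondLength = 1.42) {
  if (!hasCoords(g)) stop("graph has no coordinates; cannot write SDF")
  A <- adjacencyMatrix(g)
  ord <- attr(A, "ordering")
  rnk <- integer(g@nAtoms); rnk[ord] <- seq_len(g@nAtoms)
  xy <- g@coords[ord, , drop = FALSE] * bondLength
  b <- cbind(rnk[g@bonds[, 1]], rnk[g@bonds[, 2]])
  hdr <- c(if (is.na(g@familyTag)) "molecule" else g@familyTag,
           "  coroneneFractals", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   g@nAtoms, nrow(b)))
  atoms <- sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
                   xy[, 1], xy[, 2], 0)
  bl <- sprintf("%3d%3d  1  0  0  0  0", pmin(b[, 1], b[, 2]),
                pmax(b[, 1], b[, 2]))
  writeLines(c(hdr, atoms, bl, "M  END", "$$$$"), path)
  invisible(path)
}
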