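# Benzenoid templates on the honeycomb lattice.
#
# Hexagonal cells are addressed by cube coordinates (a, b, c) with
# a + b + c = 0.  A cell's centre in integer half-units is (2a + c, 3c),
# where the real position of an integer pair (p, q) is (p sqrt(3)/2, q/2)
# at unit bond length; the six cell vertices sit at centre + offset with
# offsets (1,1), (0,2), (-1,1), (-1,-1), (0,-2), (1,-1) (bearings
# 30 + 60j degrees).  All vertex merging is exact integer arithmetic.

.cell_offsets <- rbind(c(1L, 1L), c(0L, 2L), c(-1L, 1L),
                       c(-1L, -1L), c(0L, -2L), c(1L, -1L))

# cells for each family, as a matrix with columns (a, c)
.family_cells <- function(spec) {
  n <- spec@n
  switch(spec@family,
    ZHCF = {
      # zigzag hexagonal series: all cells within cube-distance n-1
      out <- expand.grid(a = -(n - 1):(n - 1), b = -(n - 1):(n - 1))
      cc <- -out$a - out$b
      cbind(out$a, cc)[abs(cc) <= n - 1, , drop = FALSE]
    },
    AHCF = {
      # armchair series: max pairwise cube-coordinate difference <= 3(n-1)
      r <- 3L * (n - 1L)
      out <- expand.grid(a = -r:r, b = -r:r)
      cc <- -out$a - out$b
      keep <- pmax(abs(out$a - out$b), abs(out$b - cc), abs(cc - out$a)) <= r
      cbind(out$a, cc)[keep, , drop = FALSE]
    },
    RCF = {
      # n rows of m linearly fused cells; consecutive rows two cube steps
      # apart and shifted so each column contributes one junction bond
      m <- spec@m
      g <- expand.grid(a = 0:(m - 1), r = 0:(n - 1))
      cbind(g$a - g$r, 2L * g$r)
    })
}

#' Build the benzenoid template of a fractal
#'
#' The template is the honeycomb subgraph whose vertices will each be
#' replaced by a coronene unit.  Each template edge is labeled with a
#' direction index d in 0..5 (bearing 30 + 60 d degrees as seen from its
#' first endpoint; the second endpoint sees (d + 3) mod 6), which selects
#' the rim bond along which the two units fuse.
#'
#' @param spec a [FractalSpec-class] (see [fractalSpec()])
#' @return a list with components \code{coordsInt} (integer vertex
#'   positions in lattice half-units), \code{coords} (real positions at
#'   unit bond length), \code{edges} (two-column matrix) and \code{dir}
#'   (direction label per edge).
#' @examples
#' t2 <- buildTemplate(fractalSpec("ZHCF", 2))
#' nrow(t2$coordsInt)   # 24: the coronene skeleton itself
#' @export
buildTemplate <- function(spec) {
  stopifnot(is(spec, "FractalSpec"))
  validObject(spec)
  cells <- .family_cells(spec)
  centres <- cbind(2L * cells[, 1] + cells[, 2], 3L * cells[, 2])
  vs <- unique(do.call(rbind, lapply(seq_len(nrow(centres)), function(i)
    cbind(centres[i, 1] + .cell_offsets[, 1],
          centres[i, 2] + .cell_offsets[, 2]))))
  vs <- vs[order(vs[, 1], vs[, 2]), , drop = FALSE]
  key <- paste(vs[, 1], vs[, 2])
  lookup <- stats::setNames(seq_len(nrow(vs)), key)
  # induced honeycomb edges: unit-length steps (1,1), (0,2), (-1,1)
  steps <- rbind(c(1L, 1L), c(0L, 2L), c(-1L, 1L))
  dirs <- c(0L, 1L, 2L)   # bearings 30, 90, 150 degrees
  edges <- NULL; dir <- integer(0)
  for (s in 1:3) {
    nb <- paste(vs[, 1] + steps[s, 1], vs[, 2] + steps[s, 2])
    j <- lookup[nb]
    hit <- which(!is.na(j))
    if (length(hit)) {
      edges <- rbind(edges, cbind(hit, unname(j[hit])))
      dir <- c(dir, rep(dirs[s], length(hit)))
    }
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  # per-vertex direction labels must be distinct (honeycomb guarantees it)
  if (nrow(edges)) {
    seen <- c(paste(edges[, 1], dir), paste(edges[, 2], (dir + 3L) %% 6L))
    if (anyDuplicated(seen))
      stop("direction-label clash: two fusions request the same rim bond")
  }
  list(coordsInt = vs,
       coords = cbind(vs[, 1] * sqrt(3) / 2, vs[, 2] / 2),
       edges = edges, dir = dir)
}

#' Construct a FractalSpec
#'
#' @param family \code{"ZHCF"}, \code{"AHCF"} or \code{"RCF"}
#' @param n positive integer size (number of rows for RCF)
#' @param m hexagons per row; required for RCF, ignored otherwise
#' @return a [FractalSpec-class]
#' @export
fractalSpec <- function(family, n, m = NA_integer_) {
  family <- toupper(as.character(family))
  if (family == "RCF" && is.na(m))
    stop("RCF requires both m (hexagons per row) and n (rows)")
  if (family != "RCF") m <- NA_integer_
  new("FractalSpec", family = family, n = as.integer(n), m = as.integer(m))
}

setMethod("show", "FractalSpec", function(object) {
  if (object@family == "RCF")
    cat(sprintf("FractalSpec: RCF(m = %d, n = %d)\n", object@m, object@n))
  else
    cat(sprintf("FractalSpec: %s(n = %d)\n", object@family, object@n))
})

.spec_label <- function(spec) {
  if (spec@family == "RCF") sprintf("RCF(%d,%d)", spec@m, spec@n)
  else sprintf("%s(%d)", spec@family, spec@n)
}
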