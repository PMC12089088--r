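#' Expand a benzenoid template into a coronene fractal
#'
#' Replaces every template vertex by a [coroneneUnit()] and, for every
#' template edge with direction label d (seen as d' = (d + 3) mod 6 from
#' the other endpoint), identifies the two rim atoms of the fusable bond
#' F_d of one unit with those of F_d' of the neighbour, so that the two
#' units share one C-C bond.  The merge is purely combinatorial
#' (union-find over (unit, local-atom) pairs); coordinates of merged atoms
#' coincide geometrically by construction.
#'
#' With V_T template vertices and E_T template edges the result has
#' 24 V_T - 2 E_T atoms, 30 V_T - E_T bonds, and edge partition
#' (2,2): 6 V_T - 2 E_T, (2,3): 12 V_T - 4 E_T, (3,3): 12 V_T + 5 E_T.
#'
#' @param tmpl a template from [buildTemplate()]
#' @param familyTag provenance label for the result
#' @param swapIdentification exchange the two atom identifications of every
#'   fusion (orientation robustness check; yields an isomorphic graph).
#' @return a [MolecularGraph-class] with 2D coordinates
#' @export
expandTemplate <- function(tmpl, familyTag = NA_character_,
                           swapIdentification = FALSE) {
  nv <- nrow(tmpl$coordsInt)
  ne <- nrow(tmpl$edges)
  N <- nv * 24L
  parent <- seq_len(N)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  gid <- function(u, loc) (u - 1L) * 24L + loc
  if (ne > 0) for (i in seq_len(ne)) {
    u <- tmpl$edges[i, 1]; v <- tmpl$edges[i, 2]
    d <- tmpl$dir[i]; dp <- (d + 3L) %% 6L
    fu <- .unit_fusable(d); fv <- .unit_fusable(dp)
    if (swapIdentification) fv <- rev(fv)
    for (pair in list(c(gid(u, fu[1]), gid(v, fv[2])),
                      c(gid(u, fu[2]), gid(v, fv[1])))) {
      r1 <- findRoot(pair[1]); r2 <- findRoot(pair[2])
      if (r1 != r2) parent[r1] <- r2
    }
  }
  roots <- vapply(seq_len(N), findRoot, numeric(1))
  ids <- match(roots, unique(roots))
  # atom coordinates: unit centre (template position scaled by 3 sqrt(3),
  # which rotates the 30-degree template bearings onto the unit's fusion
  # geometry) plus the local unit coordinate
  centres <- tmpl$coords * (3 * sqrt(3))
  local <- .unit_local_coords()
  xy <- matrix(0, max(ids), 2)
  for (u in seq_len(nv)) {
    at <- gid(u, 1:24)
    xy[ids[at], ] <- cbind(centres[u, 1] + local[, 1],
                           centres[u, 2] + local[, 2])
  }
  ub <- .unit_local_bonds()
  E <- do.call(rbind, lapply(seq_len(nv), function(u)
    cbind(ids[gid(u, ub[, 1])], ids[gid(u, ub[, 2])])))
  E <- unique(cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
  molecularGraph(E, nAtoms = max(ids), coords = xy, familyTag = familyTag)
}

#' Closed-form structure counts
#'
#' Evaluates the exact polynomials for vertex count, edge count and
#' degree-based edge partition of each family:
#' \tabular{llll}{
#'   \tab ZHCF(n) \tab AHCF(n) \tab RCF(m,n) \cr
#'   |V| \tab 126n^2+6n \tab 378n^2-366n+120 \tab 84mn+2m+46n \cr
#'   |E| \tab 171n^2+3n \tab 513n^2-507n+168 \tab 114mn+m+59n \cr
#'   (2,2) \tab 18n^2+6n \tab 54n^2-42n+12 \tab 12mn+2m+10n \cr
#'   (2,3) \tab 36n^2+12n \tab 108n^2-84n+24 \tab 24mn+4m+20n \cr
#'   (3,3) \tab 117n^2-15n \tab 351n^2-381n+132 \tab 78mn-5m+29n \cr
#' }
#'
#' @param spec a [FractalSpec-class]
#' @return list with \code{nAtoms}, \code{nBonds} and \code{partition}
#'   (named integer vector as from [edgePartition()])
#' @examples
#' closedFormCounts(fractalSpec("ZHCF", 2))
#' @export
closedFormCounts <- function(spec) {
  stopifnot(is(spec, "FractalSpec"))
  validObject(spec)
  n <- spec@n; m <- spec@m
  out <- switch(spec@family,
    ZHCF = list(V = 126 * n^2 + 6 * n, E = 171 * n^2 + 3 * n,
                p = c(18 * n^2 + 6 * n, 36 * n^2 + 12 * n, 117 * n^2 - 15 * n)),
    AHCF = list(V = 378 * n^2 - 366 * n + 120, E = 513 * n^2 - 507 * n + 168,
                p = c(54 * n^2 - 42 * n + 12, 108 * n^2 - 84 * n + 24,
                      351 * n^2 - 381 * n + 132)),
    RCF  = list(V = 84 * m * n + 2 * m + 46 * n, E = 114 * m * n + m + 59 * n,
                p = c(12 * m * n + 2 * m + 10 * n, 24 * m * n + 4 * m + 20 * n,
                      78 * m * n - 5 * m + 29 * n)))
  part <- as.integer(out$p)
  names(part) <- c("2-2", "2-3", "3-3")
  list(nAtoms = as.integer(out$V), nBonds = as.integer(out$E),
       partition = part)
}

#' Generate a coronene fractal
#'
#' Builds the family template, expands it with coronene units, and
#' validates the result against the closed-form counts of
#' [closedFormCounts()]; a non-conforming graph is never returned.
#'
#' @param spec a [FractalSpec-class], or a family name when \code{n} is
#'   given
#' @param n,m convenience size arguments forwarded to [fractalSpec()]
#' @return a validated [MolecularGraph-class] with 2D coordinates
#' @examples
#' g <- generateFractal("ZHCF", 1)
#' c(nAtoms(g), nBonds(g))   # 132, 174
#' @export
generateFractal <- function(spec, n = NULL, m = NA_integer_) {
  if (!is(spec, "FractalSpec")) spec <- fractalSpec(spec, n, m)
  g <- expandTemplate(buildTemplate(spec), familyTag = .spec_label(spec))
  ref <- closedFormCounts(spec)
  if (nAtoms(g) != ref$nAtoms)
    stop(sprintf("%s: generated %d atoms, closed form requires %d",
                 .spec_label(spec), nAtoms(g), ref$nAtoms))
  if (nBonds(g) != ref$nBonds)
    stop(sprintf("%s: generated %d bonds, closed form requires %d",
                 .spec_label(spec), nBonds(g), ref$nBonds))
  part <- edgePartition(g)
  if (!identical(part[names(ref$partition)], ref$partition))
    stop(sprintf("%s: edge partition (%s) disagrees with closed form (%s)",
                 .spec_label(spec), paste(part, collapse = ","),
                 paste(ref$partition, collapse = ",")))
  g
}
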