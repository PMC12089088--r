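# The 24-carbon coronene unit: seven peri-fused hexagons (one central cell
# plus its six neighbours on the honeycomb lattice).  Local atom numbering:
#   1..6    inner 6-cycle, atom d+1 at angle 60d degrees, radius 1
#   7..24   rim 18-cycle, atom 7+j; hubs r_{3d} = 7+3d at radius 2 carry the
#           spoke to inner atom d+1; the (r_{3d+1}, r_{3d+2}) rim bonds are
#           the six fusable (2,2) bonds F_d, one per 60-degree direction d.

.unit_local_coords <- function() {
  rot <- function(p, d) {
    th <- pi * d / 3
    c(cos(th) * p[1] - sin(th) * p[2], sin(th) * p[1] + cos(th) * p[2])
  }
  xy <- matrix(0, 24, 2)
  for (d in 0:5) {
    xy[d + 1L, ] <- rot(c(1, 0), d)
    xy[7L + 3L * d, ] <- rot(c(2, 0), d)
    xy[8L + 3L * d, ] <- rot(c(2.5, sqrt(3) / 2), d)
    xy[9L + 3L * d, ] <- rot(c(2, sqrt(3)), d)
  }
  xy
}

.unit_local_bonds <- function() {
  d <- 0:5; j <- 0:17
  rbind(cbind(d + 1L, (d + 1L) %% 6L + 1L),        # inner cycle
        cbind(7L + j, 7L + (j + 1L) %% 18L),       # rim cycle
        cbind(d + 1L, 7L + 3L * d))                # spokes
}

# local ids of the fusable bond F_d (both endpoints degree 2)
.unit_fusable <- function(d) c(8L + 3L * d, 9L + 3L * d)

#' The coronene unit
#'
#' Builds the 24-atom, 30-bond carbon skeleton of coronene, the repeating
#' motif of all three fractal families, with 2D coordinates at unit bond
#' length (central hexagon centred on the origin).  Twelve atoms have
#' degree 3 (six inner, six rim hubs) and twelve have degree 2; the six
#' degree-(2,2) rim bonds are the fusion sites used by [expandTemplate()].
#'
#' @return a [MolecularGraph-class] tagged \code{"coronene"}
#' @examples
#' u <- coroneneUnit()
#' edgePartition(u)
#' @export
coroneneUnit <- function() {
  molecularGraph(.unit_local_bonds(), nAtoms = 24L,
                 coords = .unit_local_coords(), familyTag = "coronene")
}
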