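# Residue depth (DPX) and protrusion (CX) indices.
#
# DPX: per-atom distance to the nearest solvent-accessible atom (atoms with
# SASA > 0 have depth 0), averaged over the residue's heavy atoms.
# CX: unoccupied/occupied volume ratio in a 10 A sphere around each atom,
# occupancy approximated as atom count x mean atom volume (20.1 A^3),
# averaged over the residue's heavy atoms.

#' Average residue depth index (DPX)
#'
#' @param complex A `complex_structure` (depth is computed in the bound
#'   complex: all chains present).
#' @param per_atom_sasa Per-atom areas from [shrake_rupley()] on the same
#'   atom table (all chains, same order as `atom_table(complex)`).
#' @return Data frame `chain_id`, `seq_index`, `dpx` (A).
#' @export
depth_index <- function(complex, per_atom_sasa) {
  at <- atom_table(complex)
  stopifnot(length(per_atom_sasa) == nrow(at))
  accessible <- per_atom_sasa > 0
  if (!any(accessible)) stop("undefined depth: structure has no solvent-accessible atom")
  axyz <- as.matrix(at[accessible, c("x", "y", "z")])
  depth <- numeric(nrow(at))
  buried <- which(!accessible)
  for (i in buried) {
    d2 <- (axyz[, 1] - at$x[i])^2 + (axyz[, 2] - at$y[i])^2 +
      (axyz[, 3] - at$z[i])^2
    depth[i] <- sqrt(min(d2))
  }
  agg <- stats::aggregate(depth,
                          by = list(chain_id = at$chain_id,
                                    seq_index = at$seq_index), FUN = mean)
  names(agg)[3] <- "dpx"
  agg[order(agg$chain_id, agg$seq_index), , drop = FALSE]
}

#' Average residue protrusion index (CX)
#'
#' For each atom, the occupied volume of a `sphere_radius` sphere is the
#' number of heavy atoms inside it (self included) times `mean_atom_volume`;
#' CX is free volume over occupied volume, clamped at zero when the local
#' packing fills the sphere.
#'
#' @param complex A `complex_structure`.
#' @param sphere_radius Sphere radius in Angstrom (default 10.0).
#' @param mean_atom_volume Mean heavy-atom volume in A^3 (default 20.1).
#' @return Data frame `chain_id`, `seq_index`, `cx`.
#' @export
protrusion_index <- function(complex, sphere_radius = 10.0,
                             mean_atom_volume = 20.1) {
  at <- atom_table(complex)
  n <- nrow(at)
  v_sphere <- 4 / 3 * pi * sphere_radius^3
  r2 <- sphere_radius^2
  cx <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (at$x - at$x[i])^2 + (at$y - at$y[i])^2 + (at$z - at$z[i])^2
    cnt <- sum(d2 <= r2)  # includes self
    v_int <- max(cnt, 1) * mean_atom_volume
    v_ext <- max(v_sphere - v_int, 0)
    cx[i] <- v_ext / v_int
  }
  agg <- stats::aggregate(cx,
                          by = list(chain_id = at$chain_id,
                                    seq_index = at$seq_index), FUN = mean)
  names(agg)[3] <- "cx"
  agg[order(agg$chain_id, agg$seq_index), , drop = FALSE]
}

#' Compute DPX and CX together
#'
#' Convenience wrapper running one Shrake-Rupley pass on the bound complex.
#'
#' @inheritParams depth_index
#' @inheritParams protrusion_index
#' @param probe_radius,n_points Passed to [shrake_rupley()].
#' @return Data frame `chain_id`, `seq_index`, `dpx`, `cx`.
#' @export
geometry_features <- function(complex, probe_radius = 1.4, n_points = 960L,
                              sphere_radius = 10.0, mean_atom_volume = 20.1) {
  at <- atom_table(complex)
  area <- shrake_rupley(at, probe_radius, n_points)
  d <- depth_index(complex, area)
  p <- protrusion_index(complex, sphere_radius, mean_atom_volume)
  merge(d, p, by = c("chain_id", "seq_index"), sort = TRUE)
}
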