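# Solvent-accessible surface area by the Shrake-Rupley method.
#
# A deterministic Fibonacci-spiral point set replaces DSSP/PSAIA so areas are
# reproducible and self-contained. MASA (chain alone) and CASA (full complex)
# are the unbound/bound per-residue tables whose difference defines
# interfacial contact.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-angle) spiral; the same `n` always yields the same set.
#'
#' @param n Number of points.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  theta <- acos(1 - 2 * i / n)
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Canonical orientation frame of a coordinate set: principal axes with the
# sign of each axis fixed by the third moment of the projections. Rotating
# the quadrature sphere into this frame makes areas invariant under rigid
# transforms of the structure (the frame co-rotates).
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 2) return(diag(3))
  ctr <- colMeans(xyz)
  y <- sweep(xyz, 2, ctr)
  v <- eigen(crossprod(y) / nrow(y), symmetric = TRUE)$vectors
  proj <- y %*% v
  s <- colSums(proj^3)
  flip <- s < 0
  v[, flip] <- -v[, flip]
  v
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's surface is sampled with `n_points` test points on a sphere of
#' radius `vdw + probe`; a point is accessible when it lies outside every
#' other atom's probe-expanded sphere. Area is the accessible fraction times
#' the full sphere area. The quadrature sphere is oriented along the
#' structure's principal axes so areas do not depend on the global frame.
#'
#' @param atoms Data frame with columns `x`, `y`, `z`, `vdw_radius`.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom (quadrature resolution).
#' @param frame Optional 3 x 3 orientation matrix for the point set;
#'   defaults to the canonical frame of `atoms`. Pass a shared frame when
#'   several related computations (e.g. bound vs unbound states) must use
#'   identical test directions.
#' @return Numeric vector of per-atom areas in A^2.
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960L,
                          frame = NULL) {
  stopifnot(n_points >= 1, probe_radius >= 0)
  n <- nrow(atoms)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- atoms$vdw_radius + probe_radius
  if (is.null(frame)) frame <- canonical_frame(xyz)
  pts <- sphere_points(n_points) %*% t(frame)
  out <- numeric(n)
  # neighbour cutoff: spheres can only intersect within r_i + r_j
  maxr <- max(rad)
  for (i in seq_len(n)) {
    ri <- rad[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * ri^2
      next
    }
    px <- pts[, 1] * ri + xyz[i, 1]
    py <- pts[, 2] * ri + xyz[i, 2]
    pz <- pts[, 3] * ri + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
      acc <- acc & (dj2 > rad[j]^2)
    }
    out[i] <- sum(acc) / n_points * 4 * pi * ri^2
  }
  out
}

sasa_table_cols <- c("total_asa", "backbone_asa", "sidechain_asa",
                     "polar_asa", "nonpolar_asa")
rasa_table_cols <- c("total_rasa", "backbone_rasa", "sidechain_rasa",
                     "polar_rasa", "nonpolar_rasa")

#' Per-residue ASA components in the bound or unbound state
#'
#' In the `"bound"` context all chains are present; in the `"unbound"` context
#' each chain is computed in isolation (partner chains removed), which is the
#' MASA of the interface definition. Per-atom areas are summed into five
#' components per residue: total, backbone/side-chain (atom name in
#' N/CA/C/O or not) and polar/non-polar (element N/O vs C/S).
#'
#' @param complex A `complex_structure`.
#' @param context `"bound"` or `"unbound"`.
#' @param probe_radius,n_points Passed to [shrake_rupley()].
#' @return A `sasa_table` data frame: one row per residue (chain, seq_index,
#'   author_number, aa, five ASA columns, five RASA columns initialised NA).
#' @export
residue_asa <- function(complex, context = c("bound", "unbound"),
                        probe_radius = 1.4, n_points = 960L) {
  context <- match.arg(context)
  stopifnot(inherits(complex, "complex_structure"))
  chain_sets <- if (context == "bound") list(names(complex$chains))
                else as.list(names(complex$chains))
  # one frame for the whole complex: bound and unbound states then share
  # identical test directions per atom, so occlusion can only reduce area
  all_at <- atom_table(complex)
  frame <- canonical_frame(cbind(all_at$x, all_at$y, all_at$z))
  rows <- list()
  for (set in chain_sets) {
    at <- atom_table(complex, set)
    area <- shrake_rupley(at, probe_radius, n_points, frame = frame)
    key <- paste(at$chain_id, at$seq_index)
    for (cid in set) {
      ch <- complex$chains[[cid]]
      for (res in ch$residues) {
        sel <- key == paste(cid, res$seq_index)
        a <- area[sel]
        bb <- at$is_backbone[sel]
        pol <- at$is_polar[sel]
        rows[[length(rows) + 1L]] <- data.frame(
          chain_id = cid, seq_index = res$seq_index,
          author_number = res$author_number, aa = res$aa,
          total_asa = sum(a), backbone_asa = sum(a[bb]),
          sidechain_asa = sum(a[!bb]), polar_asa = sum(a[pol]),
          nonpolar_asa = sum(a[!pol]), stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  # unbound rows come out chain-by-chain already in order; keep stable order
  tab <- tab[order(match(tab$chain_id, names(complex$chains)), tab$seq_index), ]
  rownames(tab) <- NULL
  for (col in rasa_table_cols) tab[[col]] <- NA_real_
  attr(tab, "context") <- context
  class(tab) <- c("sasa_table", "data.frame")
  tab
}

#' Fill relative accessibility columns of a SASA table
#'
#' Every ASA component is divided by the amino acid's maximum reference area
#' (Tien et al. 2013 theoretical set), so the five RASA components keep the
#' same additivity as the ASA components. Unknown residues (`"X"`) use the
#' mean reference area and are flagged in `rasa_ref_imputed`.
#'
#' @param asa A `sasa_table` from [residue_asa()].
#' @return The table with `*_rasa` columns filled (fractions, not percent).
#' @export
relative_asa <- function(asa) {
  stopifnot(inherits(asa, "sasa_table"))
  ref <- MAX_ASA[asa$aa]
  imputed <- is.na(ref)
  ref[imputed] <- mean(MAX_ASA)
  for (k in seq_along(sasa_table_cols)) {
    asa[[rasa_table_cols[k]]] <- asa[[sasa_table_cols[k]]] / ref
  }
  asa$rasa_ref_imputed <- unname(imputed)
  asa
}

#' Read per-residue accessibility from a DSSP file
#'
#' Parses the ACC column of a DSSP v2/v3 text file. Chain-break marker lines
#' (residue code `!`) are skipped without shifting the alignment.
#'
#' @param path Path to a DSSP output file.
#' @return Data frame with `chain_id`, `author_number`, `aa`, `acc` (A^2).
#' @export
read_dssp_asa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file (missing residue header): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(trimws(body)) > 0]
  aa_col <- substr(body, 14, 14)
  body <- body[aa_col != "!"]
  if (length(body) == 0) stop("DSSP file has no residue rows: ", path)
  num <- trimws(substr(body, 6, 10))
  chain <- substr(body, 12, 12)
  aa <- toupper(substr(body, 14, 14))
  acc_str <- trimws(substr(body, 35, 38))
  acc <- suppressWarnings(as.numeric(acc_str))
  if (anyNA(acc)) {
    stop("non-numeric ACC value '", acc_str[which(is.na(acc))[1]],
         "' in ", path)
  }
  data.frame(chain_id = chain, author_number = as.integer(num), aa = aa,
             acc = acc, stringsAsFactors = FALSE)
}

#' Write a SASA table to CSV
#' @param asa A `sasa_table`.
#' @param path Output CSV path.
#' @export
write_sasa_csv <- function(asa, path) {
  out <- as.data.frame(asa)
  out$context <- attr(asa, "context")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
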