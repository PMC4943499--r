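# Shared fixtures and independent oracles.

# --- tiny PDB text ---------------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          element = substr(name, 1, 1), occ = 1.0,
                          altloc = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resname, chain, resseq, x, y, z, occ, 0.0,
          element)
}

write_ala_pdb <- function(path) {
  # one ALA residue, 5 heavy atoms
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.0, 0.0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.009, 1.420, 0.0, "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.251, 2.390, 0.0, "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.988, -0.773, -1.199, "C"),
    "END")
  writeLines(lines, path)
  path
}

# residue with three atoms and no CA (centroid fallback case)
write_no_ca_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "C", "GLY", "A", 1, 3.0, 0.0, 0.0, "C"),
    pdb_atom_line(3, "O", "GLY", "A", 1, 0.0, 3.0, 0.0, "O"),
    "END")
  writeLines(lines, path)
  path
}

# --- DSSP stub -------------------------------------------------------------

dssp_stub_lines <- function(rows) {
  # rows: data.frame num, chain, aa, acc (acc may be character to test errors)
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N"
  body <- vapply(seq_len(nrow(rows)), function(i) {
    pre <- sprintf("%5d%5s %s %s", i, rows$num[i], rows$chain[i], rows$aa[i])
    paste0(pre, strrep(" ", 34 - nchar(pre)), sprintf("%4s", rows$acc[i]))
  }, "")
  c("==== Secondary Structure Definition ====", hdr, body)
}

# --- HSSP stub -------------------------------------------------------------

# percents: matrix L x 20 of integer percentages in HSSP column order
# (V L I M F W Y G A P S T C H R K Q E N D)
hssp_stub_lines <- function(percents, nocc = 10, entropy = 0.5, relent = 17,
                            weight = 1.0, var = NULL) {
  L <- nrow(percents)
  out <- c("HSSP       HOMOLOGY DERIVED SECONDARY STRUCTURE OF PROTEINS",
           "PDBID      stub")
  if (!is.null(var)) {
    hdr <- " SeqNo  PDBNo AA STRUCTURE BP1 BP2  ACC NOCC  VAR"
    vend <- as.integer(regexpr("VAR", hdr)) + 2L
    out <- c(out, "## ALIGNMENTS    1 -    1", hdr,
             vapply(seq_len(L), function(i) {
               pre <- sprintf("%5d %5d A S", i, i)
               paste0(pre, strrep(" ", vend - 5L - nchar(pre)),
                      sprintf("%5d", var[i]))
             }, ""))
  }
  out <- c(out, "## SEQUENCE PROFILE AND ENTROPY",
           paste(" SeqNo PDBNo   V   L   I   M   F   W   Y   G   A   P",
                 "  S   T   C   H   R   K   Q   E   N   D  NOCC NDEL NINS",
                 " ENTROPY RELENT WEIGHT"))
  body <- vapply(seq_len(L), function(i) {
    paste(sprintf("%5d %4d A", i, i),
          paste(sprintf("%3d", percents[i, ]), collapse = " "),
          sprintf("%5d %4d %4d %7.3f %6d %5.2f",
                  nocc, 0, 0, entropy, relent, weight))
  }, "")
  c(out, body, "##")
}

# --- independent oracles ---------------------------------------------------

# Monte-Carlo SASA with random (seeded) directions, independent of the
# package's deterministic spiral quadrature.
oracle_sasa_mc <- function(atoms, probe = 1.4, n_mc = 8000, seed = 42) {
  set.seed(seed)
  u <- matrix(stats::rnorm(n_mc * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- atoms$vdw_radius + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  vapply(seq_len(nrow(atoms)), function(i) {
    p <- sweep(u * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(atoms))[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rad[j]^2
    }
    mean(acc) * 4 * pi * rad[i]^2
  }, numeric(1))
}

# O(n_pos * n_neg) concordance-probability AUC
oracle_auc_concordance <- function(y, s) {
  sp <- s[y == 1]
  sn <- s[y == 0]
  gt <- outer(sp, sn, `>`)
  eq <- outer(sp, sn, `==`)
  (sum(gt) + 0.5 * sum(eq)) / (length(sp) * length(sn))
}

# loop-based confusion recount
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# random rigid transform applied to every atom of a complex
rigid_transform_complex <- function(complex, seed = 7) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  tr <- stats::runif(3, -20, 20)
  for (cid in names(complex$chains)) {
    ch <- complex$chains[[cid]]
    for (k in seq_along(ch$residues)) {
      res <- ch$residues[[k]]
      xyz <- as.matrix(res$atoms[, c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, tr, `+`)
      res$atoms$x <- xyz[, 1]
      res$atoms$y <- xyz[, 2]
      res$atoms$z <- xyz[, 3]
      res$ca_coord <- as.numeric(R %*% res$ca_coord + tr)
      complex$chains[[cid]]$residues[[k]] <- res
    }
  }
  complex
}

# small random atom cluster for quadrature tests
random_cluster <- function(n, seed, spread = 3) {
  set.seed(seed)
  new_atom_table(name = rep("CA", n),
                 element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
                 x = stats::runif(n, 0, spread),
                 y = stats::runif(n, 0, spread),
                 z = stats::runif(n, 0, spread))
}
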