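# PDB reading and the in-memory chain/residue/atom model.
#
# Only heavy atoms from ATOM records of the first model are kept; altlocs are
# resolved to the highest-occupancy (first on ties) conformer; waters, ligands
# (HETATM) and hydrogens are dropped. Internal residue indexing is 0-based
# (seq_index); R-level positional arguments are 1-based as usual.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_atom_table <- function(name, element, x, y, z) {
  element <- toupper(element)
  data.frame(
    name = name, element = element, x = x, y = y, z = z,
    vdw_radius = vdw_radius(element),
    is_backbone = name %in% BACKBONE_ATOMS,
    is_polar = element %in% c("N", "O"),
    stringsAsFactors = FALSE
  )
}

new_residue_record <- function(chain_id, seq_index, author_number, aa, atoms) {
  stopifnot(nrow(atoms) > 0)
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) >= 1) {
    ca_coord <- c(ca$x[1], ca$y[1], ca$z[1])
    ca_approx <- FALSE
  } else {
    # centroid fallback keeps window distances defined; flagged
    ca_coord <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
    ca_approx <- TRUE
  }
  structure(
    list(chain_id = chain_id, seq_index = seq_index,
         author_number = author_number, aa = aa, atoms = atoms,
         ca_coord = ca_coord, ca_approx = ca_approx),
    class = "residue_record"
  )
}

new_chain_structure <- function(chain_id, residues) {
  structure(list(chain_id = chain_id, residues = residues,
                 length = length(residues)),
            class = "chain_structure")
}

new_complex_structure <- function(chains, pdb_id = "XXXX") {
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids)) stop("duplicate chain ids: ", toString(ids))
  structure(list(pdb_id = pdb_id, chains = stats::setNames(chains, ids)),
            class = "complex_structure")
}

#' Read a protein complex from a PDB file
#'
#' Parses ATOM records (wwPDB v3.3 fixed columns) of the first model into a
#' `complex_structure`: a list of chains, each an ordered list of residue
#' records carrying heavy-atom coordinates and a C-alpha coordinate (heavy-atom
#' centroid, flagged, when CA is missing). Hydrogens, waters and HETATM
#' ligands are excluded; alternate locations are resolved to the
#' highest-occupancy conformer; non-standard residue names map to `"X"`.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @return A `complex_structure` object.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- which(rec == "ATOM  ")
  if (length(keep) == 0) stop("empty structure: no ATOM records in ", path)
  al <- lines[keep]

  bad <- which(nchar(al) < 54)
  if (length(bad) > 0) {
    stop("malformed ATOM record at line ", keep[bad[1]], ": truncated")
  }
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  resseq <- trimws(substr(al, 23, 26))
  icode <- substr(al, 27, 27)
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(substr(al, 77, 78)))
  # derive element from the atom name when the element column is blank
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]+", "", name)), 1, 1))
  elem[elem == ""] <- guess[elem == ""]

  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("malformed ATOM record at line ",
         keep[which(is.na(x) | is.na(y) | is.na(z))[1]],
         ": non-numeric coordinate")
  }

  heavy <- elem != "H" & elem != "D"
  df <- data.frame(name = name, element = elem, x = x, y = y, z = z,
                   occ = occ, altloc = altloc, resname = resname,
                   chain = chain, resseq = resseq, icode = icode,
                   stringsAsFactors = FALSE)[heavy, , drop = FALSE]
  if (nrow(df) == 0) stop("empty structure: no heavy atoms in ", path)

  reskey <- paste(df$chain, df$resseq, df$icode, sep = "|")
  chains <- list()
  for (cid in unique(df$chain)) {
    cdf <- df[df$chain == cid, , drop = FALSE]
    residues <- list()
    i <- 0L
    for (rk in unique(paste(cdf$resseq, cdf$icode, sep = "|"))) {
      rdf <- cdf[paste(cdf$resseq, cdf$icode, sep = "|") == rk, , drop = FALSE]
      # altloc resolution: per atom name keep highest occupancy, first on tie
      if (any(rdf$altloc != " ")) {
        ord <- order(rdf$name, -rdf$occ, rdf$altloc)
        rdf <- rdf[ord, , drop = FALSE]
        rdf <- rdf[!duplicated(rdf$name), , drop = FALSE]
      }
      aa <- AA_FROM_THREE[rdf$resname[1]]
      if (is.na(aa)) aa <- "X"
      atoms <- new_atom_table(rdf$name, rdf$element, rdf$x, rdf$y, rdf$z)
      residues[[length(residues) + 1L]] <- new_residue_record(
        chain_id = cid, seq_index = i,
        author_number = as.integer(rdf$resseq[1]), aa = unname(aa),
        atoms = atoms)
      i <- i + 1L
    }
    chains[[length(chains) + 1L]] <- new_chain_structure(cid, residues)
  }
  pdb_id <- sub("\\.(pdb|ent)$", "", basename(path))
  new_complex_structure(chains, pdb_id = pdb_id)
}

#' Per-residue C-alpha coordinates of a chain
#'
#' @param chain A `chain_structure`.
#' @return An L x 3 matrix of coordinates in sequence order, with a logical
#'   attribute `"approx"` marking residues whose CA was absent and whose
#'   coordinate is the heavy-atom centroid.
#' @export
get_ca_coords <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"), chain$length > 0)
  m <- t(vapply(chain$residues, `[[`, numeric(3), "ca_coord"))
  dimnames(m) <- NULL
  attr(m, "approx") <- vapply(chain$residues, `[[`, logical(1), "ca_approx")
  m
}

#' Chain amino-acid sequence as one-letter codes
#' @param chain A `chain_structure`.
#' @return Character vector of length L.
#' @export
chain_sequence <- function(chain) {
  vapply(chain$residues, `[[`, "", "aa")
}

# Flatten chains into one atom table with residue bookkeeping columns.
# `chain_ids = NULL` takes every chain.
atom_table <- function(complex, chain_ids = NULL) {
  stopifnot(inherits(complex, "complex_structure"))
  if (is.null(chain_ids)) chain_ids <- names(complex$chains)
  out <- list()
  for (cid in chain_ids) {
    ch <- complex$chains[[cid]]
    for (res in ch$residues) {
      a <- res$atoms
      a$chain_id <- cid
      a$seq_index <- res$seq_index
      out[[length(out) + 1L]] <- a
    }
  }
  do.call(rbind, out)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column ATOM records (one chain after another, TER
#' between chains) so that [read_pdb()] round-trips its own output.
#'
#' @param complex A `complex_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "complex_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in complex$chains) {
    for (res in ch$residues) {
      res3 <- if (res$aa %in% names(AA_THREE)) AA_THREE[[res$aa]] else "UNK"
      a <- res$atoms
      for (k in seq_len(nrow(a))) {
        serial <- serial + 1L
        nm <- a$name[k]
        # column-13 alignment rule: 1-3 char names start in column 14
        nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
        writeLines(sprintf(
          "ATOM  %5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm_fmt, " ", res3, ch$chain_id,
          res$author_number %% 10000L, " ",
          a$x[k], a$y[k], a$z[k], 1.0, 0.0, a$element[k]), con)
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure", x$pdb_id, "-", length(x$chains), "chain(s):\n")
  for (ch in x$chains) {
    cat("  chain", ch$chain_id, ":", ch$length, "residues\n")
  }
  invisible(x)
}
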