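# Sequence-profile (HSSP) features, physicochemical lookups, and assembly of
# the 50-dimensional per-residue descriptor.
#
# Profile tables hold, per residue: 20 substitution probabilities (package
# order is alphabetical one-letter codes), entropy, relative entropy (0-100),
# conservation weight, sequence variability (0-100) and NOCC (number of
# aligned sequences; the 25th profile feature).

# HSSP prints the 20 amino-acid columns in this order
HSSP_AA_ORDER <- c("V", "L", "I", "M", "F", "W", "Y", "G", "A", "P",
                   "S", "T", "C", "H", "R", "K", "Q", "E", "N", "D")

PROFILE_P_COLS <- paste0("p_", AA_CODES)
PROFILE_STAT_COLS <- c("entropy", "relative_entropy", "conservation_weight",
                       "sequence_variability", "nocc")
PROFILE_COLS <- c(PROFILE_P_COLS, PROFILE_STAT_COLS)

new_profile_table <- function(df) {
  stopifnot(all(PROFILE_COLS %in% names(df)))
  df <- df[PROFILE_COLS]
  p <- as.matrix(df[PROFILE_P_COLS])
  if (any(p < 0)) stop("invalid profile: negative substitution probability")
  s <- rowSums(p)
  off <- which(abs(s - 1) > 0.02 & s > 0)
  if (length(off) > 0) {
    stop("invalid profile: probabilities in row ", off[1], " sum to ",
         format(s[off[1]], digits = 4), " (tolerance 0.02)")
  }
  class(df) <- c("profile_table", "data.frame")
  df
}

#' Shannon entropy of a substitution-probability row
#'
#' Natural-log entropy with the 0*log(0) = 0 convention, and the relative
#' entropy scaled so the uniform distribution over 20 amino acids maps to 100.
#'
#' @param p Numeric vector of 20 non-negative probabilities.
#' @return Named vector `entropy` (nats) and `relative_entropy` (0-100).
#' @export
profile_entropy <- function(p) {
  stopifnot(length(p) == 20, all(p >= 0), sum(p) <= 1.02)
  nz <- p[p > 0]
  h <- -sum(nz * log(nz))
  c(entropy = h, relative_entropy = 100 * h / log(20))
}

#' Parse the sequence profile of an HSSP file
#'
#' Reads the `## SEQUENCE PROFILE AND ENTROPY` section (20 percent columns in
#' HSSP order, NOCC, ENTROPY, RELENT, WEIGHT) and, when present, the
#' per-residue `VAR` column of the `## ALIGNMENTS` section for sequence
#' variability. Percentages are divided by 100.
#'
#' @param path Path to an HSSP file.
#' @return A `profile_table` with one row per residue.
#' @export
parse_hssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- grep("^## SEQUENCE PROFILE", lines)
  if (length(sec) == 0) stop("not an HSSP file (missing SEQUENCE PROFILE section): ", path)
  i <- sec[1] + 1L
  # column-header line
  while (i <= length(lines) && !grepl("SeqNo", lines[i])) i <- i + 1L
  if (i > length(lines)) stop("malformed HSSP: profile header not found in ", path)
  rows <- list()
  j <- i + 1L
  while (j <= length(lines) && !grepl("^##", lines[j]) &&
         nchar(trimws(lines[j])) > 0) {
    tok <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]]
    # PDBNo may carry a separate chain-letter token
    if (length(tok) == 29 && grepl("^[A-Za-z]$", tok[3])) tok <- tok[-3]
    if (length(tok) != 28) {
      stop("malformed HSSP profile row (", length(tok), " fields): ",
           trimws(lines[j]))
    }
    v <- suppressWarnings(as.numeric(tok[3:28]))
    if (anyNA(v)) stop("non-numeric HSSP profile value in row: ", trimws(lines[j]))
    rows[[length(rows) + 1L]] <- v
    j <- j + 1L
  }
  if (length(rows) == 0) stop("HSSP profile section has no rows: ", path)
  m <- do.call(rbind, rows)
  p <- m[, 1:20, drop = FALSE] / 100
  colnames(p) <- paste0("p_", HSSP_AA_ORDER)
  df <- as.data.frame(p)[paste0("p_", AA_CODES)]  # reorder alphabetically
  names(df) <- PROFILE_P_COLS
  df$entropy <- m[, 24]
  df$relative_entropy <- m[, 25]
  df$conservation_weight <- m[, 26]
  df$sequence_variability <- parse_hssp_var(lines, nrow(m))
  df$nocc <- m[, 21]
  new_profile_table(df)
}

# VAR lives in the ALIGNMENTS header block; absent -> 0 (flagged via attr)
parse_hssp_var <- function(lines, L) {
  ali <- grep("^## ALIGNMENTS", lines)
  if (length(ali) == 0) return(rep(0, L))
  i <- ali[1] + 1L
  while (i <= length(lines) && !grepl("SeqNo", lines[i])) i <- i + 1L
  if (i > length(lines)) return(rep(0, L))
  hdr <- lines[i]
  vpos <- regexpr("VAR", hdr)
  if (vpos < 0) return(rep(0, L))
  vend <- vpos + 2L
  out <- rep(NA_real_, L)
  j <- i + 1L
  k <- 0L
  while (j <= length(lines) && !grepl("^##", lines[j]) &&
         nchar(trimws(lines[j])) > 0 && k < L) {
    if (substr(lines[j], 14, 14) != "!") {
      k <- k + 1L
      out[k] <- suppressWarnings(as.numeric(substr(lines[j], vend - 4L, vend)))
    }
    j <- j + 1L
  }
  out[is.na(out)] <- 0
  out
}

#' Read a simplified tab-separated profile file
#'
#' Fixture-friendly dialect: a header row naming the 25 profile columns
#' (`p_A` ... `p_Y`, entropy, relative_entropy, conservation_weight,
#' sequence_variability, nocc), one row per residue. A missing `nocc` column
#' defaults to 1 and is flagged in the `"nocc_defaulted"` attribute.
#'
#' @param path Path to a TSV file.
#' @return A `profile_table`.
#' @export
parse_profile_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nocc_defaulted <- FALSE
  if (!"nocc" %in% names(df)) {
    df$nocc <- 1
    nocc_defaulted <- TRUE
  }
  missing <- setdiff(PROFILE_COLS, names(df))
  if (length(missing) > 0) {
    stop("profile TSV is missing columns: ", toString(missing))
  }
  extra <- setdiff(names(df), PROFILE_COLS)
  if (length(extra) > 0) {
    stop("profile TSV has unexpected columns: ", toString(extra))
  }
  out <- new_profile_table(df)
  attr(out, "nocc_defaulted") <- nocc_defaulted
  out
}

#' Write a profile table in the simplified TSV dialect
#' @param profiles A `profile_table`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles)[PROFILE_COLS], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Physicochemical feature vector of an amino acid
#'
#' Eight HQI8 cluster values followed by the five Atchley factors. Unknown
#' residues (`"X"`) get the column-wise mean over the 20 amino acids.
#'
#' @param aa One-letter amino-acid code.
#' @return Named numeric vector of length 13.
#' @export
physchem_lookup <- function(aa) {
  if (aa %in% AA_CODES) {
    out <- c(HQI8_TABLE[aa, ], AA_FACTORS[aa, ])
  } else {
    out <- c(colMeans(HQI8_TABLE), colMeans(AA_FACTORS))
  }
  names(out) <- c(paste0("hqi_", HQI8_ACCESSIONS), AA_FACTOR_NAMES)
  out
}

#' Names and order of the 50 per-residue features
#'
#' 25 profile features, 12 structure features (5 ASA, 5 RASA, DPX, CX),
#' 13 physicochemical features. This ordering is fixed; every feature matrix
#' in the package uses it.
#'
#' @return Character vector of length 50.
#' @export
residue_feature_names <- function() {
  c(PROFILE_COLS[1:24], "nocc",
    sasa_table_cols, rasa_table_cols, "dpx", "cx",
    paste0("hqi_", HQI8_ACCESSIONS), AA_FACTOR_NAMES)
}

#' Assemble the 50-dimensional residue descriptor
#'
#' @param profile_row One row of a `profile_table` (list or data frame row).
#' @param sasa_row One row of an unbound `sasa_table` with RASA filled.
#' @param geom_row List/row with `dpx` and `cx`.
#' @param physchem Length-13 vector from [physchem_lookup()].
#' @return Named numeric vector of length 50 in [residue_feature_names()]
#'   order.
#' @export
assemble_residue_vector <- function(profile_row, sasa_row, geom_row, physchem) {
  for (part in list(c("profile", "entropy"), c("sasa", "total_asa"),
                    c("geometry", "dpx"))) {
    src <- switch(part[1], profile = profile_row, sasa = sasa_row,
                  geometry = geom_row)
    if (is.null(src) || is.null(src[[part[2]]]) || is.na(src[[part[2]]])) {
      stop("cannot assemble residue vector: missing ", part[1], " part")
    }
  }
  if (length(physchem) != 13) {
    stop("cannot assemble residue vector: physchem part has length ",
         length(physchem), ", expected 13")
  }
  v <- c(
    as.numeric(profile_row[PROFILE_P_COLS]),
    profile_row[["entropy"]], profile_row[["relative_entropy"]],
    profile_row[["conservation_weight"]],
    profile_row[["sequence_variability"]], profile_row[["nocc"]],
    as.numeric(sasa_row[sasa_table_cols]),
    as.numeric(sasa_row[rasa_table_cols]),
    geom_row[["dpx"]], geom_row[["cx"]],
    as.numeric(physchem)
  )
  names(v) <- residue_feature_names()
  v
}
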