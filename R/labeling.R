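# Surface / interface residue labeling and chain curation.
#
# Surface: total relative accessibility in the unbound chain >= 16 %.
# Interface: surface residue whose total ASA changes by at least 1 A^2
# between the unbound (MASA) and bound (CASA) states.

#' Surface residue flags from unbound relative accessibility
#'
#' @param rasa_unbound A `sasa_table` with RASA filled, unbound context.
#' @param threshold Fraction of the maximum reference area that must be
#'   exposed (default 0.16; boundary inclusive).
#' @return Logical vector aligned to the table rows.
#' @export
label_surface <- function(rasa_unbound, threshold = 0.16) {
  stopifnot(inherits(rasa_unbound, "sasa_table"))
  if (anyNA(rasa_unbound$total_rasa)) {
    stop("RASA not filled; call relative_asa() first")
  }
  rasa_unbound$total_rasa >= threshold
}

#' Interface residue flags from buried surface area
#'
#' A surface residue is an interface residue when its total ASA differs by at
#' least `delta` between the unbound (MASA) and bound (CASA) states. The
#' surface gate guarantees `is_interface` implies `is_surface`.
#'
#' @param masa Unbound `sasa_table`.
#' @param casa Bound `sasa_table`.
#' @param surface Logical surface flags aligned to both tables.
#' @param delta Buried-area threshold in A^2 (default 1.0; inclusive).
#' @return Logical vector of interface flags.
#' @export
label_interface <- function(masa, casa, surface, delta = 1.0) {
  key_m <- paste(masa$chain_id, masa$seq_index)
  key_c <- paste(casa$chain_id, casa$seq_index)
  if (length(key_m) != length(key_c) || !all(key_m == key_c)) {
    stop("misaligned SASA tables: residue keys differ")
  }
  if (length(surface) != length(key_m)) {
    stop("misaligned surface flags: length ", length(surface),
         " vs ", length(key_m), " residues")
  }
  surface & (abs(masa$total_asa - casa$total_asa) >= delta)
}

#' Chain-level curation report
#'
#' A chain passes curation when it has at least 100 residues and at least 20
#' (heterocomplex) or 30 (homocomplex) interface residues.
#'
#' @param chain A `chain_structure`.
#' @param is_interface Logical interface flags aligned to the chain.
#' @param complex_type `"hetero"` or `"homo"`.
#' @param min_length Minimum chain length (default 100).
#' @return A one-row data frame: chain_id, length, length_ok,
#'   interface_count, interface_count_ok, passed.
#' @export
curate_chain <- function(chain, is_interface,
                         complex_type = c("hetero", "homo"),
                         min_length = 100L) {
  complex_type <- match.arg(complex_type)
  stopifnot(inherits(chain, "chain_structure"))
  if (length(is_interface) != chain$length) {
    stop("labels not aligned to chain: ", length(is_interface),
         " flags for ", chain$length, " residues")
  }
  need <- if (complex_type == "hetero") 20L else 30L
  n_int <- sum(is_interface)
  length_ok <- chain$length >= min_length
  count_ok <- n_int >= need
  data.frame(chain_id = chain$chain_id, length = chain$length,
             length_ok = length_ok, interface_count = n_int,
             interface_count_ok = count_ok,
             passed = length_ok && count_ok, stringsAsFactors = FALSE)
}

#' Label every residue of a complex
#'
#' Runs the unbound/bound SASA computation, fills RASA, and applies the
#' surface and interface rules.
#'
#' @param complex A `complex_structure`.
#' @param surface_threshold RASA fraction for surface calls (default 0.16).
#' @param interface_delta Buried-area threshold in A^2 (default 1.0).
#' @param probe_radius,n_points Passed to the SASA computation.
#' @return A data frame per residue: chain_id, seq_index, author_number, aa,
#'   masa, casa, total_rasa, is_surface, is_interface.
#' @export
label_complex <- function(complex, surface_threshold = 0.16,
                          interface_delta = 1.0,
                          probe_radius = 1.4, n_points = 960L) {
  masa <- relative_asa(residue_asa(complex, "unbound", probe_radius, n_points))
  casa <- residue_asa(complex, "bound", probe_radius, n_points)
  surf <- label_surface(masa, surface_threshold)
  intf <- label_interface(masa, casa, surf, interface_delta)
  data.frame(chain_id = masa$chain_id, seq_index = masa$seq_index,
             author_number = masa$author_number, aa = masa$aa,
             masa = masa$total_asa, casa = casa$total_asa,
             total_rasa = masa$total_rasa,
             is_surface = surf, is_interface = intf,
             stringsAsFactors = FALSE)
}

#' Write residue labels to CSV
#' @param labels Data frame from [label_complex()].
#' @param path Output CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
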