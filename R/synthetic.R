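# Synthetic desk-scale fixtures: two-chain toy complexes with a known
# contact patch, synthetic sequence profiles, and direct labelled feature
# matrices for classifier tests. Everything is generated in code from a
# seed; no external downloads.

#' Specification of a toy two-chain complex
#'
#' Chains are built from pseudo-residues (backbone N, CA, C, O plus one
#' side-chain bead CB) laid along a smooth path with the idealized 3.8 A
#' C-alpha spacing. The first `contact_patch_size` residues of each chain
#' face each other across `inter_chain_gap`; the remaining residues of chain
#' B turn away from chain A so only the patch is in contact.
#'
#' @param n_res_per_chain Residues per chain.
#' @param contact_patch_size Residues per chain in the contact patch.
#' @param inter_chain_gap Approximate closest atom-atom separation across
#'   the interface, Angstrom.
#' @param geometry `"extended"` (straight backbone) or `"helix"` (ideal
#'   alpha-helical offsets around the path).
#' @param seed Seed for the small coordinate jitter.
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_res_per_chain = 30L, contact_patch_size = 8L,
                             inter_chain_gap = 4.0,
                             geometry = c("extended", "helix"), seed = 1L) {
  geometry <- match.arg(geometry)
  if (contact_patch_size > n_res_per_chain) {
    stop("infeasible geometry: contact patch (", contact_patch_size,
         ") larger than chain (", n_res_per_chain, ")")
  }
  stopifnot(inter_chain_gap > 0, n_res_per_chain >= 1)
  structure(list(n_res_per_chain = as.integer(n_res_per_chain),
                 contact_patch_size = as.integer(contact_patch_size),
                 inter_chain_gap = inter_chain_gap, geometry = geometry,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# CA path of one chain: straight along +x for `patch` steps, then turning
# away along `turn_dir`. 3.8 A per step.
toy_ca_path <- function(n, patch, origin, turn_dir) {
  ca <- matrix(0, n, 3)
  pos <- origin
  dirv <- c(1, 0, 0)
  for (i in seq_len(n)) {
    ca[i, ] <- pos
    if (i == max(patch, 1L)) dirv <- turn_dir
    pos <- pos + 3.8 * dirv
  }
  ca
}

# Backbone + CB offsets relative to CA; `side` flips the CB bead toward the
# partner chain (+y or -y). Glycine gets no side-chain bead.
toy_residue_atoms <- function(ca, side, helix_phase = NULL, aa = "A") {
  off <- rbind(N = c(-1.20, 0.50 * side, 0.45),
               CA = c(0, 0, 0),
               C = c(1.25, 0.40 * side, -0.45),
               O = c(1.45, 1.55 * side, -0.55),
               CB = c(0.15, -1.05 * side, 1.05))
  elem <- c("N", "C", "C", "O", "C")
  if (aa == "G") {
    off <- off[1:4, , drop = FALSE]
    elem <- elem[1:4]
  }
  if (!is.null(helix_phase)) {
    # ideal helix: wrap the offsets around the path with a 100-degree turn
    rot <- matrix(c(cos(helix_phase), -sin(helix_phase),
                    sin(helix_phase), cos(helix_phase)), 2, 2, byrow = TRUE)
    off[, 2:3] <- off[, 2:3] %*% t(rot)
  }
  xyz <- sweep(off, 2, ca, `+`)
  new_atom_table(name = rownames(off), element = elem,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

toy_chain <- function(chain_id, n, patch, origin, turn_dir, side, geometry,
                      aa_seq) {
  ca <- toy_ca_path(n, patch, origin, turn_dir)
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    phase <- if (geometry == "helix") (i - 1) * 100 * pi / 180 else NULL
    atoms <- toy_residue_atoms(ca[i, ], side, phase, aa_seq[i])
    residues[[i]] <- new_residue_record(chain_id, i - 1L, i, aa_seq[i], atoms)
  }
  new_chain_structure(chain_id, residues)
}

#' Build a toy two-chain complex with a known contact patch
#'
#' @param spec A [toy_complex_spec()].
#' @return List: `structure` (a `complex_structure`) and `contact` (named
#'   list of per-chain logical ground-truth patch flags).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  n <- spec$n_res_per_chain
  patch <- spec$contact_patch_size
  set.seed(spec$seed)
  aa_a <- sample(AA_CODES, n, replace = TRUE)
  aa_b <- sample(AA_CODES, n, replace = TRUE)
  # CB beads reach ~1.05 A + backbone spread either side; CA planes are
  # separated so the closest atoms sit near the requested gap
  ca_sep <- spec$inter_chain_gap + 2.1
  if (patch == 0) {
    # no designated patch: chain B runs parallel at the full gap
    chain_a <- toy_chain("A", n, n, c(0, 0, 0), c(1, 0, 0), +1,
                         spec$geometry, aa_a)
    chain_b <- toy_chain("B", n, n, c(0, ca_sep, 0), c(1, 0, 0), -1,
                         spec$geometry, aa_b)
  } else {
    chain_a <- toy_chain("A", n, patch, c(0, 0, 0), c(1, 0, 0), +1,
                         spec$geometry, aa_a)
    chain_b <- toy_chain("B", n, patch, c(0, ca_sep, 0), c(0, 1, 0), -1,
                         spec$geometry, aa_b)
  }
  contact <- list(A = seq_len(n) <= patch, B = seq_len(n) <= patch)
  list(structure = new_complex_structure(list(chain_a, chain_b),
                                         pdb_id = "TOY1"),
       contact = contact)
}

#' Signal specification for synthetic labelled data
#'
#' @param n_informative Number of feature columns carrying signal.
#' @param effect_size Mean shift of informative columns for positives, in
#'   pooled standard deviations.
#' @param class_balance Positive-class fraction.
#' @param seed Seed.
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(n_informative = 10L, effect_size = 2,
                        class_balance = 0.5, seed = 1L) {
  stopifnot(n_informative >= 0, n_informative <= 550, effect_size >= 0,
            class_balance > 0, class_balance < 1)
  structure(list(n_informative = as.integer(n_informative),
                 effect_size = effect_size, class_balance = class_balance,
                 seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate synthetic sequence profiles with class-dependent conservation
#'
#' Non-interface rows draw substitution probabilities from a flat Dirichlet;
#' interface rows mix in a one-hot component whose weight grows with
#' `effect_size`, lowering their entropy (stronger conservation). Entropy
#' statistics, conservation weight, variability and NOCC are filled
#' consistently with the generated probabilities.
#'
#' @param L Number of residues.
#' @param labels Logical/0-1 interface flags of length `L`.
#' @param signal A [signal_spec()]; only `effect_size` and `seed` are used.
#' @return A `profile_table` with `L` rows.
#' @export
make_synthetic_profiles <- function(L, labels, signal = signal_spec()) {
  stopifnot(length(labels) == L)
  labels <- as.logical(labels)
  set.seed(signal$seed)
  lambda <- min(0.2 * signal$effect_size, 0.9)
  p <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    g <- stats::rgamma(20, shape = 1)
    row <- g / sum(g)
    if (labels[i] && lambda > 0) {
      hot <- sample.int(20, 1)
      row <- (1 - lambda) * row
      row[hot] <- row[hot] + lambda
    }
    p[i, ] <- row
  }
  colnames(p) <- PROFILE_P_COLS
  ent <- t(apply(p, 1, profile_entropy))
  df <- as.data.frame(p)
  df$entropy <- ent[, "entropy"]
  df$relative_entropy <- ent[, "relative_entropy"]
  df$conservation_weight <- pmin(pmax(
    100 - df$relative_entropy + stats::rnorm(L, 0, 2), 0), 100)
  df$sequence_variability <- pmin(pmax(
    df$relative_entropy + stats::rnorm(L, 0, 2), 0), 100)
  df$nocc <- stats::rpois(L, 50) + 1
  new_profile_table(df)
}

#' Generate a labelled 550-column dataset (structure bypass)
#'
#' Standard-normal features; `n_informative` columns (chosen from the seed)
#' are shifted by `effect_size` SDs for positive samples. Used to test the
#' classifier stack independently of the structural pipeline.
#'
#' @param n Number of samples.
#' @param signal A [signal_spec()].
#' @param p Number of feature columns (default 550).
#' @return List: `X` (n x p), `y` (0/1), `informative` (column indices).
#' @export
make_labeled_dataset <- function(n, signal = signal_spec(), p = 550L) {
  stopifnot(n >= 1, signal$n_informative <= p)
  set.seed(signal$seed)
  y <- as.integer(stats::runif(n) < signal$class_balance)
  X <- matrix(stats::rnorm(n * p), n, p)
  informative <- sort(sample.int(p, signal$n_informative))
  if (length(informative) > 0 && any(y == 1)) {
    X[y == 1, informative] <- X[y == 1, informative] + signal$effect_size
  }
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y, informative = informative)
}
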