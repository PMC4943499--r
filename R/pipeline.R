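# End-to-end orchestration: structure + profiles -> WFD matrix -> bagging
# model -> metrics, with a manifest for reproducibility.

#' Pipeline configuration
#'
#' Defaults follow the method's stated constants: window 11, surface
#' threshold 16 % RASA, interface contact |MASA - CASA| >= 1 A^2, fivefold
#' cross-validation.
#'
#' @param window Odd sliding-window size (default 11).
#' @param surface_threshold Unbound RASA fraction for surface calls.
#' @param interface_delta Buried-area threshold, A^2.
#' @param m Number of bagging base learners.
#' @param seed Master seed.
#' @param folds Cross-validation folds.
#' @param complex_type `"hetero"` or `"homo"` (curation thresholds).
#' @param weighted `FALSE` switches off distance weighting (the "noWFD"
#'   encoding: all distances treated as 1).
#' @param order_by WFD block ordering, `"distance"` or `"sequence"`.
#' @param n_points Shrake-Rupley quadrature points.
#' @return A `run_config` list.
#' @export
run_config <- function(window = 11L, surface_threshold = 0.16,
                       interface_delta = 1.0, m = 10L, seed = 1L,
                       folds = 5L, complex_type = "hetero",
                       weighted = TRUE, order_by = "distance",
                       n_points = 960L) {
  structure(list(window = as.integer(window),
                 surface_threshold = surface_threshold,
                 interface_delta = interface_delta, m = as.integer(m),
                 seed = as.integer(seed), folds = as.integer(folds),
                 complex_type = complex_type, weighted = weighted,
                 order_by = order_by, n_points = as.integer(n_points)),
            class = "run_config")
}

#' Extract the WFD training matrix from a complex and its profiles
#'
#' Runs the full feature stage: bound/unbound SASA, RASA, surface/interface
#' labels, depth and protrusion indices, per-residue 50-vectors, and the
#' windowed distance-weighted encoding of every surface residue.
#'
#' @param complex A `complex_structure`.
#' @param profiles Named list (chain id -> `profile_table`), row-aligned to
#'   each chain.
#' @param config A [run_config()].
#' @return List: `X`, `y`, `meta` (as [encode_dataset()]), `labels`
#'   (per-residue label table), `curation` (per-chain curation reports),
#'   `features` (per-chain 50-column matrices).
#' @export
extract_features <- function(complex, profiles, config = run_config()) {
  stopifnot(inherits(complex, "complex_structure"))
  missing <- setdiff(names(complex$chains), names(profiles))
  if (length(missing) > 0) {
    stop("missing profile for chain ", toString(missing))
  }
  masa <- relative_asa(residue_asa(complex, "unbound",
                                   n_points = config$n_points))
  casa <- residue_asa(complex, "bound", n_points = config$n_points)
  surf <- label_surface(masa, config$surface_threshold)
  intf <- label_interface(masa, casa, surf, config$interface_delta)
  labels <- data.frame(chain_id = masa$chain_id, seq_index = masa$seq_index,
                       author_number = masa$author_number, aa = masa$aa,
                       masa = masa$total_asa, casa = casa$total_asa,
                       total_rasa = masa$total_rasa, is_surface = surf,
                       is_interface = intf, stringsAsFactors = FALSE)
  geom <- geometry_features(complex, n_points = config$n_points)

  chain_features <- list()
  chain_ca <- list()
  curation <- list()
  for (cid in names(complex$chains)) {
    ch <- complex$chains[[cid]]
    prof <- profiles[[cid]]
    if (nrow(prof) != ch$length) {
      stop("profile for chain ", cid, " has ", nrow(prof),
           " rows, chain has ", ch$length, " residues")
    }
    sel <- masa$chain_id == cid
    masa_c <- masa[sel, , drop = FALSE]
    geom_c <- geom[geom$chain_id == cid, , drop = FALSE]
    geom_c <- geom_c[order(geom_c$seq_index), , drop = FALSE]
    fm <- matrix(0, ch$length, 50,
                 dimnames = list(NULL, residue_feature_names()))
    for (i in seq_len(ch$length)) {
      fm[i, ] <- assemble_residue_vector(
        prof[i, , drop = FALSE], masa_c[i, , drop = FALSE],
        geom_c[i, , drop = FALSE], physchem_lookup(ch$residues[[i]]$aa))
    }
    chain_features[[cid]] <- fm
    chain_ca[[cid]] <- get_ca_coords(ch)
    curation[[cid]] <- curate_chain(ch, intf[masa$chain_id == cid],
                                    config$complex_type)
  }
  ds <- encode_dataset(chain_features, chain_ca, labels, w = config$window,
                       weighted = config$weighted,
                       order_by = config$order_by)
  c(ds, list(labels = labels, curation = do.call(rbind, curation),
             features = chain_features))
}

#' Run feature extraction from files and write artifacts
#'
#' @param pdb_path Input PDB file.
#' @param profile_paths Named character vector (chain id -> profile file;
#'   `.hssp` files go through [parse_hssp()], anything else through
#'   [parse_profile_tsv()]).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, the [extract_features()] result. Writes
#'   `features.csv`, `labels.csv` and `manifest.json` (config + input MD5
#'   hashes) into `out_dir`.
#' @export
run_extract <- function(pdb_path, profile_paths, out_dir,
                        config = run_config()) {
  complex <- read_pdb(pdb_path)
  for (cid in names(complex$chains)) {
    if (!cid %in% names(profile_paths)) {
      stop("missing profile file for chain ", cid)
    }
  }
  profiles <- lapply(profile_paths, function(p) {
    if (grepl("\\.hssp$", p, ignore.case = TRUE)) parse_hssp(p)
    else parse_profile_tsv(p)
  })
  res <- extract_features(complex, profiles, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_csv(res$X, res$y, file.path(out_dir, "features.csv"))
  write_labels_csv(res$labels, file.path(out_dir, "labels.csv"))
  manifest <- list(config = unclass(config),
                   inputs = as.list(tools::md5sum(c(pdb_path,
                                                    unname(profile_paths)))),
                   n_rows = nrow(res$X), n_cols = ncol(res$X))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Cross-validate, train and report
#'
#' Fivefold (by default) cross-validation grouped by chain when `groups` is
#' given, then a final model trained on all rows. Metrics, ROC points and
#' the model archive are written when `out_dir` is set.
#'
#' @param X,y Training matrix and labels.
#' @param config A [run_config()].
#' @param groups Optional chain ids per row (keeps chains within one fold).
#' @param out_dir Optional output directory.
#' @return List: `cv` (from [cross_validate()]), `model`, `report`
#'   (out-of-fold metrics + ROC + AUC).
#' @export
run_train_eval <- function(X, y, config = run_config(), groups = NULL,
                           out_dir = NULL) {
  if (nrow(X) == 0) stop("empty feature matrix")
  if (length(unique(y)) < 2) stop("single-class input: cannot train")
  bc <- bagging_config(m = config$m, seed = config$seed)
  cv <- cross_validate(X, y, k = config$folds, config = bc,
                       seed = config$seed, groups = groups)
  model <- train_bagging(X, y, bc)
  ok <- !is.na(cv$scores)
  report <- metrics_report(y[ok], cv$scores[ok])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    m <- report[c("rec", "pre", "acc", "f", "mcc", "auc")]
    jsonlite::write_json(m, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    saveRDS(model, file.path(out_dir, "model.rds"))
  }
  list(cv = cv, model = model, report = report)
}
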