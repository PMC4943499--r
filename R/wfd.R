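# The weighted feature descriptor (WFD).
#
# A query residue is described by an odd-width sliding window of sequence
# neighbours; each neighbour's 50-vector is divided by its C-alpha Euclidean
# distance to the query (the query's own distance is 1 by convention), and
# the blocks are concatenated in ascending-distance order (ties broken by
# sequence position, padding blocks of zeros last).

#' Window slot positions for a query residue
#'
#' @param query 1-based residue position in the chain.
#' @param w Odd window size.
#' @param L Chain length.
#' @return Integer vector of length `w`: positions `query - (w-1)/2` ...
#'   `query + (w-1)/2`, with `NA` for slots falling off the chain.
#' @export
window_indices <- function(query, w, L) {
  if (w %% 2 == 0) stop("window size must be odd, got ", w)
  stopifnot(query >= 1, query <= L)
  half <- (w - 1) %/% 2
  idx <- (query - half):(query + half)
  idx[idx < 1 | idx > L] <- NA_integer_
  idx
}

#' Euclidean distance between two points, with the self-pair convention
#'
#' The distance of a residue to itself is defined as 1 so the query's own
#' feature block enters the descriptor unweighted.
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @param self Set `TRUE` for the query-to-itself pair.
#' @return Distance in Angstrom (1 when `self`).
#' @export
euclidean_distance <- function(a, b, self = FALSE) {
  if (self) return(1)
  sqrt(sum((a - b)^2))
}

#' Encode one residue as a weighted feature descriptor
#'
#' @param features L x 50 matrix of per-residue descriptors.
#' @param ca L x 3 matrix of C-alpha coordinates.
#' @param query 1-based query position.
#' @param w Odd window size (default 11).
#' @param weighted Divide neighbour blocks by their distance (`FALSE` gives
#'   the plain windowed encoding, the "noWFD" variant).
#' @param order_by `"distance"` (ascending C-alpha distance to the query,
#'   self block first) or `"sequence"` (chain order).
#' @return A `wfd_vector`: list with `values` (length `w * ncol(features)`),
#'   `slots`, `distances`, `padding_mask`, `query`.
#' @export
encode_wfd <- function(features, ca, query, w = 11L, weighted = TRUE,
                       order_by = c("distance", "sequence")) {
  order_by <- match.arg(order_by)
  stopifnot(nrow(features) == nrow(ca))
  L <- nrow(features)
  idx <- window_indices(query, w, L)
  if (anyNA(ca[query, ])) {
    stop("query residue ", query, " has no usable coordinates")
  }
  real <- which(!is.na(idx))
  pos <- idx[real]
  d <- vapply(pos, function(p) {
    euclidean_distance(ca[p, ], ca[query, ], self = (p == query))
  }, numeric(1))
  if (any(!is.finite(d)) || any(d <= 0 & pos != query)) {
    stop("degenerate C-alpha distance in window of residue ", query)
  }
  d[d == 0] <- 1  # duplicate coordinates: treat as unit distance
  ord <- if (order_by == "distance") order(d, pos) else order(pos)
  nf <- ncol(features)
  blocks <- matrix(0, nrow = w, ncol = nf)
  for (k in seq_along(ord)) {
    p <- pos[ord[k]]
    wgt <- if (weighted) d[ord[k]] else 1
    blocks[k, ] <- features[p, ] / wgt
  }
  values <- as.numeric(t(blocks))
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("f", seq_len(nf))
  names(values) <- paste0("s", sprintf("%02d", rep(seq_len(w), each = nf)),
                          "_", rep(fn, w))
  structure(list(values = values,
                 slots = c(pos[ord], rep(NA_integer_, w - length(ord))),
                 distances = c(d[ord], rep(NA_real_, w - length(ord))),
                 padding_mask = c(rep(FALSE, length(ord)),
                                  rep(TRUE, w - length(ord))),
                 query = query, w = w),
            class = "wfd_vector")
}

#' Encode the surface residues of labelled chains as a training matrix
#'
#' One row per surface residue, `w * 50` columns, label 1 for interface
#' residues. Windows never cross chain boundaries.
#'
#' @param chain_features Named list (by chain id) of L x 50 feature matrices.
#' @param chain_ca Named list of L x 3 C-alpha coordinate matrices.
#' @param labels Data frame from [label_complex()] (columns chain_id,
#'   seq_index, is_surface, is_interface).
#' @param w Odd window size (default 11).
#' @param weighted,order_by Passed to [encode_wfd()].
#' @return List: `X` (n_surface x w*50 matrix), `y` (integer 0/1),
#'   `meta` (chain_id, seq_index, author_number per row).
#' @export
encode_dataset <- function(chain_features, chain_ca, labels, w = 11L,
                           weighted = TRUE, order_by = "distance") {
  rows <- list()
  ys <- integer(0)
  meta <- list()
  for (cid in names(chain_features)) {
    lab <- labels[labels$chain_id == cid, , drop = FALSE]
    lab <- lab[order(lab$seq_index), , drop = FALSE]
    feats <- chain_features[[cid]]
    ca <- chain_ca[[cid]]
    stopifnot(nrow(lab) == nrow(feats))
    for (r in which(lab$is_surface)) {
      enc <- encode_wfd(feats, ca, r, w = w, weighted = weighted,
                        order_by = order_by)
      rows[[length(rows) + 1L]] <- enc$values
      ys <- c(ys, as.integer(lab$is_interface[r]))
      meta[[length(meta) + 1L]] <- data.frame(
        chain_id = cid, seq_index = lab$seq_index[r],
        author_number = lab$author_number[r], stringsAsFactors = FALSE)
    }
  }
  X <- if (length(rows) > 0) do.call(rbind, rows) else
    matrix(numeric(0), 0, w * 50)
  list(X = X, y = ys,
       meta = if (length(meta) > 0) do.call(rbind, meta) else NULL)
}

#' Write a WFD feature matrix and labels to CSV
#' @param X Feature matrix from [encode_dataset()].
#' @param y Labels aligned to rows.
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(X, y, path) {
  df <- as.data.frame(X)
  df$label <- y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
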