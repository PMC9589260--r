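#' Feature connectivity graph with its Laplacian
#'
#' A `feature_graph` stores a symmetric nonnegative connectivity matrix `L`
#' over the features of one omics layer, its degree diagonal `D` with
#' `D[j, j] = sum_q L[j, q]`, and the graph Laplacian `B = D - L`.  The
#' quadratic form `Tr(H B t(H))` equals `1/2 * sum_{p,q} L[p, q] *
#' ||h_p - h_q||^2` over columns `h` of `H`, which is the penalty used to
#' pull connected features toward similar factor loadings.
#'
#' @param connectivity Symmetric nonnegative matrix with zero diagonal.
#' @param feature_ids Optional feature identifiers (defaults to rownames).
#' @return Object of class `feature_graph` with fields `connectivity`,
#'   `degree`, `laplacian` and `feature_ids`.
#' @export
feature_graph <- function(connectivity, feature_ids = rownames(connectivity)) {
  laplacian_from_adjacency(connectivity, feature_ids)
}

#' Build a graph Laplacian from an adjacency matrix
#'
#' @param A Symmetric nonnegative matrix; the diagonal must be zero.
#' @param feature_ids Optional feature identifiers.
#' @return A [feature_graph] with `degree = diag(rowSums(A))` and
#'   `laplacian = degree - A`.
#' @export
laplacian_from_adjacency <- function(A, feature_ids = rownames(A)) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (nrow(A) != ncol(A)) stop_validation("adjacency must be square")
  if (nrow(A) > 0 && max(abs(A - t(A))) > 1e-9) {
    stop_validation("adjacency must be symmetric (max asymmetry ",
                    format(max(abs(A - t(A)))), ")")
  }
  if (any(A < 0)) stop_validation("adjacency entries must be nonnegative")
  diag(A) <- 0
  A <- (A + t(A)) / 2   # remove sub-tolerance asymmetry exactly
  deg <- rowSums(A)
  D <- diag(deg, nrow(A))
  B <- D - A
  ids <- feature_ids %||% as.character(seq_len(nrow(A)))
  dimnames(A) <- dimnames(B) <- dimnames(D) <- list(ids, ids)
  structure(list(connectivity = A, degree = D, laplacian = B,
                 feature_ids = as.character(ids)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("feature_graph: %d features, %d edges (weight sum %.4g)\n",
              nrow(x$connectivity), sum(x$connectivity > 0) / 2,
              sum(x$connectivity) / 2))
  invisible(x)
}

#' Build a feature connectivity graph from expression
#'
#' Connects features of one omics matrix by absolute Pearson correlation
#' across samples, either by thresholding (`|r| >= tau`) or by mutual
#' OR-symmetrized k-nearest neighbours.  Features with zero variance get no
#' connections.  The result feeds the Laplacian noise penalty of the
#' factorization.
#'
#' @param X An [omics_matrix] with at least 3 samples.
#' @param method `"corr_threshold"` (default) or `"knn"`.
#' @param tau Correlation threshold in `[0, 1]` (default 0.8).
#' @param k_neighbors Number of neighbours per feature in `"knn"` mode.
#' @param weighted If `TRUE` surviving edges carry `|r|` instead of 1.
#' @return A [feature_graph] aligned to `X`'s features.
#' @export
build_feature_graph <- function(X, method = c("corr_threshold", "knn"),
                                tau = 0.8, k_neighbors = 10, weighted = FALSE) {
  stopifnot(inherits(X, "omics_matrix"))
  method <- match.arg(method)
  if (nrow(X$values) < 3) stop_validation("need >= 3 samples to correlate features")
  if (tau < 0 || tau > 1) stop_validation("tau must lie in [0, 1]")
  if (method == "knn" && (k_neighbors < 1 || k_neighbors != round(k_neighbors))) {
    stop_validation("k_neighbors must be a positive integer")
  }
  r <- suppressWarnings(stats::cor(X$values))
  r[!is.finite(r)] <- 0     # zero-variance features contribute no edges
  absr <- abs(r)
  diag(absr) <- 0
  p <- ncol(absr)
  if (method == "corr_threshold") {
    A <- (absr >= tau) * 1
  } else {
    k <- min(k_neighbors, p - 1)
    A <- matrix(0, p, p)
    for (j in seq_len(p)) {
      ord <- order(absr[j, ], decreasing = TRUE)[seq_len(k)]
      ord <- ord[absr[j, ord] > 0]
      A[j, ord] <- 1
    }
    A <- pmax(A, t(A))    # OR symmetrization
  }
  if (weighted) A <- A * absr
  diag(A) <- 0
  laplacian_from_adjacency(A, X$feature_ids)
}
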