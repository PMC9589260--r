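#' Construct an omics expression matrix
#'
#' An `omics_matrix` holds one samples x features expression matrix together
#' with its sample and feature identifiers and an omics label (for example
#' `"mRNA"`, `"lncRNA"` or `"miRNA"`).  All matrices entering one joint
#' factorization must share identical sample identifiers in identical order.
#'
#' @param values Numeric matrix, samples in rows and features in columns.
#'   All entries must be finite.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row.  Defaults to the rownames of `values`.
#' @param feature_ids Character vector of unique feature identifiers, one per
#'   column.  Defaults to the colnames of `values`.
#' @param omics_name Single string labelling the omics layer.
#' @return An object of class `omics_matrix` with fields `values`,
#'   `sample_ids`, `feature_ids` and `omics_name`.
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values), omics_name = "omics") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop_validation("omics_matrix requires sample and feature identifiers")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop_validation("number of sample_ids (", length(sample_ids),
                    ") does not match rows (", nrow(values), ")")
  }
  if (length(feature_ids) != ncol(values)) {
    stop_validation("number of feature_ids (", length(feature_ids),
                    ") does not match columns (", ncol(values), ")")
  }
  if (anyDuplicated(sample_ids)) {
    stop_validation("duplicated sample identifiers: ",
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop_validation("duplicated feature identifiers: ",
                    paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_validation("non-finite value at sample '", sample_ids[bad[1]],
                    "', feature '", feature_ids[bad[2]], "'")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, omics_name = omics_name),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix '%s': %d samples x %d features\n",
              x$omics_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited UTF-8 file whose header row carries the feature
#' identifiers and whose first column carries the sample identifiers; the
#' body must be fully numeric and finite.  Files stored features x samples
#' can be read with `transpose = TRUE`.
#'
#' @param path Path to the TSV file.
#' @param omics_name Label attached to the resulting matrix.
#' @param transpose If `TRUE` the file is interpreted as features x samples
#'   and transposed after reading.
#' @return An [omics_matrix].
#' @export
read_omics_matrix <- function(path, omics_name = "omics", transpose = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop_validation("expression TSV '", path, "' has no feature columns")
  row_ids <- raw[[1]]
  feat_ids <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (any(!is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1, ]
    stop_validation("non-numeric cell in '", path, "' at row '", row_ids[bad[1]],
                    "', column '", feat_ids[bad[2]], "' (value '",
                    body[bad[1], bad[2]], "')")
  }
  dimnames(num) <- list(row_ids, feat_ids)
  if (transpose) num <- t(num)
  out <- omics_matrix(num, omics_name = omics_name)
  message(sprintf("read %s: %d samples x %d features from %s",
                  omics_name, nrow(out$values), ncol(out$values), path))
  out
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_omics_matrix()]: values are serialized with 17
#' significant digits so a read/write round trip reproduces them exactly.
#'
#' @param x An [omics_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", x$feature_ids), collapse = "\t"), con)
  body <- apply(x$values, 1, function(r) paste(format_full(r), collapse = "\t"))
  writeLines(paste(x$sample_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Construct a binary feature-interaction prior
#'
#' A `prior_network` is a symmetric 0/1 adjacency over the feature set of one
#' omics matrix, typically protein-protein interactions among the assayed
#' mRNAs.  The diagonal is zero.
#'
#' @param adjacency Square binary matrix (entries 0/1).
#' @param feature_ids Feature identifiers, in the exact order of the target
#'   omics matrix.
#' @return An object of class `prior_network`.
#' @export
prior_network <- function(adjacency, feature_ids) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  feature_ids <- as.character(feature_ids)
  p <- length(feature_ids)
  if (!all(dim(adjacency) == c(p, p))) {
    stop_validation("prior adjacency must be ", p, " x ", p)
  }
  if (!all(adjacency %in% c(0, 1))) stop_validation("prior adjacency entries must be 0 or 1")
  if (max(abs(adjacency - t(adjacency))) > 0) stop_validation("prior adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop_validation("prior adjacency diagonal must be zero")
  dimnames(adjacency) <- list(feature_ids, feature_ids)
  structure(list(adjacency = adjacency, feature_ids = feature_ids),
            class = "prior_network")
}

#' Read a PPI edge list and align it to a feature panel
#'
#' Reads a two- or three-column tab-delimited edge list (source, target and an
#' optional score column, which is ignored: score filtering is assumed to have
#' happened upstream).  Edges naming features outside `features` are dropped
#' with a reported count, self-loops are removed, and the result is
#' symmetrized.
#'
#' @param path Path to the edge-list TSV.
#' @param features Ordered feature identifiers of the omics matrix the prior
#'   attaches to (must be non-empty).
#' @param header Whether the file has a header line (default `FALSE`).
#' @return A [prior_network] over `features`; the number of dropped edges is
#'   available as `attr(, "dropped_edges")`.
#' @export
read_ppi_edges <- function(path, features, header = FALSE) {
  features <- as.character(features)
  if (length(features) == 0) stop_validation("empty feature list for PPI prior")
  tab <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", blank.lines.skip = TRUE)
  if (ncol(tab) < 2) stop_validation("PPI edge list '", path, "' needs >= 2 columns")
  src <- tab[[1]]
  dst <- tab[[2]]
  keep <- src %in% features & dst %in% features & src != dst
  n_drop <- sum((!(src %in% features) | !(dst %in% features)) & src != dst)
  A <- matrix(0, length(features), length(features),
              dimnames = list(features, features))
  if (any(keep)) {
    i <- match(src[keep], features)
    j <- match(dst[keep], features)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  diag(A) <- 0
  message(sprintf("read PPI: %d edges kept, %d dropped (unknown feature IDs) from %s",
                  sum(A) / 2, n_drop, path))
  out <- prior_network(A, features)
  attr(out, "dropped_edges") <- n_drop
  out
}

#' Write a feature-feature adjacency to TSV
#'
#' @param adjacency Square matrix with feature identifiers as dimnames, or a
#'   [prior_network] / [feature_graph] (its connectivity is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adjacency, path) {
  if (inherits(adjacency, "prior_network")) adjacency <- adjacency$adjacency
  if (inherits(adjacency, "feature_graph")) adjacency <- adjacency$connectivity
  ids <- rownames(adjacency) %||% as.character(seq_len(nrow(adjacency)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", ids), collapse = "\t"), con)
  body <- apply(adjacency, 1, function(r) paste(format_full(r), collapse = "\t"))
  writeLines(paste(ids, body, sep = "\t"), con)
  invisible(path)
}
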