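# shared fixtures, all generated in code

rand_omics <- function(n, p, omics_name, seed = NULL, prefix = omics_name) {
  if (!is.null(seed)) set.seed(seed)
  omics_matrix(matrix(rnorm(n * p), n, p),
               sample_ids = sprintf("s%02d", seq_len(n)),
               feature_ids = sprintf("%s_f%02d", prefix, seq_len(p)),
               omics_name = omics_name)
}

# a small three-omics instance with a prior and graphs, for objective and
# gradient tests
small_instance <- function(seed = 1, n = 6, p = c(5, 4, 3)) {
  set.seed(seed)
  X <- list(rand_omics(n, p[1], "mRNA"), rand_omics(n, p[2], "lncRNA"),
            rand_omics(n, p[3], "miRNA"))
  A <- matrix(rbinom(p[1]^2, 1, 0.4), p[1], p[1])
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  P <- prior_network(A, X[[1]]$feature_ids)
  graphs <- lapply(X, build_feature_graph, tau = 0.3)
  list(X = X, P = P, graphs = graphs)
}

# random symmetric nonnegative adjacency with zero diagonal
rand_adjacency <- function(p, density = 0.3, weighted = FALSE) {
  A <- matrix(0, p, p)
  up <- which(upper.tri(A))
  w <- rbinom(length(up), 1, density)
  if (weighted) w <- w * runif(length(up), 0.1, 2)
  A[up] <- w
  A + t(A)
}

# brute-force pairwise form of the Laplacian penalty: the independent oracle
brute_laplacian_penalty <- function(H, A) {
  tot <- 0
  for (p in seq_len(ncol(A))) {
    for (q in seq_len(ncol(A))) {
      tot <- tot + A[p, q] * sum((H[, p] - H[, q])^2)
    }
  }
  tot / 2
}

# brute-force assignment by permutation enumeration (n <= 7)
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) {
      best <- s
      best_p <- p
    }
  }
  list(cost = best, assignment = best_p)
}

write_tsv_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
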