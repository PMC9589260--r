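#' Layer dimension profile
#'
#' Validates a latent dimension vector `k = c(k0, k1, ..., kN)` against the
#' data shapes.  `k0` is the number of factors (and of co-expression
#' modules); deeper dimensions give the sigmoid hierarchy.  `k0` must not
#' exceed the sample count nor any omics' feature count, and the default
#' profile decreases with depth.
#'
#' @param k Vector of positive integers, length >= 2.
#' @param n Optional sample count to validate against.
#' @param p Optional vector of per-omics feature counts.
#' @return `k` as an integer vector, invisibly classed `layer_dims`.
#' @export
layer_dims <- function(k, n = NULL, p = NULL) {
  k <- as.integer(k)
  if (length(k) < 2) stop_validation("layer dims need at least c(k0, k1)")
  if (any(k <= 0)) stop_validation("all layer dims must be positive")
  if (!is.null(n) && k[1] > n) {
    stop_validation("k0 = ", k[1], " exceeds sample count n = ", n)
  }
  if (!is.null(p) && k[1] > min(p)) {
    stop_validation("k0 = ", k[1], " exceeds smallest feature count ", min(p))
  }
  structure(k, class = "layer_dims")
}

n_sublayers <- function(dims) length(dims) - 1L

#' Construct a deep factor model container
#'
#' Holds the shared sample-latent matrix `U` (n x k0, unconstrained sign)
#' and, for each omics `i`, the junction matrices `Z[[i]][[m]]`
#' (`k_{m-1} x k_m`, unconstrained) and the deepest feature-latent matrix
#' `Hdeep[[i]]` (`k_N x p_i`, unconstrained).  The nonnegative intermediate
#' layers are derived, not stored: `H^{m-1} = sigmoid(Z^m %*% H^m)` with
#' `H^N = Hdeep`, so every derived layer lies in `(0, 1)` by construction.
#' The linear ablation variant (`variant = "jnmf"`) instead stores the
#' first-layer coefficients directly in `Hlin` with nonnegativity enforced
#' by projection.
#'
#' @param U Sample-latent matrix.
#' @param Z List (per omics) of lists of junction matrices.
#' @param Hdeep List (per omics) of deepest feature-latent matrices.
#' @param dims Layer dimension vector `c(k0, ..., kN)`.
#' @param omics_names Character vector of omics labels.
#' @param feature_ids List of per-omics feature identifier vectors.
#' @param sample_ids Sample identifiers.
#' @param variant `"pdjdsnmf"`, `"jdsnmf"` or `"jnmf"`.
#' @param Hlin For `variant = "jnmf"`: list of k0 x p_i nonnegative matrices.
#' @return Object of class `deep_factor_model`.
#' @export
deep_factor_model <- function(U, Z, Hdeep, dims, omics_names, feature_ids,
                              sample_ids, variant = "pdjdsnmf", Hlin = NULL) {
  structure(list(U = U, Z = Z, Hdeep = Hdeep, Hlin = Hlin,
                 dims = as.integer(dims), omics_names = omics_names,
                 feature_ids = feature_ids, sample_ids = sample_ids,
                 variant = variant),
            class = "deep_factor_model")
}

#' @export
print.deep_factor_model <- function(x, ...) {
  cat(sprintf("deep_factor_model (%s): n = %d samples, k = [%s], omics: %s\n",
              x$variant, nrow(x$U), paste(x$dims, collapse = ", "),
              paste(x$omics_names, collapse = ", ")))
  invisible(x)
}

n_omics <- function(model) length(model$omics_names)

#' Forward pass through one omics hierarchy
#'
#' Evaluates the derived layers `H^{m-1} = sigmoid(Z^m %*% H^m)` from the
#' deepest stored matrix upward and the reconstruction `Xhat = U %*% H^0`.
#'
#' @param model A [deep_factor_model].
#' @param omics_index Which omics (1-based).
#' @return List with `H0` (k0 x p_i, entries in `(0, 1)` for the deep
#'   variants), `Xhat` (n x p_i) and `layers` (list of all derived layers,
#'   deepest last).
#' @export
forward <- function(model, omics_index) {
  if (model$variant == "jnmf") {
    H0 <- model$Hlin[[omics_index]]
    return(list(H0 = H0, Xhat = model$U %*% H0, layers = list(H0)))
  }
  Zs <- model$Z[[omics_index]]
  N <- length(Zs)
  H <- vector("list", N + 1)       # H[[m + 1]] is layer H^m
  H[[N + 1]] <- model$Hdeep[[omics_index]]
  for (m in N:1) {
    Zm <- Zs[[m]]
    Hm <- H[[m + 1]]
    if (ncol(Zm) != nrow(Hm)) {
      stop_validation("shape mismatch at layer ", m, ": Z is ",
                      nrow(Zm), "x", ncol(Zm), " but H^", m, " is ",
                      nrow(Hm), "x", ncol(Hm))
    }
    H[[m]] <- sigmoid(Zm %*% Hm)
  }
  list(H0 = H[[1]], Xhat = model$U %*% H[[1]], layers = H)
}

# first-layer coefficient matrices for every omics
model_H0 <- function(model) {
  lapply(seq_len(n_omics(model)), function(i) forward(model, i)$H0)
}

#' Reconstruction Pearson correlation
#'
#' Pearson correlation between a data matrix and its model reconstruction,
#' both flattened to vectors.  This is the model-selection score used
#' throughout the package.
#'
#' @param X An [omics_matrix] or plain matrix.
#' @param Xhat Reconstruction of the same shape.
#' @return A number in `[-1, 1]`.
#' @export
reconstruction_correlation <- function(X, Xhat) {
  x <- if (inherits(X, "omics_matrix")) X$values else X
  if (!all(dim(x) == dim(Xhat))) stop_validation("X and Xhat shapes differ")
  a <- as.vector(x)
  b <- as.vector(Xhat)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_numeric("reconstruction correlation undefined: zero variance")
  }
  stats::cor(a, b)
}

# resolve which omics carries the interaction prior; defaults to the omics
# whose feature set matches the prior's node set best
resolve_ppi_omics <- function(X, P, ppi_omics = NULL) {
  if (is.null(P)) return(NA_integer_)
  if (!is.null(ppi_omics)) {
    i <- if (is.character(ppi_omics)) {
      match(ppi_omics, vapply(X, function(x) x$omics_name, ""))
    } else as.integer(ppi_omics)
    if (is.na(i) || i < 1 || i > length(X)) stop_validation("unknown ppi_omics")
  } else {
    overlap <- vapply(X, function(x) sum(x$feature_ids %in% P$feature_ids), 0)
    i <- which.max(overlap)
  }
  if (!identical(X[[i]]$feature_ids, P$feature_ids)) {
    stop_validation("PPI prior features do not match omics '",
                    X[[i]]$omics_name, "' (order-sensitive)")
  }
  i
}

# penalty matrix actually used for the prior term
ppi_penalty_matrix <- function(P, ppi_mode) {
  if (is.null(P)) return(NULL)
  if (ppi_mode == "laplacian") {
    laplacian_from_adjacency(P$adjacency)$laplacian
  } else {
    P$adjacency
  }
}

#' Penalized objective of the joint deep factorization
#'
#' Evaluates
#' `sum_i ||X_i - U H_i^0||_F^2 + lambda1 * sum_S ||S||_F^2 +
#'  lambda2 * Tr(H^0 M t(H^0)) + lambda3 * sum_i Tr(H_i^0 B_i t(H_i^0))`
#' where `S` ranges over `U`, all junction matrices and the deepest layers,
#' `M` is the Laplacian of the interaction prior (`ppi_mode = "laplacian"`,
#' default) or the raw adjacency (`"literal"`), and `B_i` are the per-omics
#' feature-graph Laplacians.  Setting a lambda to zero disables its term.
#'
#' @param model A [deep_factor_model].
#' @param X List of [omics_matrix] objects (one per omics).
#' @param P Optional [prior_network] aligned to one omics.
#' @param graphs Optional list of [feature_graph]s (per omics; `NULL`
#'   entries allowed).
#' @param lambda1,lambda2,lambda3 Nonnegative penalty strengths for the
#'   parameter norms, the interaction prior and the Laplacian smoothing.
#' @param ppi_mode `"laplacian"` or `"literal"`.
#' @param ppi_omics Index or name of the omics carrying the prior
#'   (auto-detected when `NULL`).
#' @return List with `total` and the four `terms`
#'   (`residual`, `norm`, `ppi`, `laplacian`), unweighted.
#' @export
objective <- function(model, X, P = NULL, graphs = NULL,
                      lambda1 = 0, lambda2 = 0, lambda3 = 0,
                      ppi_mode = c("laplacian", "literal"), ppi_omics = NULL) {
  ppi_mode <- match.arg(ppi_mode)
  obj_and_grad(model, X, P, graphs, lambda1, lambda2, lambda3,
               ppi_mode, ppi_omics, want_grad = FALSE)[c("total", "terms")]
}

# Shared objective/gradient engine.  Gradients are the exact analytic
# derivatives: the residual and quadratic penalties act on H^0 and are
# backpropagated through the sigmoid chain (ds = s (1 - s)).
obj_and_grad <- function(model, X, P, graphs, lambda1, lambda2, lambda3,
                         ppi_mode, ppi_omics, want_grad = TRUE,
                         Mppi = NULL, ppi_idx = NULL) {
  I <- n_omics(model)
  if (length(X) != I) stop_validation("model covers ", I, " omics but ", length(X), " matrices given")
  if (is.null(ppi_idx)) ppi_idx <- resolve_ppi_omics(X, P, ppi_omics)
  if (is.null(Mppi)) Mppi <- ppi_penalty_matrix(P, ppi_mode)

  U <- model$U
  residual <- 0; ppi_term <- 0; lap_term <- 0
  gU <- if (want_grad) matrix(0, nrow(U), ncol(U))
  gZ <- vector("list", I); gHdeep <- vector("list", I); gHlin <- vector("list", I)

  for (i in seq_len(I)) {
    fw <- forward(model, i)
    H0 <- fw$H0
    R <- X[[i]]$values - fw$Xhat
    residual <- residual + sum(R * R)

    G0 <- NULL
    if (want_grad) G0 <- -2 * crossprod(U, R)

    Bi <- if (!is.null(graphs) && length(graphs) >= i && !is.null(graphs[[i]])) {
      graphs[[i]]$laplacian
    }
    if (!is.null(Bi) && lambda3 != 0) {
      H0B <- H0 %*% Bi
      lap_term <- lap_term + sum(H0B * H0)
      if (want_grad) G0 <- G0 + 2 * lambda3 * H0B
    } else if (!is.null(Bi)) {
      lap_term <- lap_term + sum((H0 %*% Bi) * H0)
    }
    if (!is.null(Mppi) && i == ppi_idx) {
      H0M <- H0 %*% Mppi
      ppi_term <- ppi_term + sum(H0M * H0)
      if (want_grad && lambda2 != 0) G0 <- G0 + 2 * lambda2 * H0M
    }

    if (want_grad) {
      gU <- gU - 2 * R %*% t(H0)
      if (model$variant == "jnmf") {
        gHlin[[i]] <- G0 + 2 * lambda1 * H0
      } else {
        Zs <- model$Z[[i]]
        N <- length(Zs)
        G <- G0
        gZi <- vector("list", N)
        for (m in seq_len(N)) {
          Hm1 <- fw$layers[[m]]           # H^{m-1} = s(Z^m H^m)
          D <- G * Hm1 * (1 - Hm1)
          gZi[[m]] <- D %*% t(fw$layers[[m + 1]]) + 2 * lambda1 * Zs[[m]]
          G <- crossprod(Zs[[m]], D)
        }
        gZ[[i]] <- gZi
        gHdeep[[i]] <- G + 2 * lambda1 * model$Hdeep[[i]]
      }
    }
  }

  norm_term <- frob2(U)
  if (model$variant == "jnmf") {
    norm_term <- norm_term + sum(vapply(model$Hlin, frob2, 0))
  } else {
    for (i in seq_len(I)) {
      norm_term <- norm_term + sum(vapply(model$Z[[i]], frob2, 0)) +
        frob2(model$Hdeep[[i]])
    }
  }
  if (want_grad) gU <- gU + 2 * lambda1 * U

  total <- residual + lambda1 * norm_term + lambda2 * ppi_term + lambda3 * lap_term
  out <- list(total = total,
              terms = c(residual = residual, norm = norm_term,
                        ppi = ppi_term, laplacian = lap_term))
  if (want_grad) {
    out$grad <- list(U = gU, Z = gZ, Hdeep = gHdeep, Hlin = gHlin)
  }
  out
}

#' SVD-based initialization of the deep factor model
#'
#' Initializes `U` and the first-layer coefficients from a rank-`k0`
#' truncated SVD of the column-concatenated data `[X1 X2 ... ]`, mapping the
#' right factor affinely into `(eps, 1 - eps)`.  Deeper layers are obtained
#' recursively: the current layer is logit-transformed, truncated-SVD
#' factored at the next width, and the right factor squashed back into the
#' unit interval (the deepest layer stays unconstrained, taken directly from
#' the SVD).  Junction matrices at intermediate depths are refit by least
#' squares.  Finally `U` is refit by least squares against the derived
#' `H^0`.  The procedure is deterministic; singular-vector signs follow a
#' fixed largest-entry convention, and `seed` is recorded for provenance.
#'
#' Because the factorization objective is invariant under convex mixing of
#' the factors, the raw singular vectors would start the optimizer in an
#' arbitrarily rotated basin; by default the right factor is therefore
#' rotated to simple structure (varimax) before squashing, which is
#' deterministic, preserves the rank-`k0` reconstruction exactly, and aligns
#' the initial factors with any parts-based structure in the data.
#'
#' @param X List of [omics_matrix] objects sharing samples.
#' @param dims Layer dimension vector `c(k0, ..., kN)`.
#' @param seed Integer recorded with the model.
#' @param eps Margin keeping initial layers strictly inside `(0, 1)`.
#' @param rotate `"varimax"` (default) or `"none"`: simple-structure
#'   rotation of the rank-`k0` right factor.
#' @return A [deep_factor_model].
#' @export
svd_init <- function(X, dims, seed = 0, eps = 1e-4,
                     rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  dims <- layer_dims(dims,
                     n = nrow(X[[1]]$values),
                     p = vapply(X, function(x) ncol(x$values), 0))
  k0 <- dims[1]
  N <- n_sublayers(dims)
  Xcat <- do.call(cbind, lapply(X, function(x) x$values))
  if (k0 > min(dim(Xcat))) {
    stop_validation("k0 = ", k0, " exceeds min(n, total features) = ", min(dim(Xcat)))
  }
  set.seed(seed)
  sv <- fix_svd_signs(svd(Xcat, nu = k0, nv = k0))
  V0 <- sv$v[, seq_len(k0), drop = FALSE]
  if (rotate == "varimax" && k0 > 1) {
    V0 <- V0 %*% stats::varimax(V0, normalize = FALSE)$rotmat
    for (j in seq_len(k0)) {              # point each factor "upward"
      if (V0[which.max(abs(V0[, j])), j] < 0) V0[, j] <- -V0[, j]
    }
  }
  H0raw <- t(V0)
  H0cat <- squash_unit(H0raw, eps)

  p <- vapply(X, function(x) ncol(x$values), 0)
  ends <- cumsum(p)
  starts <- c(1, utils::head(ends, -1) + 1)

  build_chains <- function(H0target_cat) {
    Z <- vector("list", length(X))
    Hdeep <- vector("list", length(X))
    for (i in seq_along(X)) {
      ch <- decompose_chain(H0target_cat[, starts[i]:ends[i], drop = FALSE],
                            dims, eps)
      Z[[i]] <- ch$Z
      Hdeep[[i]] <- ch$Hdeep
    }
    list(Z = Z, Hdeep = Hdeep)
  }

  ch <- build_chains(H0cat)
  model <- deep_factor_model(
    U = matrix(0, nrow(Xcat), k0), Z = ch$Z, Hdeep = ch$Hdeep, dims = dims,
    omics_names = vapply(X, function(x) x$omics_name, ""),
    feature_ids = lapply(X, function(x) x$feature_ids),
    sample_ids = X[[1]]$sample_ids)
  H0d <- do.call(cbind, model_H0(model))
  model$U <- ls_right_solve(Xcat, H0d)   # U = argmin ||Xcat - U H0||_F

  # alternating refinement: the new first-layer target clamp(pinv(U) X) is
  # lossless where the data truly admit (0, 1) coefficients; the alternation
  # is not monotone, so keep the best pass by residual
  best <- list(model = model, rss = frob2(Xcat - model$U %*% H0d))
  for (pass in 1:4) {
    H0tgt <- ls_right_solve(t(Xcat), t(model$U))   # = argmin ||X - U H||, p x k0
    H0tgt <- pmin(pmax(t(H0tgt), eps), 1 - eps)
    ch <- build_chains(H0tgt)
    model$Z <- ch$Z
    model$Hdeep <- ch$Hdeep
    H0d <- do.call(cbind, model_H0(model))
    model$U <- ls_right_solve(Xcat, H0d)
    rss <- frob2(Xcat - model$U %*% H0d)
    if (rss < best$rss) best <- list(model = model, rss = rss)
  }
  best$model
}

# Recursive truncated-SVD decomposition of one first-layer block into a
# sigmoid chain: Z^1..Z^N and the unconstrained deepest layer, followed by a
# bottom-up least-squares refit of each junction against its layer target.
decompose_chain <- function(H0block, dims, eps = 1e-4) {
  if (!all(is.finite(H0block))) {
    stop_numeric("non-finite values during initialization; ",
                 "check the input scale")
  }
  N <- length(dims) - 1L
  targets <- vector("list", N)             # targets[[m]] approximates H^{m-1}
  targets[[1]] <- H0block
  Zi <- vector("list", N)
  Hdeep <- NULL
  for (m in seq_len(N)) {
    Tm <- logit(targets[[m]])
    r <- dims[m + 1]
    svt <- fix_svd_signs(svd(Tm, nu = r, nv = r))
    B <- diag(svt$d[seq_len(r)], r) %*% t(svt$v[, seq_len(r), drop = FALSE])
    if (m == N) {
      Zi[[m]] <- svt$u[, seq_len(r), drop = FALSE]
      Hdeep <- B
    } else {
      Hnext <- squash_unit(B, eps)
      Zm <- ls_right_solve(Tm, Hnext)
      # a few rounds of alternating least squares in logit space tighten the
      # truncated factorization before descending
      for (it in 1:3) {
        Hnext <- pmin(pmax(ls_left_solve(Zm, Tm), eps), 1 - eps)
        Zm <- ls_right_solve(Tm, Hnext)
      }
      Zi[[m]] <- Zm
      targets[[m + 1]] <- Hnext            # descend to the next layer
    }
  }
  Hder <- Hdeep
  for (m in N:1) {
    Zi[[m]] <- ls_right_solve(logit(targets[[m]]), Hder)
    Hder <- sigmoid(Zi[[m]] %*% Hder)
    Hder <- pmin(pmax(Hder, eps), 1 - eps)
  }
  list(Z = Zi, Hdeep = Hdeep)
}
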