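# min-max scale each feature column into [0, 1]; constant columns map to 0.5
scale_features <- function(X) {
  lapply(X, function(x) {
    v <- x$values
    mn <- apply(v, 2, min)
    rg <- apply(v, 2, max) - mn
    flat <- rg <= 0
    rg[flat] <- 1
    v <- sweep(sweep(v, 2, mn, "-"), 2, rg, "/")
    v[, flat] <- 0.5
    out <- x
    out$values <- v
    attr(out, "scale_min") <- mn
    attr(out, "scale_range") <- rg
    out
  })
}

validate_inputs <- function(X, P, graphs) {
  if (!is.list(X) || !all(vapply(X, inherits, TRUE, "omics_matrix"))) {
    stop_validation("X must be a list of omics_matrix objects")
  }
  sids <- X[[1]]$sample_ids
  for (x in X[-1]) {
    if (!identical(x$sample_ids, sids)) {
      stop_validation("omics '", x$omics_name,
                      "' does not share the sample order of '", X[[1]]$omics_name, "'")
    }
  }
  if (!is.null(graphs)) {
    for (i in seq_along(graphs)) {
      g <- graphs[[i]]
      if (is.null(g)) next
      if (!inherits(g, "feature_graph")) stop_validation("graphs[[", i, "]] is not a feature_graph")
      if (!identical(g$feature_ids, X[[i]]$feature_ids)) {
        stop_validation("graph ", i, " features do not match omics '",
                        X[[i]]$omics_name, "'")
      }
    }
  }
  invisible(TRUE)
}

# flatten/unflatten parameter lists for the optimizer
collect_params <- function(model) {
  if (model$variant == "jnmf") {
    c(list(model$U), model$Hlin)
  } else {
    c(list(model$U), unlist(model$Z, recursive = FALSE), model$Hdeep)
  }
}

collect_grads <- function(model, grad) {
  if (model$variant == "jnmf") {
    c(list(grad$U), grad$Hlin)
  } else {
    c(list(grad$U), unlist(grad$Z, recursive = FALSE), grad$Hdeep)
  }
}

inject_params <- function(model, params) {
  model$U <- params[[1]]
  I <- n_omics(model)
  if (model$variant == "jnmf") {
    # classical joint NMF constrains both factors nonnegative
    model$U <- pmax(model$U, 0)
    model$Hlin <- lapply(params[1 + seq_len(I)], function(h) pmax(h, 0))
  } else {
    N <- n_sublayers(model$dims)
    idx <- 1
    for (i in seq_len(I)) {
      for (m in seq_len(N)) {
        idx <- idx + 1
        model$Z[[i]][[m]] <- params[[idx]]
      }
    }
    model$Hdeep <- params[idx + seq_len(I)]
  }
  model
}

#' Fit the penalized joint deep factorization
#'
#' Minimizes the [objective()] by full-batch first-order descent with
#' adaptive moment estimation on `U`, the junction matrices and the deepest
#' feature layers (nonnegativity of the derived layers is automatic through
#' the sigmoid chain).  Each step is accepted only if it does not increase
#' the objective; otherwise the step size is halved and the step retried, so
#' the objective trace is non-increasing.  Iteration stops when the relative
#' objective change drops below `tol` or at `max_iter`.
#'
#' @param X List of [omics_matrix] objects over identical samples.
#' @param dims Layer dimension vector `c(k0, ..., kN)`.
#' @param P Optional [prior_network] (the PPI prior).
#' @param graphs Optional list of per-omics [feature_graph]s.
#' @param lambda1,lambda2,lambda3 Penalty strengths (parameter norms, PPI
#'   prior, Laplacian smoothing).  Defaults are the grid-selected values
#'   `0.001, 0.1, 0.01`.
#' @param max_iter Maximum iterations (default 2000).
#' @param tol Relative objective-change tolerance (default 1e-5).
#' @param learning_rate Initial adaptive-moment step size (default 1e-2).
#' @param ppi_mode `"laplacian"` (default) or `"literal"` prior penalty.
#' @param ppi_omics Index/name of the omics carrying the prior; auto-detected.
#' @param seed Integer seed recorded and used for any stochastic choices.
#' @param scale If `TRUE` (default) min-max scale each feature to `[0, 1]`
#'   before fitting; reconstruction correlations then refer to the scaled
#'   data the model saw.
#' @param variant `"pdjdsnmf"` (full model), `"jdsnmf"` (forces
#'   `lambda2 = lambda3 = 0`) or `"jnmf"` (single linear nonnegative layer).
#' @param init Optional starting [deep_factor_model]; default [svd_init()].
#' @param verbose Print progress every 100 iterations.
#' @return Object of class `pdjdsnmf_fit` with fields `model`,
#'   `objective_trace`, `term_trace` (matrix with columns residual, norm,
#'   ppi, laplacian), `recon_corr` (per omics plus `"mean"`), `converged`,
#'   `iterations`, `seed`, `lambda`, `ppi_mode`, `scaled`, `scaling`.
#' @export
fit_pdjdsnmf <- function(X, dims, P = NULL, graphs = NULL,
                         lambda1 = 0.001, lambda2 = 0.1, lambda3 = 0.01,
                         max_iter = 2000, tol = 1e-5, learning_rate = 1e-2,
                         ppi_mode = c("laplacian", "literal"), ppi_omics = NULL,
                         seed = 0, scale = TRUE,
                         variant = c("pdjdsnmf", "jdsnmf", "jnmf"),
                         init = NULL, verbose = FALSE) {
  ppi_mode <- match.arg(ppi_mode)
  variant <- match.arg(variant)
  validate_inputs(X, P, graphs)
  if (any(c(lambda1, lambda2, lambda3) < 0)) stop_validation("lambdas must be >= 0")
  if (variant != "pdjdsnmf") {
    lambda2 <- 0; lambda3 <- 0
  }

  scaling <- NULL
  if (scale) {
    raw <- X
    X <- scale_features(X)
    scaling <- Map(function(x, r) {
      list(min = attr(x, "scale_min"), range = attr(x, "scale_range"),
           flat = apply(r$values, 2, function(col) max(col) == min(col)))
    }, X, raw)
  }
  dims <- layer_dims(dims, n = nrow(X[[1]]$values),
                     p = vapply(X, function(x) ncol(x$values), 0))

  set.seed(seed)
  model <- if (!is.null(init)) init else svd_init(X, dims, seed = seed)
  if (variant == "jnmf") {
    H0 <- model_H0(model)
    model$Hlin <- lapply(H0, pmax, 0)
    model$U <- pmax(model$U, 0)
    model$variant <- "jnmf"
  } else {
    model$variant <- variant
  }

  ppi_idx <- resolve_ppi_omics(X, P, ppi_omics)
  Mppi <- ppi_penalty_matrix(P, ppi_mode)

  eval_all <- function(mod, want_grad) {
    obj_and_grad(mod, X, P, graphs, lambda1, lambda2, lambda3,
                 ppi_mode, ppi_omics, want_grad = want_grad,
                 Mppi = Mppi, ppi_idx = ppi_idx)
  }

  cur <- eval_all(model, want_grad = TRUE)
  if (!is.finite(cur$total)) stop_numeric("objective not finite at initialization")

  params <- collect_params(model)
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  lr <- learning_rate
  trace <- numeric(max_iter + 1)
  terms <- matrix(0, max_iter + 1, 4,
                  dimnames = list(NULL, c("residual", "norm", "ppi", "laplacian")))
  trace[1] <- cur$total
  terms[1, ] <- cur$terms
  converged <- FALSE
  it <- 0

  backtrack <- function(dir, lr0, halvings) {
    lr_try <- lr0
    for (h in seq_len(halvings)) {
      cand_params <- Map(function(p, d) p - lr_try * d, params, dir)
      cand_model <- inject_params(model, cand_params)
      cand <- eval_all(cand_model, want_grad = TRUE)
      if (is.finite(cand$total) && cand$total <= cur$total * (1 + 1e-12)) {
        return(list(model = cand_model, eval = cand, lr = lr_try))
      }
      lr_try <- lr_try / 2
    }
    NULL
  }

  for (it in seq_len(max_iter)) {
    g <- collect_grads(model, cur$grad)
    m1n <- Map(function(m, gr) b1 * m + (1 - b1) * gr, m1, g)
    m2n <- Map(function(v, gr) b2 * v + (1 - b2) * gr * gr, m2, g)
    c1 <- 1 - b1^it
    c2 <- 1 - b2^it
    dir <- Map(function(m, v) (m / c1) / (sqrt(v / c2) + adam_eps), m1n, m2n)

    step <- backtrack(dir, lr, 20)
    if (!is.null(step)) {
      m1 <- m1n
      m2 <- m2n
    } else {
      # adaptive direction no longer descends: restart the moments and fall
      # back to plain gradient descent with backtracking
      gnorm <- sqrt(sum(vapply(g, frob2, 0)))
      step <- backtrack(g, lr / max(gnorm, 1), 60)
      if (is.null(step)) {              # stationary point
        converged <- TRUE
        it <- it - 1
        break
      }
      m1 <- lapply(params, function(p) p * 0)
      m2 <- m1
    }
    cand_model <- step$model
    cand <- step$eval
    lr_try <- step$lr
    lr <- min(lr_try * 1.25, learning_rate)
    # for the projected (jnmf) variant keep the clamped values as the state
    params <- collect_params(cand_model)
    model <- cand_model
    rel_change <- (cur$total - cand$total) / max(cand$total, .Machine$double.xmin)
    cur <- cand
    trace[it + 1] <- cur$total
    terms[it + 1, ] <- cur$terms
    if (verbose && it %% 100 == 0) {
      message(sprintf("iter %4d  objective %.6g", it, cur$total))
    }
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }

  trace <- trace[seq_len(it + 1)]
  terms <- terms[seq_len(it + 1), , drop = FALSE]
  rc <- vapply(seq_along(X), function(i) {
    reconstruction_correlation(X[[i]], forward(model, i)$Xhat)
  }, 0)
  names(rc) <- vapply(X, function(x) x$omics_name, "")
  rc <- c(rc, mean = mean(rc))

  structure(list(model = model, objective_trace = trace, term_trace = terms,
                 recon_corr = rc, converged = converged, iterations = it,
                 seed = seed,
                 lambda = c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
                 ppi_mode = ppi_mode, variant = variant,
                 scaled = scale, scaling = scaling),
            class = "pdjdsnmf_fit")
}

#' @export
print.pdjdsnmf_fit <- function(x, ...) {
  cat(sprintf("pdjdsnmf_fit (%s): %d iterations%s, objective %.6g\n",
              x$variant, x$iterations,
              if (x$converged) " (converged)" else "", utils::tail(x$objective_trace, 1)))
  cat("  reconstruction correlations:",
      paste(sprintf("%s=%.4f", names(x$recon_corr), x$recon_corr), collapse = "  "), "\n")
  invisible(x)
}

# apply the fit's stored feature scaling to raw data (identity if unscaled)
apply_fit_scaling <- function(fit, X) {
  if (!isTRUE(fit$scaled)) return(X)
  Map(function(x, s) {
    v <- sweep(sweep(x$values, 2, s$min, "-"), 2, s$range, "/")
    v[, s$flat] <- 0.5
    out <- x
    out$values <- v
    out
  }, X, fit$scaling)
}
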