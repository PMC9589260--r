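#' Penalty-grid model selection
#'
#' Fits the model at every combination `(lambda1, lambda2, lambda3)` drawn
#' from `grid^3` (27 combinations for the default three-point grid), all with
#' the same seed and initialization so that differences reflect the
#' penalties, and scores each by per-omics and mean reconstruction Pearson
#' correlation.  `lambda3` varies fastest, then `lambda2`, then `lambda1`;
#' the 1-based `combination` index follows that order.  The best combination
#' maximizes the mean correlation.
#'
#' @param X List of [omics_matrix] objects.
#' @param dims Layer dimension vector.
#' @param grid Numeric vector of candidate penalty values
#'   (default `c(0.001, 0.01, 0.1)`).
#' @param P,graphs Priors passed to [fit_pdjdsnmf()].
#' @param ... Further fit options (`max_iter`, `seed`, ...).
#' @return `data.frame` with columns `combination`, `lambda1`, `lambda2`,
#'   `lambda3`, one `corr_<omics>` per omics, `corr_mean` and `best`
#'   (logical).  A diverged fit leaves `NA` correlations.  The best row
#'   index is in `attr(, "best")`.
#' @export
lambda_grid_search <- function(X, dims, grid = c(0.001, 0.01, 0.1),
                               P = NULL, graphs = NULL, ...) {
  if (length(grid) == 0) stop_validation("empty penalty grid")
  combos <- expand.grid(lambda3 = grid, lambda2 = grid, lambda1 = grid,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, c("lambda1", "lambda2", "lambda3")]
  omics <- vapply(X, function(x) x$omics_name, "")
  res <- matrix(NA_real_, nrow(combos), length(omics) + 1)
  colnames(res) <- c(paste0("corr_", omics), "corr_mean")
  for (r in seq_len(nrow(combos))) {
    fit <- tryCatch(
      fit_pdjdsnmf(X, dims, P = P, graphs = graphs,
                   lambda1 = combos$lambda1[r], lambda2 = combos$lambda2[r],
                   lambda3 = combos$lambda3[r], ...),
      pdjdsnmf_numeric_error = function(e) NULL)
    if (!is.null(fit)) res[r, ] <- fit$recon_corr
  }
  out <- cbind(data.frame(combination = seq_len(nrow(combos))), combos,
               as.data.frame(res))
  best <- if (all(is.na(out$corr_mean))) NA_integer_ else which.max(out$corr_mean)
  out$best <- seq_len(nrow(out)) == best
  attr(out, "best") <- best
  out
}

#' Layer-dimension sweep
#'
#' Fits the model once per candidate dimension profile (shared seed) and
#' tabulates the per-omics reconstruction correlations with their mean and
#' standard deviation, mirroring the usual rank-selection table.  The
#' selected profile maximizes the mean correlation, with ties broken by the
#' smallest population standard deviation.  Both the population
#' (`corr_sd`, divisor `m`) and sample (`corr_sd_sample`, divisor `m - 1`)
#' deviations are reported to avoid convention ambiguity.
#'
#' @param X List of [omics_matrix] objects.
#' @param candidates List of dimension vectors `c(k0, ..., kN)`.
#' @param P,graphs Priors passed to [fit_pdjdsnmf()].
#' @param ... Further fit options.
#' @return `data.frame`, rows in input order, with columns `k0..k<N>`,
#'   `corr_<omics>`, `corr_mean`, `corr_sd`, `corr_sd_sample`, `selected`.
#' @export
dims_sweep <- function(X, candidates, P = NULL, graphs = NULL, ...) {
  if (length(candidates) == 0) stop_validation("no dimension candidates")
  omics <- vapply(X, function(x) x$omics_name, "")
  maxlen <- max(vapply(candidates, length, 0))
  rows <- lapply(candidates, function(k) {
    fit <- tryCatch(
      fit_pdjdsnmf(X, k, P = P, graphs = graphs, ...),
      pdjdsnmf_numeric_error = function(e) NULL)
    rc <- if (is.null(fit)) rep(NA_real_, length(omics)) else
      fit$recon_corr[seq_along(omics)]
    kk <- c(k, rep(NA, maxlen - length(k)))
    m <- mean(rc)
    sd_pop <- sqrt(mean((rc - m)^2))
    row <- as.list(c(kk, rc, m, sd_pop, stats::sd(rc)))
    names(row) <- c(paste0("k", seq_along(kk) - 1), paste0("corr_", omics),
                    "corr_mean", "corr_sd", "corr_sd_sample")
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  sel <- order(-out$corr_mean, out$corr_sd)[1]
  out$selected <- seq_len(nrow(out)) == sel & !is.na(out$corr_mean)
  attr(out, "selected") <- sel
  out
}

#' Fit an ablation variant
#'
#' `"pdjdsnmf"` is the full prior-regularized deep model; `"jdsnmf"` drops
#' the interaction-prior and Laplacian penalties (`lambda2 = lambda3 = 0`);
#' `"jnmf"` additionally replaces the sigmoid hierarchy by a single linear
#' coefficient layer with nonnegativity enforced by projection.
#'
#' @param X List of [omics_matrix] objects.
#' @param dims Layer dimension vector (only `k0` is used by `"jnmf"`).
#' @param variant One of `"pdjdsnmf"`, `"jdsnmf"`, `"jnmf"`.
#' @param P,graphs Priors (ignored by the ablated variants).
#' @param ... Further fit options, including the lambdas.
#' @return A `pdjdsnmf_fit`.
#' @export
ablation_fit <- function(X, dims, variant = c("pdjdsnmf", "jdsnmf", "jnmf"),
                         P = NULL, graphs = NULL, ...) {
  variant <- match.arg(variant)
  fit_pdjdsnmf(X, dims, P = P, graphs = graphs, variant = variant, ...)
}
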