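#' Extract co-expression modules by coefficient z-scores
#'
#' Each of the `k0` latent factors defines one module.  For every omics the
#' factor's row of the first-layer coefficient matrix `H^0` is standardized
#' across features (`z = (h - mean) / sd`), and a feature joins the module
#' when its z-score reaches `zscore_threshold` (or `|z|` does, with
#' `two_sided = TRUE`).  A feature may belong to several modules; a constant
#' row contributes no members.
#'
#' @param fit A `pdjdsnmf_fit` or [deep_factor_model].
#' @param zscore_threshold Positive membership threshold (default 1.96, the
#'   two-sided 5\% normal tail).
#' @param two_sided Threshold `|z|` instead of `z` (default `FALSE`).
#' @return Object of class `module_set`: list with `modules` (length `k0`;
#'   each has `factor_index`, `members` — a per-omics list of data frames
#'   with `feature` and `z` — and `correlation`, `NA` until scored),
#'   `k0`, `threshold`, `two_sided`, `omics_names`.
#' @export
extract_modules <- function(fit, zscore_threshold = 1.96, two_sided = FALSE) {
  model <- if (inherits(fit, "pdjdsnmf_fit")) fit$model else fit
  if (!inherits(model, "deep_factor_model")) {
    stop_validation("fit must be a pdjdsnmf_fit or deep_factor_model")
  }
  if (zscore_threshold <= 0) stop_validation("zscore_threshold must be > 0")
  H0 <- model_H0(model)
  k0 <- model$dims[1]
  dropped <- 0L
  modules <- lapply(seq_len(k0), function(r) {
    members <- lapply(seq_along(H0), function(i) {
      h <- H0[[i]][r, ]
      s <- stats::sd(h)
      if (!is.finite(s) || s == 0) {
        dropped <<- dropped + 1L
        return(data.frame(feature = character(0), z = numeric(0)))
      }
      z <- (h - mean(h)) / s
      sel <- if (two_sided) abs(z) >= zscore_threshold else z >= zscore_threshold
      data.frame(feature = model$feature_ids[[i]][sel], z = z[sel])
    })
    names(members) <- model$omics_names
    list(factor_index = r, members = members, correlation = NA_real_)
  })
  if (dropped > 0) {
    message(dropped, " constant factor row(s) contributed no members")
  }
  structure(list(modules = modules, k0 = k0, threshold = zscore_threshold,
                 two_sided = two_sided, omics_names = model$omics_names),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (z >= %.3g%s) over omics %s\n",
              x$k0, x$threshold, if (x$two_sided) ", two-sided" else "",
              paste(x$omics_names, collapse = ", ")))
  invisible(x)
}

#' Reconstruction correlation of one module
#'
#' Pearson correlation between the data restricted to the module's member
#' features and the corresponding columns of the reconstruction `U %*% H^0`,
#' flattened and pooled across all omics.  When the module came from a fit
#' with feature scaling, pass the raw data and the fit; the fit's scaling is
#' applied so data and reconstruction live on the same scale.
#'
#' @param module One element of a `module_set`'s `modules` list.
#' @param fit A `pdjdsnmf_fit` (or [deep_factor_model] if no scaling).
#' @param X List of [omics_matrix] objects as used for fitting.
#' @return A number in `[-1, 1]`, or `NA` for an empty module.
#' @export
module_correlation <- function(module, fit, X) {
  model <- if (inherits(fit, "pdjdsnmf_fit")) fit$model else fit
  if (inherits(fit, "pdjdsnmf_fit")) X <- apply_fit_scaling(fit, X)
  xs <- c(); hs <- c()
  for (i in seq_along(X)) {
    feats <- module$members[[i]]$feature
    if (length(feats) == 0) next
    idx <- match(feats, X[[i]]$feature_ids)
    fw <- forward(model, i)
    xs <- c(xs, as.vector(X[[i]]$values[, idx, drop = FALSE]))
    hs <- c(hs, as.vector(fw$Xhat[, idx, drop = FALSE]))
  }
  if (length(xs) < 2 || stats::sd(xs) == 0 || stats::sd(hs) == 0) return(NA_real_)
  stats::cor(xs, hs)
}

#' Score every module's reconstruction correlation
#'
#' @param ms A `module_set`.
#' @param fit The fit the modules came from.
#' @param X The data used for fitting (raw scale).
#' @return `ms` with each module's `correlation` filled in.
#' @export
score_modules <- function(ms, fit, X) {
  ms$modules <- lapply(ms$modules, function(mod) {
    mod$correlation <- module_correlation(mod, fit, X)
    mod
  })
  ms
}

#' Tabulate a module set
#'
#' One row per module with per-omics member counts and the module's
#' reconstruction correlation, ranked by correlation.  Mean member counts
#' across modules are attached as `attr(, "mean_members")`.
#'
#' @param ms A `module_set`.
#' @return A `data.frame` with columns `module`, `n_<omics>` for each omics,
#'   `correlation` and `rank`.
#' @export
module_summary <- function(ms) {
  if (length(ms$modules) == 0) {
    out <- data.frame(module = integer(0), correlation = numeric(0))
    attr(out, "mean_members") <- stats::setNames(numeric(length(ms$omics_names)),
                                          ms$omics_names)
    return(out)
  }
  counts <- t(vapply(ms$modules, function(mod) {
    vapply(mod$members, nrow, 0L)
  }, integer(length(ms$omics_names))))
  out <- data.frame(module = vapply(ms$modules,
                                    function(m) as.integer(m$factor_index), 0L))
  for (j in seq_along(ms$omics_names)) {
    out[[paste0("n_", ms$omics_names[j])]] <- counts[, j]
  }
  out$correlation <- vapply(ms$modules, function(m) m$correlation, 0)
  out$rank <- rank(-out$correlation, ties.method = "first", na.last = "keep")
  attr(out, "mean_members") <- stats::setNames(colMeans(counts), ms$omics_names)
  out
}

#' Serialize a module set
#'
#' Writes the module set as JSON (full structure) and/or a flat TSV with one
#' row per (module, omics, feature, z).
#'
#' @param ms A `module_set`.
#' @param json_path,tsv_path Output paths; `NULL` skips that format.
#' @return Invisibly, the list of paths written.
#' @export
write_module_set <- function(ms, json_path = NULL, tsv_path = NULL) {
  written <- list()
  if (!is.null(json_path)) {
    payload <- list(
      k0 = ms$k0, threshold = ms$threshold, two_sided = ms$two_sided,
      modules = lapply(ms$modules, function(mod) {
        list(factor_index = mod$factor_index,
             correlation = mod$correlation,
             members = lapply(mod$members, function(df) {
               list(id = df$feature, z = df$z)
             }))
      }))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    written$json <- json_path
  }
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(ms$modules, function(mod) {
      do.call(rbind, lapply(names(mod$members), function(om) {
        df <- mod$members[[om]]
        if (nrow(df) == 0) return(NULL)
        data.frame(module = mod$factor_index, omics = om,
                   feature = df$feature, z = df$z)
      }))
    }))
    if (is.null(rows)) {
      rows <- data.frame(module = integer(0), omics = character(0),
                         feature = character(0), z = numeric(0))
    }
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$tsv <- tsv_path
  }
  invisible(written)
}

#' Read a module set written by [write_module_set()]
#'
#' @param json_path Path to the JSON serialization.
#' @return A `module_set`.
#' @export
read_module_set <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  modules <- lapply(payload$modules, function(mod) {
    members <- lapply(mod$members, function(m) {
      ids <- as.character(unlist(m$id))
      z <- if (length(m$z) == 0) numeric(0) else {
        vapply(m$z, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
      }
      if (length(z) != length(ids)) z <- rep(NA_real_, length(ids))
      data.frame(feature = ids, z = z)
    })
    list(factor_index = mod$factor_index,
         members = members,
         correlation = if (is.null(mod$correlation)) NA_real_ else mod$correlation)
  })
  structure(list(modules = modules, k0 = payload$k0,
                 threshold = payload$threshold,
                 two_sided = isTRUE(payload$two_sided),
                 omics_names = names(payload$modules[[1]]$members)),
            class = "module_set")
}
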