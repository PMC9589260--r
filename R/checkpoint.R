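write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(m)), function(r) {
    paste(format_full(m[r, ]), collapse = "\t")
  }, ""), con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a fitted model checkpoint
#'
#' Serializes a fit as a directory of TSV matrices (`U`, per-omics junction
#' matrices, deepest layers, derived first layers, the objective trace) plus
#' a JSON manifest holding dimensions, penalties, seed, omics names, feature
#' and sample identifiers, scaling and convergence metadata.  Checkpoints
#' are plain text and fully reproduce the model on reading.
#'
#' @param fit A `pdjdsnmf_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_checkpoint <- function(fit, dir) {
  stopifnot(inherits(fit, "pdjdsnmf_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- fit$model
  write_matrix_tsv(model$U, file.path(dir, "U.tsv"))
  I <- n_omics(model)
  for (i in seq_len(I)) {
    om <- model$omics_names[i]
    if (model$variant == "jnmf") {
      write_matrix_tsv(model$Hlin[[i]], file.path(dir, sprintf("Hlin_%s.tsv", om)))
    } else {
      for (m in seq_along(model$Z[[i]])) {
        write_matrix_tsv(model$Z[[i]][[m]],
                         file.path(dir, sprintf("Z%d_%s.tsv", m, om)))
      }
      write_matrix_tsv(model$Hdeep[[i]], file.path(dir, sprintf("Hdeep_%s.tsv", om)))
    }
    write_matrix_tsv(forward(model, i)$H0, file.path(dir, sprintf("H0_%s.tsv", om)))
  }
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trace) - 1,
               objective = format_full(fit$objective_trace),
               apply(fit$term_trace, 2, format_full)),
    file.path(dir, "objective_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pdjdsnmf")),
    variant = model$variant, dims = model$dims,
    omics_names = model$omics_names,
    sample_ids = model$sample_ids, feature_ids = model$feature_ids,
    lambda = as.list(fit$lambda), ppi_mode = fit$ppi_mode, seed = fit$seed,
    iterations = fit$iterations, converged = fit$converged,
    recon_corr = as.list(fit$recon_corr),
    scaled = fit$scaled,
    scaling = if (isTRUE(fit$scaled)) fit$scaling else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a model checkpoint
#'
#' @param dir Directory written by [write_checkpoint()].
#' @return A `pdjdsnmf_fit` (model, trace and metadata restored).
#' @export
read_checkpoint <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  omics <- manifest$omics_names
  dims <- as.integer(manifest$dims)
  U <- read_matrix_tsv(file.path(dir, "U.tsv"))
  feature_ids <- manifest$feature_ids
  if (is.data.frame(feature_ids)) feature_ids <- as.list(feature_ids)
  variant <- manifest$variant
  Z <- NULL; Hdeep <- NULL; Hlin <- NULL
  if (variant == "jnmf") {
    Hlin <- lapply(omics, function(om) {
      read_matrix_tsv(file.path(dir, sprintf("Hlin_%s.tsv", om)))
    })
  } else {
    N <- length(dims) - 1
    Z <- lapply(omics, function(om) {
      lapply(seq_len(N), function(m) {
        read_matrix_tsv(file.path(dir, sprintf("Z%d_%s.tsv", m, om)))
      })
    })
    Hdeep <- lapply(omics, function(om) {
      read_matrix_tsv(file.path(dir, sprintf("Hdeep_%s.tsv", om)))
    })
  }
  model <- deep_factor_model(
    U = U, Z = Z, Hdeep = Hdeep, dims = dims, omics_names = omics,
    feature_ids = feature_ids, sample_ids = manifest$sample_ids,
    variant = variant, Hlin = Hlin)
  tr <- utils::read.table(file.path(dir, "objective_trace.tsv"),
                          header = TRUE, sep = "\t")
  scaling <- NULL
  if (isTRUE(manifest$scaled) && !is.null(manifest$scaling)) {
    scaling <- lapply(manifest$scaling, function(s) {
      list(min = as.numeric(s$min), range = as.numeric(s$range),
           flat = as.logical(s$flat))
    })
  }
  structure(list(model = model, objective_trace = tr$objective,
                 term_trace = as.matrix(tr[, c("residual", "norm", "ppi", "laplacian")]),
                 recon_corr = unlist(manifest$recon_corr),
                 converged = manifest$converged,
                 iterations = manifest$iterations, seed = manifest$seed,
                 lambda = unlist(manifest$lambda), ppi_mode = manifest$ppi_mode,
                 variant = variant, scaled = isTRUE(manifest$scaled),
                 scaling = scaling),
            class = "pdjdsnmf_fit")
}
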