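#' Specification of a planted synthetic multi-omics instance
#'
#' Describes three coupled expression matrices generated from one shared
#' sample-latent matrix through a layered sigmoid hierarchy with planted
#' feature modules, additive Gaussian noise, and an interaction prior whose
#' edges are enriched inside the planted modules of the first omics
#' (playing the mRNA role).  Defaults mimic the mRNA >> lncRNA >> miRNA
#' feature-count ordering of bulk heart-tissue panels at desk scale.
#'
#' @param n Sample count (default 100).
#' @param p Per-omics feature counts (default `c(300, 120, 30)`).
#' @param dims Layer dimension vector; `dims[1]` is the planted module count
#'   (default `c(10, 8, 6, 4)`).
#' @param module_size Per-omics member count of each planted module
#'   (default `c(20, 8, 3)`); modules are disjoint when
#'   `dims[1] * module_size <= p`, otherwise membership is sampled with
#'   overlap.
#' @param snr Signal-to-noise variance ratio, linear scale (default 10).
#' @param ppi_within_prob,ppi_between_prob Edge probabilities inside versus
#'   across planted first-omics modules (defaults 0.5 and 0.01).
#' @param logit_amplitude Half-separation of member versus background
#'   first-layer logits (default 3, i.e. loadings near 0.95 vs 0.05).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 100, p = c(300, 120, 30), dims = c(10, 8, 6, 4),
                           module_size = c(20, 8, 3), snr = 10,
                           ppi_within_prob = 0.5, ppi_between_prob = 0.01,
                           logit_amplitude = 3, seed = 0) {
  if (length(p) != 3 || length(module_size) != 3) {
    stop_validation("p and module_size must have length 3")
  }
  dims <- layer_dims(dims, n = n, p = p)
  if (any(module_size > p)) stop_validation("module_size exceeds feature count")
  if (snr <= 0) stop_validation("snr must be > 0")
  if (ppi_within_prob < ppi_between_prob) {
    stop_validation("ppi_within_prob must be >= ppi_between_prob")
  }
  structure(list(n = n, p = p, dims = dims, n_modules = dims[1],
                 module_size = module_size, snr = snr,
                 ppi_within_prob = ppi_within_prob,
                 ppi_between_prob = ppi_between_prob,
                 logit_amplitude = logit_amplitude, seed = seed),
            class = "synthetic_spec")
}

# Fit the sigmoid hierarchy to a target first layer by the same adaptive
# descent used for data fitting, so the planted model is exactly the model
# class the fitter assumes (structure imposed on the derived layer, not
# painted on afterwards).
plant_chain <- function(target, dims, iters = 400, lr = 5e-2) {
  # initialize the chain from the targets themselves
  k0 <- dims[1]
  N <- length(dims) - 1
  Z <- vector("list", length(target))
  Hdeep <- vector("list", length(target))
  for (i in seq_along(target)) {
    Hcur <- pmin(pmax(target[[i]], 1e-4), 1 - 1e-4)
    Zi <- vector("list", N)
    for (m in seq_len(N)) {
      Tm <- logit(Hcur)
      r <- dims[m + 1]
      svt <- fix_svd_signs(svd(Tm, nu = r, nv = r))
      B <- diag(svt$d[seq_len(r)], r) %*% t(svt$v[, seq_len(r), drop = FALSE])
      if (m == N) {
        Zi[[m]] <- svt$u[, seq_len(r), drop = FALSE]
        Hdeep[[i]] <- B
      } else {
        Hnext <- squash_unit(B)
        Zi[[m]] <- ls_right_solve(Tm, Hnext)
        Hcur <- Hnext
      }
    }
    Z[[i]] <- Zi
  }
  model <- deep_factor_model(
    U = matrix(0, 1, k0), Z = Z, Hdeep = Hdeep, dims = dims,
    omics_names = paste0("om", seq_along(target)),
    feature_ids = lapply(target, function(t) paste0("f", seq_len(ncol(t)))),
    sample_ids = "s1")

  # refine: minimize sum_i ||H0_i - target_i||_F^2 over Z, Hdeep
  params <- c(unlist(model$Z, recursive = FALSE), model$Hdeep)
  m1 <- lapply(params, function(p) p * 0); m2 <- m1
  b1 <- 0.9; b2 <- 0.999
  chain_obj_grad <- function(mod) {
    tot <- 0
    gZ <- vector("list", length(target)); gH <- vector("list", length(target))
    for (i in seq_along(target)) {
      fw <- forward(mod, i)
      D0 <- fw$H0 - target[[i]]
      tot <- tot + sum(D0 * D0)
      G <- 2 * D0
      Zs <- mod$Z[[i]]
      gZi <- vector("list", length(Zs))
      for (m in seq_along(Zs)) {
        Hm1 <- fw$layers[[m]]
        Dm <- G * Hm1 * (1 - Hm1)
        gZi[[m]] <- Dm %*% t(fw$layers[[m + 1]])
        G <- crossprod(Zs[[m]], Dm)
      }
      gZ[[i]] <- gZi
      gH[[i]] <- G
    }
    list(total = tot, grads = c(unlist(gZ, recursive = FALSE), gH))
  }
  inject <- function(mod, pars) {
    idx <- 0
    for (i in seq_along(target)) {
      for (m in seq_len(N)) {
        idx <- idx + 1
        mod$Z[[i]][[m]] <- pars[[idx]]
      }
    }
    mod$Hdeep <- pars[idx + seq_along(target)]
    mod
  }
  cur <- chain_obj_grad(model)
  for (it in seq_len(iters)) {
    g <- cur$grads
    m1 <- Map(function(m, gr) b1 * m + (1 - b1) * gr, m1, g)
    m2 <- Map(function(v, gr) b2 * v + (1 - b2) * gr * gr, m2, g)
    dir <- Map(function(m, v) (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + 1e-8),
               m1, m2)
    params <- Map(function(p, d) p - lr * d, params, dir)
    model <- inject(model, params)
    cur <- chain_obj_grad(model)
  }
  model
}

#' Generate a planted synthetic multi-omics instance
#'
#' Draws a planted deep factor model whose derived first-layer rows are
#' elevated on their module's member features and near-baseline elsewhere,
#' a standard-normal sample-latent matrix, data
#' `X_i = U %*% H_i^0 + noise` with noise variance set by `snr`, and a
#' blockwise-Bernoulli interaction prior over the first omics' features.
#'
#' @param spec A [synthetic_spec] (or arguments forwarded to it via `...`).
#' @param ... Used to build a spec when `spec` is missing.
#' @return List with `X` (three [omics_matrix], named mRNA/lncRNA/miRNA),
#'   `P` (the [prior_network] on the first omics), and `truth`: the planted
#'   `module_set`, the planted `model`, its `U` and derived `H0`, and the
#'   membership index list.
#' @export
generate_synthetic <- function(spec = synthetic_spec(...), ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k0 <- spec$n_modules
  omics_names <- c("mRNA", "lncRNA", "miRNA")
  feature_ids <- lapply(seq_len(3), function(i) {
    sprintf("%s_f%03d", omics_names[i], seq_len(spec$p[i]))
  })

  # planted membership: disjoint when capacity allows, overlapping otherwise
  membership <- lapply(seq_len(3), function(i) {
    p_i <- spec$p[i]; s_i <- spec$module_size[i]
    if (k0 * s_i <= p_i) {
      perm <- sample.int(p_i)
      lapply(seq_len(k0), function(r) sort(perm[(r - 1) * s_i + seq_len(s_i)]))
    } else {
      lapply(seq_len(k0), function(r) sort(sample.int(p_i, s_i)))
    }
  })

  a <- spec$logit_amplitude
  target <- lapply(seq_len(3), function(i) {
    Tm <- matrix(-a, k0, spec$p[i])
    for (r in seq_len(k0)) Tm[r, membership[[i]][[r]]] <- a
    sigmoid(Tm + matrix(stats::rnorm(length(Tm), sd = 0.3), k0))
  })

  model <- plant_chain(target, spec$dims)
  model$omics_names <- omics_names
  model$feature_ids <- feature_ids
  U <- matrix(stats::rnorm(spec$n * k0), spec$n, k0)
  model$U <- U
  sample_ids <- sprintf("sample_%03d", seq_len(spec$n))
  model$sample_ids <- sample_ids

  H0 <- model_H0(model)
  X <- lapply(seq_len(3), function(i) {
    S <- U %*% H0[[i]]
    noise_sd <- sqrt(stats::var(as.vector(S)) / spec$snr)
    omics_matrix(S + matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S)),
                 sample_ids = sample_ids, feature_ids = feature_ids[[i]],
                 omics_name = omics_names[i])
  })

  # module-consistent interaction prior on the first omics
  p1 <- spec$p[1]
  block <- integer(p1)                       # 0 = background
  for (r in seq_len(k0)) block[membership[[1]][[r]]] <- r
  A <- matrix(0, p1, p1)
  up <- which(upper.tri(A), arr.ind = TRUE)
  same <- block[up[, 1]] != 0 & block[up[, 1]] == block[up[, 2]]
  prob <- ifelse(same, spec$ppi_within_prob, spec$ppi_between_prob)
  edge <- stats::rbinom(nrow(up), 1, prob)
  A[up] <- edge
  A <- A + t(A)
  P <- prior_network(A, feature_ids[[1]])

  truth_modules <- lapply(seq_len(k0), function(r) {
    members <- lapply(seq_len(3), function(i) {
      data.frame(feature = feature_ids[[i]][membership[[i]][[r]]],
                 z = NA_real_)
    })
    names(members) <- omics_names
    list(factor_index = r, members = members, correlation = NA_real_)
  })
  truth <- list(
    modules = structure(list(modules = truth_modules, k0 = k0,
                             threshold = NA_real_, two_sided = FALSE,
                             omics_names = omics_names),
                        class = "module_set"),
    model = model, U = U, H0 = H0, membership = membership)
  list(X = X, P = P, truth = truth, spec = spec)
}

# pooled member-set of one module as "omics||feature" keys
module_key_set <- function(mod) {
  unlist(lapply(names(mod$members), function(om) {
    paste0(om, "||", mod$members[[om]]$feature)
  }), use.names = FALSE)
}

#' Score module recovery against planted truth
#'
#' Matches recovered modules one-to-one to planted modules by maximizing the
#' summed F1 of their pooled member sets (Hungarian assignment on the padded
#' square F1 matrix) and reports the mean matched F1.
#'
#' @param recovered A `module_set` from [extract_modules()].
#' @param truth The planted `module_set` (e.g. from [generate_synthetic()]).
#' @return List with `mean_best_f1` and `per_module`, a `data.frame` with
#'   `recovered`, `planted` and `f1` for every matched pair.
#' @export
score_recovery <- function(recovered, truth) {
  R <- lapply(recovered$modules, module_key_set)
  T_ <- lapply(truth$modules, module_key_set)
  nr <- length(R); nt <- length(T_)
  n <- max(nr, nt)
  F1 <- matrix(0, n, n)
  for (i in seq_len(nr)) {
    for (j in seq_len(nt)) {
      inter <- length(intersect(R[[i]], T_[[j]]))
      denom <- length(R[[i]]) + length(T_[[j]])
      F1[i, j] <- if (denom == 0) 0 else 2 * inter / denom
    }
  }
  assign <- solve_assignment(-F1)   # maximize total F1
  matched <- data.frame(recovered = seq_len(n), planted = assign,
                        f1 = F1[cbind(seq_len(n), assign)])
  matched <- matched[matched$recovered <= nr & matched$planted <= nt, ]
  list(mean_best_f1 = mean(matched$f1), per_module = matched)
}
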