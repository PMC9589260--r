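# a minimal one-omics model whose H0 equals a prescribed matrix, for
# direct control of the z-score inputs (logit of the target, single layer)
model_with_H0 <- function(H0, omics_name = "mRNA") {
  k0 <- nrow(H0)
  H0 <- pmin(pmax(H0, 1e-12), 1 - 1e-12)
  deep_factor_model(
    U = diag(k0), Z = list(list(diag(k0))), Hdeep = list(logit(H0)),
    dims = c(k0, k0), omics_names = omics_name,
    feature_ids = list(sprintf("f%03d", seq_len(ncol(H0)))),
    sample_ids = sprintf("s%d", seq_len(k0)))
}
logit <- function(p) log(p) - log1p(-p)

test_that("z-score membership isolates a single dominant feature", {
  h <- c(0.9, rep(0.1, 100))               # p = 101, one elevated feature
  model <- model_with_H0(matrix(rep(h, 2), 2, byrow = TRUE))
  ms <- extract_modules(model, zscore_threshold = 1.96)
  expect_equal(length(ms$modules), 2)
  for (mod in ms$modules) {
    expect_equal(mod$members[[1]]$feature, "f001")
    expect_gt(mod$members[[1]]$z, 9.5)     # z approx 9.95
  }
  # independent z computation
  z1 <- (h[1] - mean(h)) / sd(h)
  expect_equal(ms$modules[[1]]$members[[1]]$z, z1)
})

test_that("constant factor rows contribute no members", {
  H0 <- rbind(rep(0.4, 10), c(0.9, rep(0.1, 9)))
  model <- model_with_H0(H0)
  ms <- suppressMessages(extract_modules(model, 1.96))
  expect_equal(nrow(ms$modules[[1]]$members[[1]]), 0)
  expect_equal(ms$modules[[2]]$members[[1]]$feature, "f001")
})

test_that("module count always equals the factor count k0", {
  inst <- small_instance(seed = 21)
  fit <- fit_pdjdsnmf(inst$X, c(3, 2), seed = 0, max_iter = 30)
  ms <- extract_modules(fit, 0.5)
  expect_equal(length(ms$modules), 3)
  expect_equal(ms$k0, 3)
})

test_that("raising the threshold never adds members; two-sided is a superset", {
  set.seed(22)
  H0 <- matrix(runif(5 * 40), 5, 40)
  model <- model_with_H0(H0)
  lo <- extract_modules(model, 0.5)
  hi <- extract_modules(model, 1.5)
  two <- extract_modules(model, 1.5, two_sided = TRUE)
  for (r in 1:5) {
    mem_lo <- lo$modules[[r]]$members[[1]]$feature
    mem_hi <- hi$modules[[r]]$members[[1]]$feature
    mem_two <- two$modules[[r]]$members[[1]]$feature
    expect_true(all(mem_hi %in% mem_lo))
    expect_true(all(mem_hi %in% mem_two))
  }
})

test_that("membership is invariant under feature permutation", {
  set.seed(23)
  sim <- generate_synthetic(synthetic_spec(n = 20, p = c(30, 15, 8),
                                           dims = c(4, 3, 2),
                                           module_size = c(5, 3, 2), seed = 3))
  fit <- fit_pdjdsnmf(sim$X, c(4, 3, 2), seed = 0, max_iter = 60, scale = FALSE)
  ms <- extract_modules(fit, 1.0)
  perm <- sample(30)
  model_p <- fit$model
  model_p$feature_ids[[1]] <- model_p$feature_ids[[1]][perm]
  # permute the mRNA chain's deepest columns so H0 permutes identically
  model_p$Hdeep[[1]] <- model_p$Hdeep[[1]][, perm]
  ms_p <- extract_modules(model_p, 1.0)
  for (r in seq_len(ms$k0)) {
    expect_setequal(ms_p$modules[[r]]$members[[1]]$feature,
                    ms$modules[[r]]$members[[1]]$feature)
  }
})

test_that("module correlation is exact on identities and hand cases", {
  inst <- small_instance(seed = 25)
  fit <- fit_pdjdsnmf(inst$X, c(3, 2), seed = 0, max_iter = 40, scale = FALSE)
  ms <- extract_modules(fit, 0.1)
  mod <- ms$modules[[1]]

  # replace the data by the exact reconstruction: correlation 1 on any module
  Xhat <- lapply(1:3, function(i) {
    omics_matrix(forward(fit$model, i)$Xhat,
                 sample_ids = inst$X[[i]]$sample_ids,
                 feature_ids = inst$X[[i]]$feature_ids,
                 omics_name = inst$X[[i]]$omics_name)
  })
  expect_equal(module_correlation(mod, fit$model, Xhat), 1.0)

  # single-feature module, data = reconstruction + constant: shift-invariant
  one <- mod
  one$members <- lapply(one$members, function(df) df[0, , drop = FALSE])
  one$members[[1]] <- data.frame(feature = inst$X[[1]]$feature_ids[1], z = 3)
  Xshift <- Xhat
  Xshift[[1]]$values <- Xshift[[1]]$values + 5
  expect_equal(module_correlation(one, fit$model, Xshift), 1.0)

  # two-feature toy against the textbook formula
  a <- as.vector(Xhat[[1]]$values[, 1:2])
  set.seed(1)
  Xn <- Xhat
  Xn[[1]]$values[, 1:2] <- Xn[[1]]$values[, 1:2] + rnorm(length(a))
  two <- one
  two$members[[1]] <- data.frame(feature = inst$X[[1]]$feature_ids[1:2],
                                 z = c(2, 2))
  b <- as.vector(Xn[[1]]$values[, 1:2])
  r_hand <- sum((b - mean(b)) * (a - mean(a))) /
    sqrt(sum((b - mean(b))^2) * sum((a - mean(a))^2))
  expect_equal(module_correlation(two, fit$model, Xn), r_hand)

  # empty module flagged as missing
  empty <- mod
  empty$members <- lapply(empty$members, function(df) df[0, , drop = FALSE])
  expect_true(is.na(module_correlation(empty, fit$model, Xhat)))
})

test_that("module summary tabulates counts, means and ranking", {
  mk_mod <- function(r, counts, corr) {
    members <- lapply(seq_along(counts), function(i) {
      data.frame(feature = sprintf("om%d_f%d", i, seq_len(counts[i])),
                 z = rep(2, counts[i]))
    })
    names(members) <- c("miRNA", "mRNA", "lncRNA")
    list(factor_index = r, members = members, correlation = corr)
  }
  ms <- structure(list(modules = list(mk_mod(1, c(1, 2, 3), 0.4),
                                      mk_mod(2, c(3, 2, 1), 0.9)),
                       k0 = 2, threshold = 1.96, two_sided = FALSE,
                       omics_names = c("miRNA", "mRNA", "lncRNA")),
                  class = "module_set")
  tab <- module_summary(ms)
  expect_equal(attr(tab, "mean_members"),
               c(miRNA = 2, mRNA = 2, lncRNA = 2))
  expect_equal(tab$rank, c(2, 1))
  expect_equal(tab$n_miRNA, c(1, 3))

  empty <- structure(list(modules = list(), k0 = 0, threshold = 1.96,
                          two_sided = FALSE, omics_names = c("a", "b", "c")),
                     class = "module_set")
  expect_equal(nrow(module_summary(empty)), 0)
})

test_that("module sets survive a JSON round trip", {
  sim <- generate_synthetic(synthetic_spec(n = 20, p = c(30, 15, 8),
                                           dims = c(4, 3, 2),
                                           module_size = c(5, 3, 2), seed = 5))
  fit <- fit_pdjdsnmf(sim$X, c(4, 3, 2), seed = 0, max_iter = 40, scale = FALSE)
  ms <- score_modules(extract_modules(fit, 1.5), fit, sim$X)
  path <- tempfile(fileext = ".json")
  write_module_set(ms, json_path = path)
  back <- read_module_set(path)
  expect_equal(back$k0, ms$k0)
  for (r in seq_len(ms$k0)) {
    expect_equal(back$modules[[r]]$members[["mRNA"]]$feature,
                 ms$modules[[r]]$members[["mRNA"]]$feature)
    expect_equal(back$modules[[r]]$correlation, ms$modules[[r]]$correlation)
  }
})
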