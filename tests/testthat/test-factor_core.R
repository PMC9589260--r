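test_that("sigmoid is exact at 0, symmetric, and overflow-safe", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(-5, -1, 2, 50)) {
    expect_equal(sigmoid(x) + sigmoid(-x), 1)
  }
  expect_true(sigmoid(710) >= 1 - 1e-300 && sigmoid(710) <= 1)
  expect_true(sigmoid(-710) >= 0 && sigmoid(-710) < 1e-300)
  m <- sigmoid(matrix(c(-1000, 0, 1000, 2), 2))
  expect_true(all(is.finite(m)))
})

test_that("forward pass matches an independent nested evaluation", {
  # zero junction matrix: every derived entry is s(0) = 0.5
  U <- matrix(rnorm(8), 4, 2)
  m0 <- deep_factor_model(U = U, Z = list(list(matrix(0, 2, 2))),
                          Hdeep = list(matrix(rnorm(6), 2, 3)),
                          dims = c(2, 2), omics_names = "m",
                          feature_ids = list(letters[1:3]),
                          sample_ids = sprintf("s%d", 1:4))
  fw <- forward(m0, 1)
  expect_true(all(fw$H0 == 0.5))
  expect_equal(fw$Xhat, 0.5 * U %*% matrix(1, 2, 3))

  # two sublayers, all-ones parameters, hand-rolled loop oracle
  Z1 <- matrix(1, 2, 2); Z2 <- matrix(1, 2, 1); Hd <- matrix(1, 1, 1)
  m2 <- deep_factor_model(U = matrix(1, 3, 2), Z = list(list(Z1, Z2)),
                          Hdeep = list(Hd), dims = c(2, 2, 1),
                          omics_names = "m", feature_ids = list("f"),
                          sample_ids = c("a", "b", "c"))
  manual <- 1 / (1 + exp(-(Z1 %*% (1 / (1 + exp(-(Z2 %*% Hd)))))))
  expect_equal(forward(m2, 1)$H0, manual)

  # sigmoid range invariant
  set.seed(3)
  inst <- small_instance()
  model <- svd_init(inst$X, c(3, 2), seed = 0)
  H0 <- forward(model, 1)$H0
  expect_true(min(H0) > 0 && max(H0) < 1)

  expect_error(forward(deep_factor_model(
    U = matrix(0, 2, 2), Z = list(list(matrix(0, 3, 2))),
    Hdeep = list(matrix(0, 3, 2)), dims = c(3, 2), omics_names = "m",
    feature_ids = list(c("a", "b")), sample_ids = c("x", "y")), 1),
    "layer 1")
})

test_that("objective reduces to the pure residual when all penalties vanish", {
  inst <- small_instance()
  model <- svd_init(inst$X, c(3, 2), seed = 0)
  ob <- objective(model, inst$X, inst$P, inst$graphs)
  resid <- sum(vapply(1:3, function(i) {
    sum((inst$X[[i]]$values - forward(model, i)$Xhat)^2)
  }, 0))
  expect_equal(ob$total, resid)
  expect_equal(unname(ob$terms["residual"]), resid)
})

test_that("Laplacian and prior terms vanish on feature-constant rows", {
  inst <- small_instance()
  model <- svd_init(inst$X, c(3, 2), seed = 0)
  # force H0 rows constant across features: zero junctions, any Hdeep
  model$Z <- lapply(model$Z, function(Zi) lapply(Zi, function(z) z * 0))
  model$Hdeep <- lapply(model$Hdeep, function(h) h * 0)
  ob <- objective(model, inst$X, inst$P, inst$graphs,
                  lambda2 = 1, lambda3 = 1, ppi_mode = "laplacian")
  expect_equal(unname(ob$terms["ppi"]), 0)
  expect_equal(unname(ob$terms["laplacian"]), 0)
})

test_that("objective trace terms match the brute-force pairwise oracle", {
  inst <- small_instance(seed = 2)
  model <- svd_init(inst$X, c(2, 2), seed = 0)
  ob <- objective(model, inst$X, inst$P, inst$graphs,
                  lambda1 = 0.3, lambda2 = 0.5, lambda3 = 0.7)
  lap_brute <- sum(vapply(1:3, function(i) {
    brute_laplacian_penalty(forward(model, i)$H0, inst$graphs[[i]]$connectivity)
  }, 0))
  ppi_brute <- brute_laplacian_penalty(forward(model, 1)$H0, inst$P$adjacency)
  expect_equal(unname(ob$terms["laplacian"]), lap_brute, tolerance = 1e-10)
  expect_equal(unname(ob$terms["ppi"]), ppi_brute, tolerance = 1e-10)
  norm_brute <- sum(model$U^2) +
    sum(vapply(1:3, function(i) {
      sum(vapply(model$Z[[i]], function(z) sum(z^2), 0)) + sum(model$Hdeep[[i]]^2)
    }, 0))
  expect_equal(unname(ob$terms["norm"]), norm_brute)
  expect_equal(ob$total,
               unname(ob$terms["residual"] + 0.3 * ob$terms["norm"] +
                        0.5 * ob$terms["ppi"] + 0.7 * ob$terms["laplacian"]))
})

test_that("analytic gradients match central finite differences", {
  inst <- small_instance(seed = 4)
  model <- svd_init(inst$X, c(3, 2), seed = 1)
  lam <- c(0.05, 0.07, 0.09)
  og <- pdjdsnmf:::obj_and_grad(model, inst$X, inst$P, inst$graphs,
                                lam[1], lam[2], lam[3], "laplacian", NULL)
  eval_obj <- function(m) {
    pdjdsnmf:::obj_and_grad(m, inst$X, inst$P, inst$graphs, lam[1], lam[2],
                            lam[3], "laplacian", NULL, want_grad = FALSE)$total
  }
  h <- 1e-6
  check_entries <- function(get, set, gmat) {
    set.seed(99)
    for (idx in sample(length(gmat), min(5, length(gmat)))) {
      bump <- function(sign) {
        m2 <- model
        v <- get(m2)
        v[idx] <- v[idx] + sign * h
        eval_obj(set(m2, v))
      }
      num <- (bump(1) - bump(-1)) / (2 * h)
      expect_equal(gmat[idx], num,
                   tolerance = 1e-4 * max(abs(num), 1))
    }
  }
  check_entries(function(m) m$U, function(m, v) { m$U <- v; m }, og$grad$U)
  for (i in 1:3) {
    for (l in seq_along(model$Z[[i]])) {
      check_entries(function(m) m$Z[[i]][[l]],
                    function(m, v) { m$Z[[i]][[l]] <- v; m },
                    og$grad$Z[[i]][[l]])
    }
    check_entries(function(m) m$Hdeep[[i]],
                  function(m, v) { m$Hdeep[[i]] <- v; m },
                  og$grad$Hdeep[[i]])
  }
})

test_that("svd_init is deterministic and validates rank bounds", {
  inst <- small_instance(seed = 6)
  a <- svd_init(inst$X, c(3, 2), seed = 5)
  b <- svd_init(inst$X, c(3, 2), seed = 5)
  expect_identical(a, b)
  expect_error(svd_init(inst$X, c(7, 2), seed = 0), "k0")
  expect_error(fit_pdjdsnmf(inst$X, c(4, 2), seed = 0), "k0")  # p_mirna = 3 < 4
})

test_that("initialization alone reconstructs noiseless planted data well", {
  sim <- generate_synthetic(synthetic_spec(
    n = 40, p = c(60, 40, 20), dims = c(8, 6, 4), module_size = c(6, 4, 2),
    snr = 1e12, seed = 0))
  model <- svd_init(sim$X, c(8, 6, 4), seed = 0)
  rc <- vapply(1:3, function(i) {
    reconstruction_correlation(sim$X[[i]], forward(model, i)$Xhat)
  }, 0)
  expect_gte(mean(rc), 0.9)
})

test_that("reconstruction_correlation matches the textbook formula", {
  X <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(reconstruction_correlation(X, X), 1.0)
  Xc <- scale(matrix(rnorm(20), 5), scale = FALSE)
  expect_equal(reconstruction_correlation(Xc, -Xc), -1.0)
  Xhat <- matrix(c(1, 3, 2, 5), 2)
  a <- as.vector(X); b <- as.vector(Xhat)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(reconstruction_correlation(X, Xhat), r_hand)
  expect_error(reconstruction_correlation(matrix(1, 2, 2), X), "variance")
})

test_that("fitting keeps every derived layer strictly inside (0,1)", {
  inst <- small_instance(seed = 8)
  fit <- fit_pdjdsnmf(inst$X, c(3, 2), P = inst$P, graphs = inst$graphs,
                      seed = 0, max_iter = 50, scale = FALSE)
  for (i in 1:3) {
    layers <- forward(fit$model, i)$layers
    for (H in layers[seq_len(length(layers) - 1)]) {  # derived layers only
      expect_true(min(H) > 0 && max(H) < 1)
    }
  }
})

test_that("fits are bit-reproducible for identical seeds and inputs", {
  inst <- small_instance(seed = 10)
  f1 <- fit_pdjdsnmf(inst$X, c(3, 2), P = inst$P, graphs = inst$graphs,
                     seed = 3, max_iter = 40)
  f2 <- fit_pdjdsnmf(inst$X, c(3, 2), P = inst$P, graphs = inst$graphs,
                     seed = 3, max_iter = 40)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("a strong Laplacian penalty shrinks the Laplacian term", {
  inst <- small_instance(seed = 12, n = 10, p = c(8, 6, 5))
  dense <- lapply(inst$X, function(x) {
    p <- ncol(x$values)
    laplacian_from_adjacency(matrix(1, p, p) - diag(p), x$feature_ids)
  })
  f0 <- fit_pdjdsnmf(inst$X, c(3, 2), graphs = dense, lambda1 = 1e-4,
                     lambda2 = 0, lambda3 = 0, seed = 0, max_iter = 300,
                     scale = FALSE)
  f1 <- fit_pdjdsnmf(inst$X, c(3, 2), graphs = dense, lambda1 = 1e-4,
                     lambda2 = 0, lambda3 = 1e3, seed = 0, max_iter = 300,
                     scale = FALSE)
  lap0 <- unname(f0$term_trace[nrow(f0$term_trace), "laplacian"])
  lap1 <- unname(f1$term_trace[nrow(f1$term_trace), "laplacian"])
  expect_lt(lap1, lap0)
})

test_that("divergent configurations raise a numeric error, not NaN results", {
  inst <- small_instance(seed = 14)
  Xhuge <- lapply(inst$X, function(x) { x$values <- x$values * 1e200; x })
  expect_error(fit_pdjdsnmf(Xhuge, c(3, 2), seed = 0, scale = FALSE),
               class = "pdjdsnmf_numeric_error")
})
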