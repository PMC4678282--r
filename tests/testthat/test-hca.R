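test_that("design blocks carry the sex indicators and stacked quadratic forms", {
  members <- data.frame(family_id = "f1",
                        individual_id = c("p", "q", "r"),
                        father_id = NA, mother_id = NA,
                        sex = c(1L, 2L, 1L))
  ped <- pedigree(members)
  X <- matrix(c(0.3, -1.2, 0.9), 3, 1, dimnames = list(NULL, "F1"))
  hb <- hca_blocks(X, ped, standardize = FALSE)
  # male indicator row (-1, 0, -1), female (0, -1, 0)
  expect_equal(unname(hb$K[3, ]), c(-1, 0, -1))
  expect_equal(unname(hb$K[4, ]), c(0, -1, 0))
  expect_equal(unname(hb$K[1, ]), drop(X))
  expect_equal(unname(hb$K[2, ]), -drop(X))
})

test_that("singleton-only samples give A = 2 K K^T", {
  ds <- small_dataset(seed = 10, n_total = 60, n_in_families = 0, d_total = 3)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  expect_equal(hb$A, 2 * tcrossprod(hb$K), tolerance = 1e-10)
})

test_that("A and B match a dense assembly oracle on a mixed sample", {
  ds <- small_dataset(seed = 11, n_total = 80, n_in_families = 40,
                      d_total = 2)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  # dense oracle on the split design K
  n <- hb$n
  phi_inv_full <- matrix(0, n, n)
  for (b in ds$blocks) phi_inv_full[b$rows, b$rows] <- solve(b$phi)
  expect_equal(hb$A, hb$K %*% phi_inv_full %*% t(hb$K), tolerance = 1e-9)
  expect_equal(hb$B, tcrossprod(hb$K), tolerance = 1e-12)
})

test_that("objective is the quadratic form plus a linear penalty", {
  ds <- small_dataset(seed = 12, n_total = 100, n_in_families = 40,
                      d_total = 2)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  expect_identical(hca_objective(rep(0, 6), hb, 3), 0)
  gamma <- withr::with_seed(1, c(runif(4), rnorm(2)))
  f1 <- hca_objective(gamma, hb, 1)
  f2 <- hca_objective(gamma, hb, 2)
  expect_equal(f2 - f1, sum(gamma[1:4]), tolerance = 1e-10)
})

test_that("split encoding is equivalent to the direct parameterization", {
  ds <- small_dataset(seed = 13, n_total = 90, n_in_families = 45,
                      d_total = 3)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  Q <- dense_quadform_oracle(hb$M, hb$sex, ds$blocks)
  withr::with_seed(2, for (i in 1:5) {
    u <- runif(3); v <- runif(3); mu <- rnorm(2)
    gamma <- c(u, v, mu)
    beta <- c(u - v, mu)
    expect_equal(hca_objective(gamma, hb, 0),
                 drop(t(beta) %*% Q %*% beta), tolerance = 1e-8)
  })
})

test_that("with one feature the solver standardizes it", {
  ds <- small_dataset(seed = 14, n_total = 120, n_in_families = 60,
                      d_total = 1, d_relevant = 1)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  m <- hca_fit(hb, lambda = 0)
  y <- derive_trait(m, ds$X, sex = ds$sex)
  n <- length(y)
  expect_equal(sum(y^2) / n, 1, tolerance = 1e-8)
  # only one direction exists: weight is the reciprocal sex-centered sd
  xs <- drop(scale(ds$X))
  resid <- residualize(xs, data.frame(male = ds$sex == 1L))
  expect_equal(unname(m$weights[1]), 1 / sqrt(mean(resid^2)),
               tolerance = 1e-3)
})

test_that("the interior-point QP matches exhaustive active-set enumeration", {
  withr::with_seed(15, {
    for (i in 1:10) {
      m <- 6  # d = 2: 4 bound constraints, 3 equalities
      L <- matrix(rnorm(m * m), m)
      W <- crossprod(L) + diag(m) * 0.5
      g <- rnorm(m)
      E <- matrix(rnorm(3 * m), 3)
      b <- rnorm(3) * 0.3
      l <- -runif(4)
      J <- 1:4
      got <- hericomp:::solve_qp(W, g, E, b, l, J)
      want <- qp_enumeration_oracle(W, g, E, b, l, J)
      expect_false(is.null(want))
      val_got <- 0.5 * drop(t(got$p) %*% W %*% got$p) + sum(g * got$p)
      expect_equal(val_got, want$value, tolerance = 1e-6)
      expect_equal(got$p, want$p, tolerance = 1e-4)
    }
  })
})

test_that("at a KKT point the QP returns a negligible step", {
  ds <- small_dataset(seed = 16, n_total = 150, n_in_families = 60,
                      d_total = 2)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  m <- hca_fit(hb, lambda = 2)
  expect_true(m$converged)
  sub <- hericomp:::qp_subproblem(m$gamma, m$alpha, hb, 2)
  expect_lt(max(abs(sub$p)), 1e-4)
})

test_that("solutions at d = 2 beat a 3600-point feasible grid", {
  withr::with_seed(17, {
    for (i in 1:20) {
      ds <- simulate_dataset(
        sim_scenario(n_total = 60 + 10 * (i %% 4), n_in_families = 30,
                     d_total = 2, d_relevant = 2),
        seed = 170 + i)
      hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
      lambda <- sample(c(0, 1, 4), 1)
      model <- hca_fit(hb, lambda = lambda)
      grid_best <- grid_oracle_d2(hb, lambda)
      expect_lte(model$objective, grid_best + 1e-4,
                 label = sprintf("instance %d (lambda %g)", i, lambda))
    }
  })
})

test_that("constraints, complementarity and merit monotonicity hold at the optimum", {
  ds <- small_dataset(seed = 18)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  for (lambda in c(0, 5, 25)) {
    m <- hca_fit(hb, lambda = lambda, keep_trace = TRUE)
    gamma <- m$gamma
    d2 <- 2 * hb$d
    expect_lt(abs(drop(crossprod(gamma, hb$B %*% gamma)) - hb$n),
              1e-6 * hb$n)
    for (b in hb$b) expect_lt(abs(sum(b * gamma)), 1e-8)
    expect_gte(min(gamma[1:d2]), -1e-10)
    u <- gamma[1:hb$d]; v <- gamma[hb$d + 1:hb$d]
    expect_lt(max(u * v), 1e-10)
    # the split-variable sum equals the l1 norm of the weights
    expect_equal(sum(gamma[1:d2]), sum(abs(m$weights)), tolerance = 1e-8)
    if (!is.null(m$trace))
      expect_true(all(m$trace[, "merit_after"] <=
                        m$trace[, "merit_before"] + 1e-8))
  }
})

test_that("fits are deterministic and equivariant under sign flips", {
  ds <- small_dataset(seed = 19)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  m1 <- hca_fit(hb, lambda = 3)
  m2 <- hca_fit(hb, lambda = 3)
  expect_identical(m1$weights, m2$weights)
  # the objective is invariant under w -> -w; the canonical representative
  # (largest-magnitude weight positive) is therefore unchanged when all
  # features are negated, and the derived trait flips sign instead
  hb_neg <- hca_blocks(-ds$X, ds$pedigree, blocks = ds$blocks)
  m3 <- hca_fit(hb_neg, lambda = 3)
  expect_equal(unname(m3$weights), unname(m1$weights), tolerance = 1e-6)
  expect_equal(derive_trait(m3, -ds$X), -derive_trait(m1, ds$X),
               tolerance = 1e-6)
})

test_that("the l1 penalty shrinks weights monotonically along the lambda path", {
  # the penalty-to-objective ratio scales as lambda/n, so shrinkage and
  # support selection are exercised on a small sample where the grid bites
  ds <- small_dataset(seed = 19, n_total = 600, n_in_families = 240)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  path <- lapply(c(0, 5, 20, 50), function(lam) hca_fit(hb, lambda = lam))
  l1 <- vapply(path, function(m) sum(abs(m$weights)), numeric(1))
  support <- vapply(path, function(m) sum(abs(m$weights) > 1e-6), numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
  expect_true(all(diff(support) <= 0))
  expect_lte(support[4], 8)  # the strongest penalty zeroes some weights
  expect_true(all(vapply(path, function(m) m$converged, logical(1))))
})

test_that("covariate correction projects the design as the regression residual", {
  ds <- small_dataset(seed = 20, n_total = 200, n_in_families = 80,
                      d_total = 4)
  X <- ds$X
  expect_identical(correct_covariates(X, NULL), X)
  Z <- data.frame(age = ds$age, race = ds$race)
  M <- correct_covariates(X, Z)
  expect_lt(max(abs(crossprod(M, cbind(1, ds$age, ds$race)))), 1e-7)
  # a design already orthogonal to Z is unchanged
  M2 <- correct_covariates(M, Z)
  expect_equal(M2, M, tolerance = 1e-9)
  expect_error(correct_covariates(X, cbind(Z, twice = 2 * Z$age)),
               "rank deficient")
})

test_that("deriving a trait is a pure projection", {
  ds <- small_dataset(seed = 22)
  hb <- hca_blocks(ds$X, ds$pedigree, blocks = ds$blocks)
  m <- hca_fit(hb, lambda = 1)
  y_tr <- derive_trait(m, ds$X)
  expect_equal(length(y_tr), nrow(ds$X))
  y_ctr <- derive_trait(m, ds$X, sex = ds$sex)
  expect_equal(sum(y_ctr^2) / length(y_ctr), 1, tolerance = 1e-6)
  # unit-weight pass-through model
  passthrough <- structure(
    list(weights = c(F1 = 1, F2 = 0, F3 = 0, F4 = 0, F5 = 0,
                     F6 = 0, F7 = 0, F8 = 0, F9 = 0, F10 = 0),
         center = rep(0, 10), scale = rep(1, 10),
         mu = c(mu_m = 0, mu_f = 0),
         feature_names = paste0("F", 1:10), d = 10),
    class = "hca_model")
  expect_equal(derive_trait(passthrough, ds$X), unname(ds$X[, 1]))
  expect_error(derive_trait(m, ds$X[, 1:3]), "mismatch")
})

test_that("covariate-corrected fits still recover the heritable direction", {
  ds <- simulate_dataset(sim_scenario(n_total = 2000, n_in_families = 800),
                         seed = 23)
  Z <- data.frame(age = ds$age, race = ds$race)
  # y2 carries strong fixed effects; features reconstruct y1
  hb <- hca_blocks(ds$X, ds$pedigree, covariates = Z, blocks = ds$blocks)
  m <- hca_fit(hb, lambda = 1)
  y <- derive_trait(m, ds$X)
  expect_gt(abs(cor(y, ds$y1)), 0.9)
})
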