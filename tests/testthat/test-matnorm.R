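test_that("matrix-normal log-density agrees with the Kronecker oracle", {
  # standard normal at the mode
  expect_equal(dmatnorm(matrix(0), matrix(0), 1, matrix(1)),
               -0.5 * log(2 * pi))
  set.seed(21)
  for (rep in 1:30) {
    J <- sample(1:3, 1); Tc <- sample(1:6, 1)
    Y <- matrix(rnorm(J * Tc), J, Tc)
    M <- matrix(rnorm(J * Tc), J, Tc)
    Sigma <- diag(rexp(J) + 0.2, J)
    A <- matrix(rnorm(Tc * Tc), Tc)
    Psi <- crossprod(A) + diag(0.3, Tc)
    lhs <- dmatnorm(Y, M, Sigma, Psi)
    rhs <- mvn_logpdf(as.vector(Y), as.vector(M), Psi %x% Sigma)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
  # non-PD Psi reports the offending eigenvalue
  expect_error(dmatnorm(matrix(0, 1, 2), matrix(0, 1, 2), 1,
                        matrix(c(1, 2, 2, 1), 2)), "eigenvalue")
})

test_that("matrix-normal density integrates to one (J=1, Tc=2)", {
  M <- matrix(c(0.3, -0.2), 1, 2)
  Psi <- ar1_cor(0.5, 2)
  g <- seq(-6, 6, length.out = 201)
  h <- g[2] - g[1]
  mass <- 0
  for (a in g) {
    mass <- mass + sum(vapply(g, function(b)
      exp(dmatnorm(matrix(c(a, b) + as.vector(M), 1, 2), M, 0.8, Psi)),
      numeric(1)))
  }
  expect_equal(mass * h^2, 1, tolerance = 1e-3)
})

test_that("covariance parameter counts reproduce the worked example", {
  expect_identical(n_cov_params(2, 5, "separable"), 18)
  expect_identical(n_cov_params(2, 5, "unstructured"), 55)
  # workflow spec at K = 1, J = 1, Tc = 1 under AR1: mean + variance + rho
  expect_identical(n_free_params(1, 1, 1, "ar1"), 3L)
  expect_identical(n_free_params(2, 2, 5, "full"),
                   as.integer(2 * 10 + 1 + 2 * 2 + 2 * 10))
  expect_identical(n_free_params(3, 2, 5, "ar1"),
                   as.integer(3 * 10 + 2 + 3 * 2 + 3))
  expect_error(n_cov_params(2, 5, "bogus"))
})

test_that("mixture log-likelihood matches brute-force evaluation", {
  m <- matmix_model(pi = c(0.4, 0.6),
                    M = list(matrix(0, 2, 3), matrix(1, 2, 3)),
                    sigma2 = matrix(c(0.5, 1, 2, 0.7), 2, 2),
                    Psi = c(0.3, -0.2))
  set.seed(4)
  Y <- array(rnorm(3 * 2 * 3), c(3, 2, 3))
  ll <- matmix_loglik(Y, m)
  brute <- sum(vapply(1:3, function(i) {
    d1 <- exp(dmatnorm(Y[i, , ], m$M[[1]], diag(m$sigma2[1, ]),
                       m$Psi[[1]]))
    d2 <- exp(dmatnorm(Y[i, , ], m$M[[2]], diag(m$sigma2[2, ]),
                       m$Psi[[2]]))
    log(0.4 * d1 + 0.6 * d2)
  }, numeric(1)))
  expect_equal(ll, brute, tolerance = 1e-10)
  # K = 1 reduces to a sum of matrix-normal log-densities
  m1 <- matmix_model(pi = 1, M = list(matrix(0, 2, 3)),
                     sigma2 = matrix(1, 1, 2), Psi = 0.5)
  expect_equal(matmix_loglik(Y, m1),
               sum(vapply(1:3, function(i)
                 dmatnorm(Y[i, , ], m1$M[[1]], diag(2), m1$Psi[[1]]),
                 numeric(1))), tolerance = 1e-10)
  # duplicating every observation doubles the log-likelihood
  Y2 <- array(Y[rep(1:3, 2), , ], c(6, 2, 3))
  expect_equal(matmix_loglik(Y2, m), 2 * ll, tolerance = 1e-10)
})

test_that("MAP assignment is the row argmax with low-index ties", {
  expect_identical(map_classify(diag(3)), 1:3)
  expect_identical(map_classify(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(9)
  tau <- matrix(rexp(40), 10)
  tau <- tau / rowSums(tau)
  expect_identical(map_classify(tau),
                   vapply(1:10, function(i) which.max(tau[i, ]), 1L))
})

test_that("entropy and criteria behave as defined", {
  # degenerate posterior: entropy 0, ICL = BIC
  m <- matmix_model(pi = 1, M = list(matrix(0, 1, 2)),
                    sigma2 = matrix(1, 1, 1), Psi = 0)
  set.seed(2)
  Y <- array(rnorm(40), c(20, 1, 2))
  f1 <- matmix(Y, 1, seed = 1)
  cr <- matmix_criteria(f1)
  expect_equal(cr$entropy, 0, tolerance = 1e-10)
  expect_equal(cr$icl, cr$bic)
  expect_equal(cr$bic, -f1$loglik / 20 + f1$nu / 40 * log(20))
  # a 3 x 2 toy posterior matches hand summation
  tau <- matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 3, 2, byrow = TRUE)
  hand <- -sum(tau * log(tau))
  expect_equal(threewayclust:::posterior_entropy(tau), hand)
  # hard posteriors give zero entropy
  expect_equal(threewayclust:::posterior_entropy(diag(3)), 0)
})

test_that("K = 1 fit is the closed-form matrix-normal fit", {
  set.seed(31)
  m <- toy_model_3()
  s <- simulate(m, nsim = 80, seed = 31)
  f <- matmix(s$Y, 1, seed = 1)
  # mean equals the sample mean matrix, posteriors are all one
  Mbar <- apply(unclass(s$Y), 2:3, mean)
  expect_equal(unname(f$M[[1]]), Mbar, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(f$tau - 1) < 1e-12))
  expect_equal(f$loglik, matmix_loglik(s$Y, f), tolerance = 1e-8)
})

test_that("posterior rows sum to 1 and traces are monotone on fits", {
  m <- toy_model_3()
  s <- simulate(m, nsim = 150, seed = 5)
  for (cs in c("full", "ar1")) {
    f <- matmix(s$Y, 2, column_structure = cs, n_starts = 2, seed = 3)
    expect_equal(rowSums(f$tau), rep(1, 150), tolerance = 1e-12)
    expect_true(min(diff(f$loglik_trace)) > -1e-8)
    expect_true(all(f$sigma2 > 0))
    for (P in f$Psi) {
      expect_equal(diag(P), rep(1, 5), tolerance = 1e-10)
      expect_true(min(eigen(P, TRUE, TRUE)$values) > 0)
      expect_equal(P, t(P))
    }
  }
})

test_that("well-separated two-component data are recovered", {
  m <- matmix_model(pi = c(0.5, 0.5),
                    M = list(matrix(-1.5, 2, 4), matrix(1.5, 2, 4)),
                    sigma2 = matrix(0.3, 2, 2), Psi = c(0.4, 0.4))
  s <- simulate(m, nsim = 400, seed = 8)
  f <- matmix(s$Y, 2, n_starts = 3, seed = 2)
  expect_gte(adjusted_rand(s$labels, f$labels), 0.95)
  # align labels by posterior agreement, then compare means
  ord <- if (mean(f$labels[s$labels == 1] == 1) > 0.5) 1:2 else 2:1
  for (k in 1:2)
    expect_lt(max(abs(f$M[[ord[k]]] - m$M[[k]])), 0.15)
})

test_that("the fitted likelihood is exchangeable over observations", {
  m <- toy_model_3()
  s <- simulate(m, nsim = 120, seed = 13)
  f <- matmix(s$Y, 3, n_starts = 2, seed = 4)
  perm <- sample(120)
  Yp <- unclass(s$Y)[perm, , ]
  expect_equal(matmix_loglik(Yp, f), matmix_loglik(s$Y, f),
               tolerance = 1e-8)
})

test_that("degenerate requests fail loudly", {
  set.seed(1)
  Y <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  expect_error(matmix(Y, 3), "smaller")
  expect_error(matmix(Y, 5), "smaller")
})

test_that("AR1 refinement recovers rho and respects nesting", {
  # independent columns: rho estimated near 0
  m0 <- matmix_model(pi = 1, M = list(matrix(0, 2, 5)),
                     sigma2 = matrix(0.5, 1, 2), Psi = 0)
  s0 <- simulate(m0, nsim = 500, seed = 17)
  f0 <- matmix(s0$Y, 1, seed = 1)
  a0 <- refit_ar1(s0$Y, f0)
  expect_lt(abs(a0$rho[1]), 0.1)
  # rho = 0.7 recovered
  m7 <- matmix_model(pi = 1, M = list(matrix(0, 2, 5)),
                     sigma2 = matrix(0.5, 1, 2), Psi = 0.7)
  s7 <- simulate(m7, nsim = 500, seed = 18)
  a7 <- refit_ar1(s7$Y, matmix(s7$Y, 1, seed = 1))
  expect_lt(abs(a7$rho[1] - 0.7), 0.1)
  # nesting: AR1 log-likelihood cannot exceed the general fit's
  expect_lte(a7$loglik, matmix(s7$Y, 1, seed = 1)$loglik + 1e-6)
  # a general fit that is already AR1 is a fixed point of the refit
  expect_equal(a7$loglik,
               refit_ar1(s7$Y, matmix(s7$Y, 1, seed = 1))$loglik,
               tolerance = 1e-6)
})

test_that("criteria are invariant to component relabelling", {
  m <- toy_model_3()
  s <- simulate(m, nsim = 200, seed = 23)
  f <- matmix(s$Y, 3, n_starts = 2, seed = 6)
  g <- f
  perm <- c(3, 1, 2)
  g$pi <- f$pi[perm]; g$M <- f$M[perm]; g$sigma2 <- f$sigma2[perm, ]
  g$Psi <- f$Psi[perm]; g$tau <- f$tau[, perm]
  expect_equal(unlist(matmix_criteria(g)), unlist(matmix_criteria(f)))
})

test_that("model selection picks one component for homogeneous data", {
  m1 <- matmix_model(pi = 1, M = list(matrix(0.3, 2, 4)),
                     sigma2 = matrix(0.4, 1, 2), Psi = 0.3)
  s <- simulate(m1, nsim = 300, seed = 19)
  sel <- suppressWarnings(
    matmix_select(s$Y, 1:3, column_structure = "ar1",
                  criterion = "ICL", seed = 7, n_starts = 2))
  expect_identical(sel$best$K, 1L)
  # overfitted K may legitimately collapse and drop out of the table,
  # but K = 1 must be present and win
  expect_true(1L %in% sel$table$K)
  # singleton k_range returns that fit
  sel1 <- matmix_select(s$Y, 2, seed = 3, n_starts = 2)
  expect_identical(sel1$best$K, 2L)
})
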