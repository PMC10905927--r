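# Finite mixtures of matrix-variate Gaussian distributions for three-way
# data: observations are J x Tc matrices (experiments x transformed time
# points), components have a free mean matrix, a component-specific
# diagonal row covariance Sigma (experiments independent, heteroscedastic)
# and a column correlation Psi that is either a general correlation matrix
# or AR1 (Psi[t,s] = rho^|t-s|). Identifiability: Psi has unit diagonal,
# the scale lives in Sigma.

#' Matrix-normal log-density
#'
#' Log-density of a J x Tc matrix under the matrix-normal distribution
#' with mean `M`, row covariance `Sigma` and column covariance `Psi`:
#' `-(J*Tc/2) log 2pi - (Tc/2) log|Sigma| - (J/2) log|Psi|
#'  - tr(Psi^-1 (Y-M)' Sigma^-1 (Y-M)) / 2`,
#' equivalently the `J*Tc`-variate normal density of `vec(Y)` with
#' covariance `Psi %x% Sigma`.
#'
#' @param Y,M numeric J x Tc matrices (observation and mean).
#' @param Sigma J x J positive-definite row covariance; a vector is taken
#'   as the diagonal.
#' @param Psi Tc x Tc symmetric positive-definite column covariance.
#' @return the log-density, a single finite number.
#' @export
dmatnorm <- function(Y, M, Sigma, Psi) {
  Y <- as.matrix(Y); M <- as.matrix(M)
  stopifnot(identical(dim(Y), dim(M)))
  J <- nrow(Y); Tc <- ncol(Y)
  if (is.vector(Sigma) && !is.matrix(Sigma)) Sigma <- diag(Sigma, J)
  Psi <- as.matrix(Psi)
  stopifnot(identical(dim(Sigma), c(J, J)), identical(dim(Psi), c(Tc, Tc)))
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Psi is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  cS <- chol(Sigma); cP <- chol(Psi)
  R <- Y - M
  # tr(Psi^-1 R' Sigma^-1 R) = || t(solve(cS)) R solve(cP) ||_F^2
  A <- backsolve(cS, R, transpose = TRUE)
  B <- t(backsolve(cP, t(A), transpose = TRUE))
  -0.5 * J * Tc * log(2 * pi) - Tc * sum(log(diag(cS))) -
    J * sum(log(diag(cP))) - 0.5 * sum(B * B)
}

#' AR1 correlation matrix
#'
#' @param rho autocorrelation in (-1, 1).
#' @param Tc dimension.
#' @return Tc x Tc matrix with entries `rho^|t-s|`.
#' @export
ar1_cor <- function(rho, Tc) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  rho^abs(outer(seq_len(Tc), seq_len(Tc), `-`))
}

#' Number of free covariance parameters of a matrix observation
#'
#' For a J x Tc matrix observation: the separable (matrix-normal) model
#' carries `J(J+1)/2 + Tc(Tc+1)/2` covariance parameters versus
#' `JTc(JTc+1)/2` for an unrestricted covariance of the vectorised
#' observation — e.g. 18 versus 55 at J = 2, Tc = 5. The workflow variant
#' counts the constrained specification actually fitted: J diagonal
#' variances plus either `Tc(Tc-1)/2` free correlations or a single AR1
#' parameter.
#'
#' @param J,Tc row and column dimensions.
#' @param type `"separable"`, `"unstructured"`, `"workflow-full"` or
#'   `"workflow-ar1"`.
#' @return integer count.
#' @export
n_cov_params <- function(J, Tc, type = c("separable", "unstructured",
                                         "workflow-full", "workflow-ar1")) {
  stopifnot(J >= 1, Tc >= 1)
  switch(match.arg(type),
    "separable" = J * (J + 1) / 2 + Tc * (Tc + 1) / 2,
    "unstructured" = J * Tc * (J * Tc + 1) / 2,
    "workflow-full" = J + Tc * (Tc - 1) / 2,
    "workflow-ar1" = J + 1)
}

#' Free-parameter count of the fitted mixture
#'
#' `K*J*Tc` means, `K - 1` component sizes, `K*J` diagonal variances and
#' per component either `Tc(Tc-1)/2` correlations or one AR1 parameter.
#'
#' @param K number of components; `J`, `Tc` the matrix dimensions.
#' @param column_structure `"full"` or `"ar1"`.
#' @return integer `nu_K`.
#' @export
n_free_params <- function(K, J, Tc, column_structure = c("full", "ar1")) {
  column_structure <- match.arg(column_structure)
  corpars <- if (column_structure == "full") Tc * (Tc - 1) / 2 else 1
  as.integer(K * J * Tc + (K - 1) + K * J + K * corpars)
}

## ---- internal EM machinery -------------------------------------------

# Y: n x J x Tc array -> n x (J*Tc) matrix of vec(Y_i) (j fastest)
vec_data <- function(Y) {
  Y <- unclass(Y)
  stopifnot(is.array(Y), length(dim(Y)) == 3L)
  d <- dim(Y)
  X <- matrix(aperm(Y, c(2L, 3L, 1L)), nrow = d[1L], byrow = TRUE)
  rownames(X) <- dimnames(Y)[[1L]]
  X
}

# per-component log-densities for all observations at once
comp_logdens <- function(X, J, Tc, mvec, sigma2, Psi) {
  cP <- chol(Psi)
  Pinv <- chol2inv(cP)
  W <- Pinv %x% diag(1 / sigma2, J)
  R <- sweep(X, 2L, mvec)
  q <- rowSums((R %*% W) * R)
  -0.5 * J * Tc * log(2 * pi) - 0.5 * Tc * sum(log(sigma2)) -
    J * sum(log(diag(cP))) - 0.5 * q
}

# expected complete-data log-likelihood terms in the covariance pair,
# given the per-row weighted scatters W_j = sum_i tau_i r_ij r_ij'
Q_cov <- function(sigma2, Psi, W, Nk, J, Tc) {
  cP <- chol(Psi)
  Pinv <- chol2inv(cP)
  tr <- sum(vapply(seq_len(J), function(j)
    sum(Pinv * W[[j]]) / sigma2[j], numeric(1)))
  -0.5 * Tc * Nk * sum(log(sigma2)) - J * Nk * sum(log(diag(cP))) -
    0.5 * tr
}

# M-step covariance updates for one component; returns sigma2, Psi, rho.
# The sigma update given Psi and (for AR1) the rho update given sigma are
# exact conditional maximisations. The unit-diagonal projection of the
# general correlation update is not, so it is guarded: the rescaled
# candidate is kept only if it improves the expected complete-data
# log-likelihood, keeping the overall EM a monotone generalized EM.
update_cov <- function(R, tau_k, J, Tc, Psi_old, column_structure,
                       var_floor = 1e-10, ridge = 1e-10) {
  Nk <- sum(tau_k)
  Pinv <- chol2inv(chol(Psi_old + diag(ridge, Tc)))
  sigma2 <- numeric(J)
  cols_of_row <- lapply(seq_len(J), function(j) seq(j, J * Tc, by = J))
  W <- vector("list", J)
  for (j in seq_len(J)) {
    Xj <- R[, cols_of_row[[j]], drop = FALSE]
    W[[j]] <- crossprod(Xj, tau_k * Xj)
    sigma2[j] <- max(sum(Pinv * W[[j]]) / (Tc * Nk), var_floor)
  }
  # weighted column scatter S = sum_i tau R_i' Sigma^-1 R_i
  S <- matrix(0, Tc, Tc)
  for (j in seq_len(J)) S <- S + W[[j]] / sigma2[j]
  if (Tc == 1L) return(list(sigma2 = sigma2, Psi = matrix(1, 1, 1), rho = 0))
  if (column_structure == "full") {
    C <- S / (J * Nk)
    dC <- pmax(diag(C), var_floor)
    Psi <- C / sqrt(outer(dC, dC))
    diag(Psi) <- 1
    # transfer the scale of C's diagonal into Sigma (geometric mean)
    sigma2_new <- pmax(sigma2 * exp(mean(log(dC))), var_floor)
    q_new <- tryCatch(Q_cov(sigma2_new, Psi, W, Nk, J, Tc),
                      error = function(e) -Inf)
    if (q_new >= Q_cov(sigma2, Psi_old, W, Nk, J, Tc))
      list(sigma2 = sigma2_new, Psi = Psi, rho = NULL)
    else
      list(sigma2 = sigma2, Psi = Psi_old, rho = NULL)
  } else {
    # expected complete-data log-likelihood in rho, profiled analytically:
    # -(J*Nk/2)(Tc-1) log(1-rho^2) - tr(Psi(rho)^-1 S)/2 with tridiagonal
    # inverse: tr = (a0 + rho^2 a1 - 2 rho a2) / (1 - rho^2)
    a0 <- sum(diag(S))
    a1 <- if (Tc > 2L) sum(diag(S)[2:(Tc - 1L)]) else 0
    a2 <- sum(S[cbind(seq_len(Tc - 1L), 2:Tc)])
    negq <- function(rho) {
      J * Nk * (Tc - 1L) / 2 * log(1 - rho^2) +
        0.5 * (a0 + rho^2 * a1 - 2 * rho * a2) / (1 - rho^2)
    }
    opt <- stats::optimize(negq, interval = c(-0.999, 0.999), tol = 1e-6)
    rho <- opt$minimum
    list(sigma2 = sigma2, Psi = ar1_cor(rho, Tc), rho = rho)
  }
}

# one EM run from an initial posterior matrix
em_run <- function(X, J, Tc, K, tau, column_structure, tol, max_iter,
                   var_floor = 1e-10) {
  n <- nrow(X)
  pi_k <- rep(1 / K, K)
  mvec <- matrix(0, K, J * Tc)
  sigma2 <- matrix(1, K, J)
  Psi <- replicate(K, diag(Tc), simplify = FALSE)
  rho <- rep(NA_real_, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Nk <- colSums(tau)
    if (any(Nk < J + Tc)) return(list(ok = FALSE, reason = "degenerate"))
    pi_k <- Nk / n
    logd <- matrix(0, n, K)
    for (k in seq_len(K)) {
      mvec[k, ] <- colSums(tau[, k] * X) / Nk[k]
      R <- sweep(X, 2L, mvec[k, ])
      up <- update_cov(R, tau[, k], J, Tc, Psi[[k]], column_structure,
                       var_floor)
      sigma2[k, ] <- up$sigma2
      Psi[[k]] <- up$Psi
      rho[k] <- up$rho %||% NA_real_
      logd[, k] <- comp_logdens(X, J, Tc, mvec[k, ], sigma2[k, ], Psi[[k]])
    }
    lp <- sweep(logd, 2L, log(pi_k), `+`)
    m <- apply(lp, 1L, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    tau <- exp(lp - lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(ok = TRUE, pi = pi_k, mvec = mvec, sigma2 = sigma2, Psi = Psi,
       rho = rho, tau = tau, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, converged = converged,
       n_iter = length(ll_trace))
}

init_tau <- function(X, K, start, rng_labels = NULL) {
  n <- nrow(X)
  if (start == 1L) {
    lab <- if (K == 1L) rep(1L, n) else
      tryCatch(stats::kmeans(X, centers = K, nstart = 5L,
                             iter.max = 50L)$cluster,
               error = function(e) sample.int(K, n, replace = TRUE))
  } else {
    lab <- sample.int(K, n, replace = TRUE)
    # guarantee every component is seeded
    miss <- setdiff(seq_len(K), unique(lab))
    if (length(miss)) lab[sample.int(n, length(miss))] <- miss
  }
  tau <- matrix(0, n, K)
  tau[cbind(seq_len(n), lab)] <- 1
  # soften so no component starts empty-weighted
  0.9 * tau + 0.1 / K
}

#' Fit a mixture of matrix-variate Gaussians by EM
#'
#' Fits a `K`-component mixture of matrix-normal distributions to `n`
#' observations that are J x Tc matrices (for the RNA-seq workflow: per
#' gene, experiments in rows, post-transform time points in columns).
#' Components have free mean matrices, diagonal heteroscedastic row
#' covariances and either a general correlation matrix over columns
#' (`column_structure = "full"`) or an AR1 correlation
#' (`column_structure = "ar1"`). The E step computes posterior component
#' probabilities; the M step updates sizes and means in closed form and
#' the two covariance factors by one flip-flop sweep (AR1: a bounded
#' one-dimensional search for rho). The best of `n_starts` runs by final
#' log-likelihood is returned; the first start is initialised by k-means
#' on the vectorised data, the others from random hard assignments.
#'
#' @param Y an `alr_tensor` or any n x J x Tc numeric array.
#' @param K number of components (`K < n`).
#' @param column_structure `"full"` or `"ar1"` time correlation.
#' @param n_starts number of EM starts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter iteration cap per start.
#' @param seed integer seed making the fit reproducible.
#' @param init optional `matmix` fit or posterior matrix used as the single
#'   initialisation (then `n_starts` is ignored).
#' @return an object of class `matmix`; see [summary.matmix()]. Holds the
#'   estimates (`pi`, `M`, `sigma2`, `Psi`, `rho`), posteriors `tau`, MAP
#'   `labels`, the log-likelihood trace, and `nu` (free parameters).
#' @seealso [matmix_select()] for choosing `K`, [dbsi()] and
#'   [cluster_map_data()] for diagnostics.
#' @export
matmix <- function(Y, K, column_structure = c("full", "ar1"),
                   n_starts = 10L, tol = 1e-8, max_iter = 500L,
                   seed = NULL, init = NULL) {
  column_structure <- match.arg(column_structure)
  Y <- as_array3(Y)
  d <- dim(Y)
  n <- d[1L]; J <- d[2L]; Tc <- d[3L]
  if (K >= n) stop("K must be smaller than the number of observations")
  stopifnot(K >= 1, Tc >= 1, J >= 1)
  X <- vec_data(Y)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  if (!is.null(init)) {
    tau0 <- if (inherits(init, "matmix")) init$tau else as.matrix(init)
    stopifnot(nrow(tau0) == n, ncol(tau0) == K)
    best <- em_run(X, J, Tc, K, tau0, column_structure, tol, max_iter)
    if (!isTRUE(best$ok))
      stop("EM failed from the supplied initialisation (", best$reason, ")")
  } else {
    attempts <- 0L; max_attempts <- 2L * n_starts
    start <- 1L
    while (start <= n_starts && attempts < max_attempts) {
      attempts <- attempts + 1L
      tau0 <- init_tau(X, K, start)
      run <- em_run(X, J, Tc, K, tau0, column_structure, tol, max_iter)
      if (isTRUE(run$ok)) {
        if (is.null(best) || run$loglik > best$loglik) best <- run
        start <- start + 1L
      }
      # degenerate run: retry this start with a fresh random draw
    }
    if (is.null(best))
      stop("all EM starts collapsed to a degenerate component; ",
           "reduce K or supply an initialisation")
  }
  as_matmix(best, Y, X, column_structure, seed,
            call = match.call())
}

as_matmix <- function(run, Y, X, column_structure, seed, call) {
  d <- dim(Y); n <- d[1L]; J <- d[2L]; Tc <- d[3L]
  K <- length(run$pi)
  M <- lapply(seq_len(K), function(k) matrix(run$mvec[k, ], J, Tc,
    dimnames = dimnames(Y)[2:3]))
  labels <- map_classify(run$tau)
  names(labels) <- dimnames(Y)[[1L]]
  nu <- n_free_params(K, J, Tc, column_structure)
  structure(list(
    K = K, pi = run$pi, M = M,
    sigma2 = matrix(run$sigma2, K, J, byrow = FALSE,
                    dimnames = list(NULL, dimnames(Y)[[2L]])),
    Psi = run$Psi, rho = run$rho,
    column_structure = column_structure,
    tau = run$tau, labels = labels,
    loglik = run$loglik, loglik_trace = run$loglik_trace,
    nu = nu, converged = run$converged, n_iter = run$n_iter,
    n = n, J = J, Tc = Tc, seed = seed,
    dimnames = dimnames(Y), call = call), class = "matmix")
}

as_array3 <- function(Y) {
  if (inherits(Y, "alr_tensor")) Y <- unclass(Y)
  if (is.matrix(Y)) Y <- array(Y, c(nrow(Y), 1L, ncol(Y)),
                               dimnames = list(rownames(Y), NULL,
                                               colnames(Y)))
  stopifnot(is.array(Y), length(dim(Y)) == 3L)
  storage.mode(Y) <- "double"
  Y
}

#' Refit with the AR1 restriction from a general-correlation solution
#'
#' The general-correlation fit initialises the AR1-restricted EM: each
#' component's starting autocorrelation is the average lag-1 entry of its
#' fitted correlation matrix, and the EM is run to convergence under the
#' AR1 constraint. Since AR1 correlations are nested in general ones, the
#' refit's log-likelihood cannot exceed the maximum attainable by the full
#' model.
#'
#' @param Y the data the full model was fitted to.
#' @param full_fit a `matmix` fit with `column_structure = "full"`.
#' @param tol,max_iter EM controls, as in [matmix()].
#' @return a `matmix` fit with `column_structure = "ar1"`.
#' @export
refit_ar1 <- function(Y, full_fit, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(full_fit, "matmix"))
  if (full_fit$column_structure != "full")
    stop("'full_fit' must use the general correlation structure")
  Y <- as_array3(Y)
  X <- vec_data(Y)
  run <- em_run(X, full_fit$J, full_fit$Tc, full_fit$K, full_fit$tau,
                "ar1", tol, max_iter)
  if (!isTRUE(run$ok))
    stop("AR1 refinement collapsed to a degenerate component")
  as_matmix(run, Y, X, "ar1", full_fit$seed, call = match.call())
}

#' Total mixture log-likelihood of data under a fitted model
#'
#' @param Y n x J x Tc array of observations.
#' @param model a `matmix` object.
#' @return sum over observations of the log mixture density (log-sum-exp).
#' @export
matmix_loglik <- function(Y, model) {
  stopifnot(inherits(model, "matmix"))
  Y <- as_array3(Y)
  X <- vec_data(Y)
  lp <- posterior_logmat(X, model)
  m <- apply(lp, 1L, max)
  sum(m + log(rowSums(exp(lp - m))))
}

posterior_logmat <- function(X, model) {
  K <- model$K
  lp <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    lp[, k] <- log(model$pi[k]) +
      comp_logdens(X, model$J, model$Tc, as.vector(model$M[[k]]),
                   model$sigma2[k, ], model$Psi[[k]])
  lp
}

#' MAP classification from a posterior matrix
#'
#' Argmax per row; ties go to the lowest component index.
#'
#' @param tau n x K matrix of posterior probabilities (rows sum to 1).
#' @return integer vector of component labels.
#' @export
map_classify <- function(tau) {
  tau <- as.matrix(tau)
  as.integer(apply(tau, 1L, which.max))
}
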