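#' @export
print.matmix <- function(x, ...) {
  cat("Mixture of matrix-variate Gaussians (", x$J, " x ", x$Tc,
      " observations, ", x$column_structure, " time correlation)\n",
      sep = "")
  cat("K = ", x$K, ", n = ", x$n, ", log-likelihood = ",
      format(x$loglik, digits = 8),
      if (x$converged) " (converged)" else " (iteration cap reached)",
      "\n", sep = "")
  cat("component sizes:", paste(format(x$pi, digits = 3),
                                collapse = " "), "\n")
  invisible(x)
}

#' Summarise a fitted matrix-variate mixture
#'
#' @param object a `matmix` fit.
#' @param ... unused.
#' @return the object, invisibly, after printing component sizes, counts
#'   of MAP-assigned observations, criteria and (for AR1) the estimated
#'   autocorrelations.
#' @export
summary.matmix <- function(object, ...) {
  print(object)
  cat("MAP cluster sizes:\n")
  print(table(factor(object$labels, levels = seq_len(object$K))))
  cr <- matmix_criteria(object)
  cat(sprintf("BIC = %.6f, ICL = %.6f (per observation), nu = %d\n",
              cr$bic, cr$icl, cr$nu))
  if (object$column_structure == "ar1")
    cat("AR1 autocorrelations:",
        paste(format(object$rho, digits = 3), collapse = " "), "\n")
  invisible(object)
}

#' @export
logLik.matmix <- function(object, ...) {
  structure(object$loglik, df = object$nu, nobs = object$n,
            class = "logLik")
}

#' Extract mixture parameters
#'
#' @param object a `matmix` fit.
#' @param ... unused.
#' @return list with `pi`, `M` (list of J x Tc mean matrices), `sigma2`
#'   (K x J experiment variances), `Psi` (list of time correlation
#'   matrices) and `rho` (AR1 parameters, `NA` under the full structure).
#' @export
coef.matmix <- function(object, ...) {
  list(pi = object$pi, M = object$M, sigma2 = object$sigma2,
       Psi = object$Psi, rho = object$rho)
}

#' Posterior probabilities and MAP labels for (new) data
#'
#' @param object a `matmix` fit.
#' @param newdata n x J x Tc array; defaults to recalling the training
#'   posteriors.
#' @param type `"posterior"` for the n x K matrix of component
#'   probabilities or `"class"` for MAP labels.
#' @param ... unused.
#' @export
predict.matmix <- function(object, newdata = NULL,
                           type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    tau <- object$tau
  } else {
    X <- vec_data(as_array3(newdata))
    lp <- posterior_logmat(X, object)
    m <- apply(lp, 1L, max)
    tau <- exp(lp - (m + log(rowSums(exp(lp - m)))))
  }
  if (type == "posterior") tau else map_classify(tau)
}

#' Residual matrices against the MAP component mean
#'
#' @param object a `matmix` fit.
#' @param ... unused.
#' @return n x J x Tc array `Y_i - M_{k(i)}` where `k(i)` is the MAP
#'   component — only available when the training data are supplied via
#'   `newdata`.
#' @param newdata the n x J x Tc array the model was fitted to.
#' @export
residuals.matmix <- function(object, newdata, ...) {
  Y <- as_array3(newdata)
  stopifnot(dim(Y)[1L] == object$n)
  R <- Y
  for (i in seq_len(object$n))
    R[i, , ] <- matrix(Y[i, , ], object$J, object$Tc) -
      object$M[[object$labels[i]]]
  R
}

#' Draw observations from a fitted (or constructed) mixture
#'
#' Component labels are drawn from the sizes `pi`; given a label, the
#' observation is `M_k + A Z B` with `A = Sigma_k^{1/2}`, `B' B = Psi_k`
#' and `Z` a J x Tc standard normal matrix, so that `vec(Y)` has
#' covariance `Psi_k %x% Sigma_k`.
#'
#' @param object a `matmix` model.
#' @param nsim number of observations to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list with `Y` (nsim x J x Tc array) and `labels` (true
#'   component of each draw).
#' @export
simulate.matmix <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  J <- object$J; Tc <- object$Tc; K <- object$K
  lab <- sample.int(K, nsim, replace = TRUE, prob = object$pi)
  Y <- array(NA_real_, c(nsim, J, Tc))
  B <- lapply(object$Psi, chol)          # B' B = Psi
  A <- lapply(seq_len(K), function(k) sqrt(object$sigma2[k, ]))
  for (i in seq_len(nsim)) {
    k <- lab[i]
    Z <- matrix(stats::rnorm(J * Tc), J, Tc)
    Y[i, , ] <- object$M[[k]] + (A[[k]] * Z) %*% B[[k]]
  }
  dimnames(Y) <- c(list(NULL), object$dimnames[2:3])
  list(Y = structure(Y, class = "alr_tensor"), labels = lab)
}

#' Construct a matrix-variate mixture model by hand
#'
#' Builds a `matmix` model object from explicit parameters, e.g. as the
#' generating model of a simulation. No data are attached.
#'
#' @param pi component sizes (positive, summing to 1).
#' @param M list of K mean matrices, all J x Tc.
#' @param sigma2 K x J matrix (or length-J vector recycled) of positive
#'   experiment variances.
#' @param Psi list of K time correlation matrices, or a numeric vector of
#'   K AR1 parameters `rho`.
#' @return a `matmix` object usable with [simulate.matmix()],
#'   [matmix_loglik()] and [predict.matmix()].
#' @export
matmix_model <- function(pi, M, sigma2, Psi) {
  K <- length(pi)
  stopifnot(abs(sum(pi) - 1) < 1e-12, all(pi > 0), length(M) == K)
  J <- nrow(M[[1L]]); Tc <- ncol(M[[1L]])
  if (!is.matrix(sigma2)) sigma2 <- matrix(sigma2, K, J, byrow = TRUE)
  stopifnot(all(sigma2 > 0), nrow(sigma2) == K, ncol(sigma2) == J)
  sigma2 <- matrix(as.numeric(sigma2), K, J)
  rho <- rep(NA_real_, K)
  if (is.numeric(Psi) && !is.list(Psi)) {
    rho <- Psi
    Psi <- lapply(rho, ar1_cor, Tc = Tc)
    cs <- "ar1"
  } else {
    stopifnot(length(Psi) == K)
    for (P in Psi) {
      stopifnot(all(dim(as.matrix(P)) == c(Tc, Tc)))
      if (max(abs(diag(as.matrix(P)) - 1)) > 1e-8)
        stop("Psi must be a correlation matrix (unit diagonal)")
    }
    cs <- "full"
  }
  structure(list(K = K, pi = pi, M = M, sigma2 = sigma2, Psi = Psi,
                 rho = rho, column_structure = cs, tau = NULL,
                 labels = NULL, loglik = NA_real_, loglik_trace = NULL,
                 nu = n_free_params(K, J, Tc, cs), converged = NA,
                 n_iter = 0L, n = 0L, J = J, Tc = Tc, seed = NULL,
                 dimnames = list(NULL, rownames(M[[1L]]),
                                 colnames(M[[1L]])),
                 call = match.call()), class = "matmix")
}

#' Plot fitted component mean curves
#'
#' One panel per experiment, component mean time courses overlaid in the
#' transformed (log-ratio) space.
#'
#' @param x a `matmix` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.matmix <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$J))
  on.exit(graphics::par(op))
  for (j in seq_len(x$J)) {
    mj <- t(vapply(x$M, function(m) m[j, ], numeric(x$Tc)))
    graphics::matplot(seq_len(x$Tc), t(mj), type = "b", lty = 1,
                      pch = 19, xlab = "time coordinate",
                      ylab = "mean alr coordinate",
                      main = paste("experiment",
                                   x$dimnames[[2L]][j] %||% j), ...)
  }
  invisible(x)
}
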