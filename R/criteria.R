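#' Model-selection criteria for a fitted mixture
#'
#' Per-observation BIC and ICL, smaller is better:
#' `BIC(K) = -l/n + nu_K/(2n) * log n` with `l` the total log-likelihood,
#' and `ICL(K) = BIC(K) + entropy` where
#' `entropy = -(1/n) sum_i sum_k tau_ik log tau_ik` measures how well
#' separated the partition is. The conventional scalings
#' (`-2l + nu log n`, entropy summed, not averaged) rank the same set of
#' fits identically and are reported alongside.
#'
#' @param fit a `matmix` object.
#' @return named list with `loglik`, `nu`, `entropy`, `bic`, `icl`
#'   (per-observation forms) and `bic_conventional`, `icl_conventional`.
#' @export
matmix_criteria <- function(fit) {
  stopifnot(inherits(fit, "matmix"))
  n <- fit$n
  ent <- posterior_entropy(fit$tau)
  bic <- -fit$loglik / n + fit$nu / (2 * n) * log(n)
  icl <- bic + ent / n
  list(loglik = fit$loglik, nu = fit$nu, entropy = ent / n,
       bic = bic, icl = icl,
       bic_conventional = -2 * fit$loglik + fit$nu * log(n),
       icl_conventional = -2 * fit$loglik + fit$nu * log(n) + 2 * ent)
}

# total classification entropy -sum_i sum_k tau log tau (>= 0)
posterior_entropy <- function(tau) {
  tl <- tau * log(tau)
  tl[tau == 0] <- 0
  -sum(tl)
}

#' Fit a range of component counts and select one by ICL or BIC
#'
#' Fits the mixture for every `K` in `k_range` and picks the value
#' minimising the chosen criterion. With `column_structure = "ar1"` each
#' `K` is first fitted with the general correlation structure and that
#' solution then initialises the AR1-restricted refit — the refinement
#' scheme of the workflow.
#'
#' @param Y n x J x Tc data array (an `alr_tensor`).
#' @param k_range integer vector of component counts to try.
#' @param column_structure `"full"` or `"ar1"`.
#' @param criterion `"ICL"` (default) or `"BIC"`.
#' @param seed integer seed; each `K` gets a deterministic child seed.
#' @param ... further arguments passed to [matmix()] (`n_starts`, `tol`,
#'   `max_iter`).
#' @return object of class `matmix_select`: list with `best` (the selected
#'   `matmix` fit), `table` (data frame of K, loglik, nu, BIC, ICL,
#'   convergence), `criterion`, and for AR1 also `full_fits` criteria.
#' @export
matmix_select <- function(Y, k_range, column_structure = c("full", "ar1"),
                          criterion = c("ICL", "BIC"), seed = NULL, ...) {
  column_structure <- match.arg(column_structure)
  criterion <- match.arg(criterion)
  sel <- select_k_engine(Y, k_range, column_structure, criterion,
                         seed = seed, keep_full = FALSE, ...)
  sel
}

# shared engine; keep_full = TRUE additionally returns the selection for
# the general-correlation fits (used by the simulation study so the full
# and AR1 methods share one EM pass)
select_k_engine <- function(Y, k_range, column_structure, criterion,
                            seed = NULL, keep_full = FALSE, ...) {
  stopifnot(length(k_range) >= 1L)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- vector("list", length(k_range))
  full_fits <- vector("list", length(k_range))
  rows <- vector("list", length(k_range))
  full_rows <- vector("list", length(k_range))
  for (idx in seq_along(k_range)) {
    K <- k_range[idx]
    child <- if (is.null(seed)) NULL else (seed + 1009L * K) %% 2147483629L
    fit <- tryCatch(matmix(Y, K, column_structure = "full", seed = child,
                           ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("K = ", K, " failed: ", conditionMessage(fit))
      next
    }
    if (column_structure == "ar1") {
      full_fits[[idx]] <- fit
      full_rows[[idx]] <- crit_row(fit)
      fit2 <- tryCatch(refit_ar1(Y, fit), error = function(e) e)
      if (inherits(fit2, "error")) {
        warning("AR1 refit at K = ", K, " failed: ",
                conditionMessage(fit2))
        next
      }
      fits[[idx]] <- fit2
      rows[[idx]] <- crit_row(fit2)
    } else {
      fits[[idx]] <- fit
      rows[[idx]] <- crit_row(fit)
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("every component count in k_range failed to fit")
  tab <- do.call(rbind, rows[ok])
  best_i <- which(ok)[which.min(tab[[tolower(criterion)]])]
  out <- list(best = fits[[best_i]], table = tab, criterion = criterion,
              column_structure = column_structure, k_range = k_range)
  if (keep_full && column_structure == "ar1") {
    ok_f <- !vapply(full_fits, is.null, logical(1))
    ftab <- do.call(rbind, full_rows[ok_f])
    fbest <- which(ok_f)[which.min(ftab[[tolower(criterion)]])]
    out$full <- list(best = full_fits[[fbest]], table = ftab,
                     criterion = criterion, column_structure = "full",
                     k_range = k_range)
    class(out$full) <- "matmix_select"
  }
  class(out) <- "matmix_select"
  out
}

crit_row <- function(fit) {
  cr <- matmix_criteria(fit)
  data.frame(K = fit$K, loglik = cr$loglik, nu = cr$nu, bic = cr$bic,
             icl = cr$icl, bic_conventional = cr$bic_conventional,
             converged = fit$converged)
}

#' @export
print.matmix_select <- function(x, ...) {
  cat("Model selection over K in {",
      paste(x$table$K, collapse = ", "), "} by ", x$criterion,
      " (", x$column_structure, " time correlation)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 6)
  cat("selected: K =", x$best$K, "\n")
  invisible(x)
}

#' @export
plot.matmix_select <- function(x, ...) {
  graphics::matplot(x$table$K, cbind(x$table$bic, x$table$icl),
                    type = "b", pch = c(1, 19), lty = 1,
                    col = c("grey40", "black"),
                    xlab = "number of components K",
                    ylab = "criterion (per observation, smaller better)",
                    ...)
  graphics::legend("topright", c("BIC", "ICL"), pch = c(1, 19),
                   col = c("grey40", "black"), bty = "n")
  graphics::abline(v = x$best$K, lty = 3)
  invisible(x)
}
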