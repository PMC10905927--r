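#' Gaussian clusters mapped onto the 3-part simplex
#'
#' Draws two-dimensional Gaussian clusters in log-ratio space and maps
#' them through the inverse alr transform onto the three-part simplex —
#' the construction used to illustrate how compact Euclidean clusters can
#' occupy very different volumes on the simplex.
#'
#' @param cluster_params list of per-cluster lists with elements `weight`,
#'   `mean` (length 2) and `cov` (2 x 2 positive definite).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param ref which part acts as the alr reference (default the last).
#' @return list with `comp` (n x 3 matrix of compositions summing to 1),
#'   `z` (the Euclidean draws) and `labels`.
#' @export
simplex_clusters <- function(cluster_params, n, seed = NULL, ref = 3L) {
  if (!is.null(seed)) set.seed(seed)
  w <- vapply(cluster_params, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("cluster weights must sum to 1")
  lab <- sample.int(length(w), n, replace = TRUE, prob = w)
  z <- matrix(NA_real_, n, 2L)
  for (k in seq_along(cluster_params)) {
    idx <- which(lab == k)
    if (!length(idx)) next
    cv <- as.matrix(cluster_params[[k]]$cov)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("cluster ", k, " covariance is not positive ",
                           "definite")
    L <- chol(cv)
    z[idx, ] <- matrix(stats::rnorm(2L * length(idx)), ncol = 2L) %*% L
    z[idx, ] <- sweep(z[idx, , drop = FALSE], 2L,
                      cluster_params[[k]]$mean, `+`)
  }
  comp <- t(apply(z, 1L, alr_inv, ref = ref))
  list(comp = comp, z = z, labels = lab)
}

#' Flattened two-way Gaussian mixture clustering
#'
#' The classical two-way competitor: the third (experiment) dimension is
#' flattened out, and a finite mixture of multivariate Gaussians with
#' unconstrained component covariances ("VVV") is fitted over a range of
#' component counts, selecting K by ICL (BIC also reported). Backed by
#' the mclust package.
#'
#' @param X n x (J*Tc) matrix, or an n x J x Tc array which is flattened.
#' @param k_range component counts to compare.
#' @param criterion `"ICL"` or `"BIC"`.
#' @param seed optional integer seed.
#' @return list with `labels`, `K`, `table` (K, ICL, BIC in mclust's
#'   larger-is-better convention) and the fitted `Mclust` object.
#' @importFrom mclust Mclust mclustBIC mclustICL
#' @export
flat_gmm <- function(X, k_range, criterion = c("ICL", "BIC"),
                     seed = NULL) {
  criterion <- match.arg(criterion)
  if (is.array(X) && length(dim(X)) == 3L) X <- vec_data(X)
  if (!is.null(seed)) set.seed(seed)
  icl_tab <- suppressWarnings(
    mclust::mclustICL(X, G = k_range, modelNames = "VVV", verbose = FALSE))
  bic_tab <- suppressWarnings(
    mclust::mclustBIC(X, G = k_range, modelNames = "VVV", verbose = FALSE))
  iclv <- icl_tab[, "VVV"]; bicv <- bic_tab[, "VVV"]
  if (all(is.na(iclv))) stop("no flattened mixture could be fitted")
  crit <- if (criterion == "ICL") iclv else bicv
  Kbest <- k_range[which.max(crit)]
  fit <- suppressWarnings(
    mclust::Mclust(X, G = Kbest, modelNames = "VVV", verbose = FALSE))
  list(labels = as.integer(fit$classification), K = Kbest,
       table = data.frame(K = k_range, icl = as.numeric(iclv),
                          bic = as.numeric(bicv)),
       fit = fit)
}

#' k-means with silhouette-based choice of K
#'
#' Runs k-means on the flattened data for every K in `k_range` (K >= 2)
#' and keeps the solution maximising the average Euclidean silhouette
#' width.
#'
#' @param X n x p matrix or n x J x Tc array.
#' @param k_range candidate cluster counts; values below 2 are dropped.
#' @param seed optional integer seed.
#' @param nstart random restarts per K.
#' @return list with `labels`, `K` and `avg_sil` (named vector over K).
#' @export
kmeans_silhouette <- function(X, k_range, seed = NULL, nstart = 10L) {
  if (is.array(X) && length(dim(X)) == 3L) X <- vec_data(X)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range < nrow(X)]
  if (!length(k_range)) stop("k_range must contain values in 2..n-1")
  if (!is.null(seed)) set.seed(seed)
  dX <- stats::dist(X)
  avg <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    km <- NULL
    for (try in 1:5) {
      km <- tryCatch(stats::kmeans(X, centers = k_range[i],
                                   nstart = nstart, iter.max = 100L),
                     error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) next
    sw <- cluster::silhouette(km$cluster, dX)
    avg[i] <- mean(sw[, "sil_width"])
    labs[[i]] <- km$cluster
  }
  if (all(is.na(avg))) stop("k-means failed for every K")
  best <- which.max(avg)
  list(labels = as.integer(labs[[best]]), K = k_range[best], avg_sil = avg)
}

#' Synthetic generating model for the scaled-down simulation study
#'
#' A synthetic 10-component AR1 mixture emulating the kind of model
#' fitted to a two-strain stress time course (no real fitted model is
#' shipped): K = 10 components on 2 x 5 matrices, component sizes
#' spanning 26..181 of 769 genes, smooth mean time courses with
#' the mutant row a perturbation of the wild-type row, heteroscedastic
#' experiment variances, and AR1 time autocorrelations between 0.3 and
#' 0.8. Deterministic given the seed.
#'
#' @param K,J,Tc model dimensions.
#' @param seed integer seed fixing the construction.
#' @return a `matmix` model object.
#' @export
study_generator <- function(K = 10L, J = 2L, Tc = 5L, seed = 20240301L) {
  set.seed(seed)
  sizes <- round(seq(26, 181, length.out = K))
  pi <- sizes / sum(sizes)
  M <- vector("list", K)
  for (k in seq_len(K)) {
    base <- cumsum(stats::rnorm(Tc, 0, 0.8)) + stats::rnorm(1, 0, 0.8)
    M[[k]] <- rbind(base, base + stats::rnorm(Tc, 0, 0.5))
    rownames(M[[k]]) <- c("WT", "Mut")
  }
  sigma2 <- matrix(exp(stats::rnorm(K * J, log(0.12), 0.5)), K, J)
  rho <- stats::runif(K, 0.3, 0.8)
  matmix_model(pi = pi, M = M, sigma2 = sigma2, Psi = rho)
}

#' Simulate a raw three-way count tensor
#'
#' Generates a count dataset with the structure of a two-strain osmotic
#' stress time course (n genes, T time points, J experiments, R
#' replicates): underlying expression profiles come from a matrix-variate
#' mixture in alr space mapped back to the simplex, gene abundances are
#' log-normal, per-sample depths vary log-normally, and counts are
#' Poisson draws. Purely synthetic; intended as a desk-scale stand-in for
#' a real dataset of the same shape.
#'
#' @param n,T,J,R numbers of genes, time points, experiments, replicates.
#' @param model generating mixture on (T-1)-column matrices; default
#'   [study_generator()].
#' @param mean_reads expected reads per gene per sample.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples matrix), `meta` (sample
#'   metadata data frame) and `labels` (true component per gene).
#' @export
simulate_counts <- function(n = 769L, T = 6L, J = 2L, R = 3L,
                            model = study_generator(Tc = T - 1L),
                            mean_reads = 200, seed = 1L) {
  stopifnot(model$Tc == T - 1L, model$J == J)
  set.seed(seed)
  sim <- simulate(model, nsim = n)
  P <- alr_to_profiles(sim$Y, ref_time = 1L)   # n x T x J
  abund <- exp(stats::rnorm(n, log(mean_reads * T), 1))
  depth <- exp(stats::rnorm(T * J * R, 0, 0.25))
  exps <- paste0("E", seq_len(J)); times <- sprintf("T%d", 0:(T - 1L))
  meta <- expand.grid(time = times, experiment = exps,
                      replicate = seq_len(R), stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_r%d", meta$experiment, meta$time,
                         meta$replicate)
  counts <- matrix(0L, n, nrow(meta),
                   dimnames = list(sprintf("gene%04d", seq_len(n)),
                                   meta$sample))
  for (s in seq_len(nrow(meta))) {
    ti <- match(meta$time[s], times); ji <- match(meta$experiment[s], exps)
    mu <- abund * P[, ti, ji] * depth[s]
    counts[, s] <- stats::rpois(n, mu)
  }
  list(counts = counts, meta = meta[, c("sample", "experiment", "time",
                                        "replicate")],
       labels = sim$labels)
}

#' Scaled-down simulation study comparing four clustering methods
#'
#' Replicates, at desk scale, the comparison of three-way clustering
#' (full and AR1 time correlation), flattened two-way Gaussian mixture
#' clustering, and k-means with silhouette-based K selection: for each
#' replicate dataset drawn from `model`, every method clusters the data
#' and is scored by the adjusted Rand index against the true labels and
#' by its selected number of clusters. The three-way full and AR1 methods
#' share one EM pass per dataset (the AR1 fits are refinements of the
#' full fits).
#'
#' @param model generating `matmix` mixture; default [study_generator()].
#' @param n_datasets number of replicate datasets.
#' @param n observations (genes) per dataset.
#' @param k_range component counts compared by every method.
#' @param methods subset of `"threeway-full"`, `"threeway-ar1"`,
#'   `"twoway-gmm"`, `"kmeans"`.
#' @param criterion selection criterion for the model-based methods.
#' @param seed integer master seed; per-dataset child seeds are derived
#'   deterministically.
#' @param n_starts,tol,max_iter EM controls for the three-way fits
#'   (defaults chosen for the desk-scale study).
#' @return object of class `simstudy`: data frame `results` (dataset,
#'   method, selected_K, ARI) plus `summary` (per-method median and
#'   quartiles of ARI, modal selected K) and the design.
#' @export
run_simulation_study <- function(model = study_generator(),
                                 n_datasets = 10L, n = 769L,
                                 k_range = 1:15,
                                 methods = c("threeway-full",
                                             "threeway-ar1",
                                             "twoway-gmm", "kmeans"),
                                 criterion = "ICL", seed = 1L,
                                 n_starts = 2L, tol = 1e-7,
                                 max_iter = 200L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_datasets >= 1L)
  rows <- list()
  for (d in seq_len(n_datasets)) {
    child <- (seed + 7919L * d) %% 2147483629L
    sim <- simulate(model, nsim = n, seed = child)
    truth <- sim$labels
    need3 <- any(c("threeway-full", "threeway-ar1") %in% methods)
    if (need3) {
      sel <- tryCatch(
        select_k_engine(sim$Y, k_range, "ar1", criterion, seed = child,
                        keep_full = TRUE, n_starts = n_starts, tol = tol,
                        max_iter = max_iter),
        error = function(e) e)
      if (!inherits(sel, "error")) {
        if ("threeway-full" %in% methods)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = d, method = "threeway-full", selected_K = sel$full$best$K,
            ARI = ari_or_unit(truth, sel$full$best$labels))
        if ("threeway-ar1" %in% methods)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = d, method = "threeway-ar1", selected_K = sel$best$K,
            ARI = ari_or_unit(truth, sel$best$labels))
      } else {
        warning("dataset ", d, ": three-way fit failed: ",
                conditionMessage(sel))
      }
    }
    if ("twoway-gmm" %in% methods) {
      tw <- tryCatch(flat_gmm(sim$Y, k_range, criterion, seed = child),
                     error = function(e) e)
      if (!inherits(tw, "error"))
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = d, method = "twoway-gmm", selected_K = tw$K,
          ARI = ari_or_unit(truth, tw$labels))
      else warning("dataset ", d, ": two-way fit failed")
    }
    if ("kmeans" %in% methods) {
      km <- tryCatch(kmeans_silhouette(sim$Y, k_range, seed = child),
                     error = function(e) e)
      if (!inherits(km, "error"))
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = d, method = "kmeans", selected_K = km$K,
          ARI = ari_or_unit(truth, km$labels))
      else warning("dataset ", d, ": k-means failed")
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$method), function(r)
    data.frame(method = r$method[1L],
               median_ARI = stats::median(r$ARI),
               q1_ARI = stats::quantile(r$ARI, 0.25, names = FALSE),
               q3_ARI = stats::quantile(r$ARI, 0.75, names = FALSE),
               modal_K = modal_value(r$selected_K),
               n_datasets = nrow(r))))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ,
                 design = list(n_datasets = n_datasets, n = n,
                               k_range = k_range, methods = methods,
                               criterion = criterion, seed = seed,
                               K_true = model$K, J = model$J,
                               Tc = model$Tc)),
            class = "simstudy")
}

# single-cluster truth against single-cluster estimate is a perfect match
# even though the adjustment formula is 0/0 there
ari_or_unit <- function(a, b) {
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  adjusted_rand(a, b)
}

modal_value <- function(x) {
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}

#' @export
print.simstudy <- function(x, ...) {
  cat("Simulation study:", x$design$n_datasets, "datasets of",
      x$design$n, "observations, true K =", x$design$K_true, "\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.simstudy <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(ARI ~ method, data = x$results, ylab = "ARI",
                    las = 2, ...)
  graphics::boxplot(selected_K ~ method, data = x$results,
                    ylab = "selected K", las = 2, ...)
  graphics::abline(h = x$design$K_true, lty = 3)
  invisible(x)
}
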