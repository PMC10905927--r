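#' Density-based silhouette information
#'
#' For each observation, the log ratio of its largest to its second
#' largest posterior probability, normalised by the maximum absolute log
#' ratio over all observations so that values lie in \[-1, 1\]:
#' `dbsi(y_i) = log(tau_k0 / tau_k1) / max_iota |log(tau_k0 / tau_k1)|`.
#' Posteriors are first winsorized to \[1e-5, 1 - 1e-5\] to avoid
#' infinite ratios. A value near 1 marks an observation firmly assigned
#' to its cluster; values near 0 mark ambiguous assignments.
#'
#' @param tau n x K posterior matrix (rows summing to 1), or a `matmix`
#'   fit whose `$tau` is used.
#' @param winsor length-2 clamp applied to the posteriors.
#' @return list of class `dbsi` with `values` (in \[-1, 1\]), `labels`
#'   (MAP components) and `winsor`.
#' @export
dbsi <- function(tau, winsor = c(1e-5, 1 - 1e-5)) {
  if (inherits(tau, "matmix")) tau <- tau$tau
  tau <- as.matrix(tau)
  if (ncol(tau) < 2L)
    stop("dbsi needs at least two components (no second-best cluster)")
  tw <- pmin(pmax(tau, winsor[1L]), winsor[2L])
  labels <- map_classify(tau)
  r <- vapply(seq_len(nrow(tw)), function(i) {
    o <- order(tw[i, ], decreasing = TRUE)
    log(tw[i, o[1L]] / tw[i, o[2L]])
  }, numeric(1))
  mx <- max(abs(r))
  vals <- if (mx == 0) r else r / mx
  structure(list(values = vals, labels = labels, winsor = winsor),
            class = "dbsi")
}

#' @export
print.dbsi <- function(x, ...) {
  cat("dbsi for", length(x$values), "observations in",
      length(unique(x$labels)), "clusters; overall average",
      format(mean(x$values), digits = 3), "\n")
  invisible(x)
}

#' Classic silhouette widths
#'
#' Euclidean silhouette `s(y_i) = (b - a) / max(a, b)` with `a` the
#' average distance to the observation's own cluster and `b` the smallest
#' average distance to another cluster; singletons get 0.
#'
#' @param X n x p matrix (e.g. vectorised alr tensors), or an n x J x Tc
#'   array which is vectorised.
#' @param labels integer cluster labels (at least two clusters).
#' @return numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_width <- function(X, labels) {
  if (is.array(X) && length(dim(X)) == 3L) X <- vec_data(X)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least two clusters")
  sil <- cluster::silhouette(labels, stats::dist(X))
  out <- rep(0, length(labels))
  if (is.matrix(sil)) out <- sil[, "sil_width"]
  out
}

#' Scaled distance to the cluster centre in profile space
#'
#' The fitted mean of each observation's MAP component is mapped row-wise
#' back to the simplex with [alr_inv()], giving the cluster centre as a
#' profile over all `T` time points and `J` experiments; the Euclidean
#' distance between each observation's profile and its centre is then
#' divided by the largest such distance, so values lie in \[0, 1\] with
#' the globally farthest observation at exactly 1. Small distances mark
#' compact clusters in the original space.
#'
#' @param profiles gene x time x experiment `profile_tensor` (original
#'   space, `T` time points).
#' @param model a `matmix` fit in the transformed space (`Tc = T - 1`).
#' @param labels MAP labels; default taken from the model.
#' @param ref_time reference time index used by the transform.
#' @return list with `distance` (scaled, in \[0, 1\]), `raw` (unscaled
#'   Euclidean distances) and `centers` (K x T x J array of
#'   back-transformed component means).
#' @export
center_distance <- function(profiles, model, labels = model$labels,
                            ref_time = 1L) {
  P <- unclass(profiles)
  stopifnot(is.array(P), length(dim(P)) == 3L, inherits(model, "matmix"))
  n <- dim(P)[1L]; Tt <- dim(P)[2L]; J <- dim(P)[3L]
  if (J != model$J || Tt != model$Tc + 1L)
    stop("profile dimensions do not match the model (expected T = Tc + 1 ",
         "and matching J)")
  centers <- array(NA_real_, c(model$K, Tt, J))
  for (k in seq_len(model$K))
    for (j in seq_len(J))
      centers[k, , j] <- alr_inv(model$M[[k]][j, ], ref = ref_time)
  raw <- vapply(seq_len(n), function(i)
    sqrt(sum((P[i, , ] - centers[labels[i], , ])^2)), numeric(1))
  mx <- max(raw)
  list(distance = if (mx == 0) raw else raw / mx, raw = raw,
       centers = centers)
}

#' Data behind the dbsi information plot
#'
#' Per-cluster dbsi values in decreasing order, clusters ordered by their
#' average silhouette width (supply `sil`) or, by default, by their
#' average dbsi; plus per-cluster and overall averages.
#'
#' @param d a `dbsi` object.
#' @param sil optional classic silhouette widths (same length) used for
#'   the cluster ordering.
#' @return list with `series` (list of sorted value vectors, one per
#'   cluster, in plotting order), `cluster_order`, `cluster_means`,
#'   `cluster_sizes` and `overall_mean`.
#' @export
dbsi_plot_data <- function(d, sil = NULL) {
  stopifnot(inherits(d, "dbsi"))
  cl <- sort(unique(d$labels))
  means <- vapply(cl, function(k) mean(d$values[d$labels == k]),
                  numeric(1))
  ordkey <- if (is.null(sil)) means else
    vapply(cl, function(k) mean(sil[d$labels == k]), numeric(1))
  ord <- order(ordkey, decreasing = TRUE)
  series <- lapply(cl[ord], function(k)
    sort(d$values[d$labels == k], decreasing = TRUE))
  names(series) <- cl[ord]
  list(series = series, cluster_order = cl[ord],
       cluster_means = stats::setNames(means, cl)[as.character(cl[ord])],
       cluster_sizes = stats::setNames(
         as.integer(table(factor(d$labels, levels = cl))),
         cl)[as.character(cl[ord])],
       overall_mean = mean(d$values))
}

#' Data behind the cluster map
#'
#' One point per observation — dbsi (separation, transformed space)
#' against scaled distance to the cluster centre (compactness, original
#' space) — plus the convex hull of each cluster's points in the
#' (distance, dbsi) plane. Clusters with fewer than three points yield a
#' degenerate hull (segment or single point).
#'
#' @param d a `dbsi` object.
#' @param distance scaled distances from [center_distance()].
#' @param labels cluster labels; default the dbsi MAP labels.
#' @return list with `points` (data frame: dbsi, distance, cluster) and
#'   `hulls` (per cluster, the hull vertices as a data frame).
#' @export
cluster_map_data <- function(d, distance, labels = d$labels) {
  stopifnot(inherits(d, "dbsi"),
            length(distance) == length(d$values),
            length(labels) == length(d$values))
  pts <- data.frame(dbsi = d$values, distance = distance,
                    cluster = labels)
  hulls <- lapply(split(pts, pts$cluster), function(p) {
    idx <- grDevices::chull(p$distance, p$dbsi)
    p[idx, c("distance", "dbsi")]
  })
  list(points = pts, hulls = hulls)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same
#' observations, computed from the contingency table by the
#' permutation-model adjustment. 1 for identical partitions (up to
#' relabelling), about 0 for independent ones. The degenerate case where
#' both partitions are single clusters is defined as 1.
#'
#' @param a,b label vectors of equal length.
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Contingency table of two partitions
#'
#' @param a,b label vectors of equal length.
#' @return a `table` whose entries sum to the number of observations.
#' @export
cluster_contingency <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length")
  table(a, b, dnn = c("partition a", "partition b"))
}

## ---- rendering --------------------------------------------------------

#' dbsi information plot
#'
#' Bars of per-observation dbsi values, decreasing within cluster,
#' clusters side by side in the chosen order, with per-cluster averages
#' marked.
#'
#' @param d a `dbsi` object.
#' @param sil optional silhouette widths for the cluster ordering (see
#'   [dbsi_plot_data()]).
#' @param ... passed to [graphics::barplot()].
#' @export
plot_dbsi <- function(d, sil = NULL, ...) {
  pd <- dbsi_plot_data(d, sil)
  vals <- unlist(pd$series, use.names = FALSE)
  cols <- grDevices::hcl.colors(length(pd$series), "Dark 3")
  colv <- rep(cols, lengths(pd$series))
  graphics::barplot(vals, col = colv, border = NA, space = 0,
                    ylim = c(min(0, min(vals)), 1),
                    ylab = "dbsi", xlab = "genes grouped by cluster", ...)
  graphics::abline(h = pd$overall_mean, lty = 2)
  at <- cumsum(lengths(pd$series)) - lengths(pd$series) / 2
  graphics::mtext(names(pd$series), side = 1, at = at, line = 0.5,
                  cex = 0.8)
  invisible(pd)
}

#' Cluster map plot
#'
#' Faceted scatter of dbsi against scaled distance to the cluster centre,
#' one facet per cluster, with the cluster's convex hull drawn.
#'
#' @param cm output of [cluster_map_data()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_cluster_map <- function(cm, ...) {
  cl <- names(cm$hulls)
  nc <- ceiling(sqrt(length(cl)))
  nr <- ceiling(length(cl) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3.5, 3.5, 2, 0.5),
                      mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  for (k in cl) {
    p <- cm$points[cm$points$cluster == k, ]
    if (!nrow(p)) {
      warning("cluster ", k, " is empty; facet skipped")
      next
    }
    graphics::plot(p$distance, p$dbsi, xlim = c(0, 1), ylim = c(-1, 1),
                   xlab = "distance to centre", ylab = "dbsi",
                   main = paste("cluster", k), pch = 19, cex = 0.5, ...)
    h <- cm$hulls[[k]]
    if (nrow(h) >= 2L)
      graphics::polygon(h$distance, h$dbsi, border = "grey40")
  }
  invisible(cm)
}

#' Cluster expression-profile panels
#'
#' For each selected cluster, plots every member's curve with the
#' experiments side by side along the x axis (time within experiment) —
#' either the alr coordinates or the original profiles.
#'
#' @param Y n x J x Tc (or n x T x J profile) array.
#' @param labels cluster labels.
#' @param clusters which clusters to draw (default all).
#' @param profile_space set `TRUE` when `Y` is a gene x time x experiment
#'   profile tensor rather than an alr tensor.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_cluster_profiles <- function(Y, labels, clusters = NULL,
                                  profile_space = FALSE, ...) {
  A <- unclass(Y)
  stopifnot(is.array(A), length(dim(A)) == 3L)
  if (profile_space) A <- aperm(A, c(1L, 3L, 2L))  # to gene x exp x time
  J <- dim(A)[2L]; Tc <- dim(A)[3L]
  flat <- matrix(NA_real_, dim(A)[1L], J * Tc)
  for (j in seq_len(J))
    flat[, (j - 1L) * Tc + seq_len(Tc)] <- A[, j, ]
  if (is.null(clusters)) clusters <- sort(unique(labels))
  op <- graphics::par(mfrow = c(1, length(clusters)))
  on.exit(graphics::par(op))
  for (k in clusters) {
    graphics::matplot(t(flat[labels == k, , drop = FALSE]), type = "l",
                      lty = 1, col = grDevices::adjustcolor(1, 0.3),
                      xlab = "experiment x time",
                      ylab = if (profile_space) "profile" else
                        "alr coordinate",
                      main = paste("cluster", k), ...)
    graphics::abline(v = Tc + 0.5, lty = 3)
  }
  invisible(NULL)
}
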