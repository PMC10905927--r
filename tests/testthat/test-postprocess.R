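test_that("dbsi follows the winsorized log-ratio formula", {
  tau <- matrix(c(0.9, 0.1,
                  0.6, 0.4), 2, 2, byrow = TRUE)
  d <- dbsi(tau)
  expect_equal(d$values, c(1, log(1.5) / log(9)))
  expect_identical(d$labels, c(1L, 1L))
  # equal top-two posteriors map to exactly zero
  d0 <- dbsi(matrix(c(0.5, 0.5, 0.9, 0.1), 2, 2, byrow = TRUE))
  expect_equal(d0$values[1], 0)
  # a hard (1, 0) row is clamped before the ratio and stays finite
  dh <- dbsi(matrix(c(1, 0, 0.6, 0.4), 2, 2, byrow = TRUE))
  expect_true(all(is.finite(dh$values)))
  expect_equal(max(abs(dh$values)), 1)
  expect_error(dbsi(matrix(1, 3, 1)), "two components")
})

test_that("dbsi contract: range, extreme, idempotence", {
  set.seed(14)
  tau <- matrix(rexp(60 * 4), 60, 4)
  tau <- tau / rowSums(tau)
  d <- dbsi(tau)
  expect_true(all(d$values >= -1 & d$values <= 1))
  expect_equal(max(abs(d$values)), 1)
  # recomputation from winsorized posteriors is idempotent
  tw <- pmin(pmax(tau, 1e-5), 1 - 1e-5)
  expect_equal(dbsi(tw)$values, d$values)
})

test_that("silhouette widths match a brute-force oracle", {
  X <- matrix(c(0, 0, 0, 1, 0.5, 0.5, 10, 10, 10, 11), 5, 2,
              byrow = TRUE)
  lab <- c(1, 1, 1, 2, 2)
  s <- silhouette_width(X, lab)
  D <- as.matrix(dist(X))
  oracle <- vapply(1:5, function(i) {
    own <- which(lab == lab[i] & seq_len(5) != i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(k)
      mean(D[i, lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(unname(s), oracle, tolerance = 1e-12)
  expect_true(all(s >= -1 & s <= 1))
  # two tight far-apart clusters: all widths near 1
  set.seed(2)
  X2 <- rbind(matrix(rnorm(40, 0, 0.05), 20),
              matrix(rnorm(40, 20, 0.05), 20))
  expect_true(all(silhouette_width(X2, rep(1:2, each = 20)) > 0.95))
  expect_error(silhouette_width(X2, rep(1, 40)), "two clusters")
})

test_that("centre distances are scaled Euclidean norms in profile space", {
  # 3 genes, T = 3, J = 1; model in the 2-coordinate transformed space
  m <- matmix_model(pi = c(0.5, 0.5),
                    M = list(matrix(c(log(0.5), log(0.5)), 1, 2),
                             matrix(c(log(2), log(3)), 1, 2)),
                    sigma2 = matrix(1, 2, 1), Psi = c(0, 0))
  c1 <- alr_inv(c(log(0.5), log(0.5)), ref = 1)   # (0.5, 0.25, 0.25)
  c2 <- alr_inv(c(log(2), log(3)), ref = 1)       # (1/6, 2/6, 3/6)
  P <- array(NA_real_, c(3, 3, 1))
  P[1, , 1] <- c1                  # exactly at its centre
  P[2, , 1] <- c(0.3, 0.4, 0.3)
  P[3, , 1] <- c(0.6, 0.3, 0.1)
  lab <- c(1L, 2L, 2L)
  cd <- center_distance(P, m, labels = lab)
  raw <- c(0, sqrt(sum((P[2, , 1] - c2)^2)), sqrt(sum((P[3, , 1] - c2)^2)))
  expect_equal(cd$raw, raw, tolerance = 1e-12)
  expect_equal(cd$distance, raw / max(raw), tolerance = 1e-12)
  expect_equal(max(cd$distance), 1)
  expect_equal(cd$distance[1], 0)
  # rigid translation of profiles and centres preserves the raw core
  shift <- 0.05
  cd2raw <- sqrt(sum((P[2, , 1] + shift - (c2 + shift))^2))
  expect_equal(cd2raw, raw[2])
  expect_error(center_distance(array(1 / 3, c(3, 4, 2)), m, lab),
               "dimensions")
})

test_that("dbsi plot data sorts within cluster and averages correctly", {
  d <- structure(list(values = c(0.9, 0.5, 0.7, 0.2, 0.4, 0.4),
                      labels = c(1L, 1L, 2L, 2L, 3L, 3L),
                      winsor = c(1e-5, 1 - 1e-5)), class = "dbsi")
  pd <- dbsi_plot_data(d)
  expect_true(all(vapply(pd$series, function(v) all(diff(v) <= 0),
                         logical(1))))
  expect_equal(pd$overall_mean, mean(d$values))
  expect_equal(unname(pd$cluster_means[as.character(1:3)]),
               c(0.7, 0.45, 0.4))
  # ordering by average: cluster 1 first
  expect_equal(pd$cluster_order[1], 1L)
  # weighted per-cluster averages reproduce the overall mean
  expect_equal(sum(pd$cluster_means * pd$cluster_sizes) /
                 sum(pd$cluster_sizes), pd$overall_mean)
  # shuffling observations changes nothing
  p <- c(4, 2, 6, 1, 3, 5)
  d2 <- d; d2$values <- d$values[p]; d2$labels <- d$labels[p]
  expect_equal(dbsi_plot_data(d2), pd)
})

test_that("cluster map hulls contain all their points", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  d <- structure(list(values = sq$y * 2 - 1, labels = rep(1L, 4),
                      winsor = c(1e-5, 1 - 1e-5)), class = "dbsi")
  cm <- cluster_map_data(d, distance = sq$x)
  expect_equal(nrow(cm$hulls[["1"]]), 4L)  # the square's own corners
  # identical points collapse to a single-vertex hull
  d1 <- structure(list(values = rep(0.5, 3), labels = rep(1L, 3),
                       winsor = c(1e-5, 1 - 1e-5)), class = "dbsi")
  cm1 <- cluster_map_data(d1, distance = rep(0.2, 3))
  expect_lte(nrow(cm1$hulls[["1"]]), 2L)
  # random cluster: all points inside or on the hull (ray casting via
  # sign of cross products around the hull polygon)
  set.seed(33)
  n <- 20
  dd <- structure(list(values = runif(n, -1, 1), labels = rep(1L, n),
                       winsor = c(1e-5, 1 - 1e-5)), class = "dbsi")
  dist <- runif(n)
  cm2 <- cluster_map_data(dd, distance = dist)
  h <- cm2$hulls[["1"]]
  inside <- function(px, py) {
    v <- nrow(h)
    cr <- vapply(seq_len(v), function(a) {
      b <- if (a == v) 1L else a + 1L
      (h$distance[b] - h$distance[a]) * (py - h$dbsi[a]) -
        (h$dbsi[b] - h$dbsi[a]) * (px - h$distance[a])
    }, numeric(1))
    all(cr <= 1e-12) || all(cr >= -1e-12)
  }
  expect_true(all(mapply(inside, dist, dd$values)))
  # hull vertices are a subset of the cluster's points
  expect_true(all(h$distance %in% dist & h$dbsi %in% dd$values))
})

test_that("adjusted Rand index: identities, symmetry, pair oracle", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand(a, a), 1)
  expect_equal(adjusted_rand(a, c(2, 2, 3, 3, 1, 1)), 1)  # relabelled
  expect_equal(adjusted_rand(a, rep(1, 6)), 0)  # chance level
  expect_equal(adjusted_rand(rep(1, 6), rep(1, 6)), 1)  # both trivial
  set.seed(41)
  for (rep in 1:10) {
    x <- sample(1:3, 8, replace = TRUE)
    y <- sample(1:3, 8, replace = TRUE)
    expect_equal(adjusted_rand(x, y), ari_pairs(x, y), tolerance = 1e-12)
    expect_equal(adjusted_rand(x, y), adjusted_rand(y, x))
  }
  expect_error(adjusted_rand(1:3, 1:4), "equal length")
})

test_that("adjusted Rand agrees with the mclust implementation", {
  set.seed(6)
  x <- sample(1:4, 50, replace = TRUE)
  y <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjusted_rand(x, y), mclust::adjustedRandIndex(x, y),
               tolerance = 1e-12)
})

test_that("contingency tables tally correctly and sum to n", {
  a <- c(1, 1, 2, 2); b <- c(1, 1, 2, 2)
  tab <- cluster_contingency(a, b)
  expect_equal(sum(tab), 4)
  expect_equal(as.vector(diag(tab)), c(2, 2))
  a2 <- c(1, 2, 1, 2, 2); b2 <- c("x", "x", "y", "y", "x")
  t2 <- cluster_contingency(a2, b2)
  expect_equal(t2["1", "x"], 1, ignore_attr = TRUE)
  expect_equal(t2["2", "x"], 2, ignore_attr = TRUE)
  expect_equal(sum(t2), 5)
  p <- c(3, 1, 5, 2, 4)
  expect_equal(cluster_contingency(a2[p], b2[p]), t2)
})

test_that("diagnostic plots render non-empty files", {
  m <- toy_model_3()
  s <- simulate(m, nsim = 90, seed = 3)
  f <- matmix(s$Y, 3, n_starts = 2, seed = 2)
  d <- dbsi(f)
  P <- alr_to_profiles(s$Y)
  cd <- center_distance(P, f)
  cm <- cluster_map_data(d, cd$distance)
  tmp <- withr::local_tempdir()
  for (nm in c("dbsi", "map", "prof")) {
    path <- file.path(tmp, paste0(nm, ".png"))
    grDevices::png(path, 600, 400)
    switch(nm,
           dbsi = plot_dbsi(d),
           map = plot_cluster_map(cm),
           prof = plot_cluster_profiles(s$Y, f$labels))
    grDevices::dev.off()
    expect_true(file.exists(path) && file.size(path) > 0)
  }
  # one facet (hull) per cluster in the map data
  expect_identical(sort(as.integer(names(cm$hulls))),
                   sort(unique(f$labels)))
  # plotted values lie inside the fixed axis ranges of the map
  expect_true(all(cm$points$distance >= 0 & cm$points$distance <= 1))
  expect_true(all(cm$points$dbsi >= -1 & cm$points$dbsi <= 1))
})
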