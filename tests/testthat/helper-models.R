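# small builders shared across tests

toy_model_3 <- function(sep = 2, Tc = 5, J = 2) {
  matmix_model(
    pi = c(0.3, 0.3, 0.4),
    M = list(matrix(0, J, Tc), matrix(sep, J, Tc), matrix(-sep, J, Tc)),
    sigma2 = matrix(0.2, 3, J),
    Psi = c(0.5, 0.3, 0.6))
}

random_composition <- function(D) {
  x <- stats::rexp(D) + 0.05
  x / sum(x)
}

# independent multivariate-normal log-density (no shortcuts shared with
# the implementation under test)
mvn_logpdf <- function(y, mu, V) {
  p <- length(y)
  r <- y - mu
  -0.5 * p * log(2 * pi) - 0.5 * determinant(V)$modulus[1] -
    0.5 * drop(r %*% solve(V, r))
}

# brute-force ARI by enumerating all observation pairs
ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  np <- n11 + n00 + n10 + n01
  exp_idx <- (n11 + n10) * (n11 + n01) / np
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# minimal complete count fixture: n genes, T time points, J experiments,
# R replicates, deterministic counts
tiny_counts <- function(n = 4, T = 3, J = 2, R = 2, seed = 7) {
  set.seed(seed)
  meta <- expand.grid(time = paste0("T", 0:(T - 1)),
                      experiment = c("WT", "Mut")[1:J],
                      replicate = 1:R, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_r%d", meta$experiment, meta$time,
                         meta$replicate)
  counts <- matrix(rpois(n * nrow(meta), 50), n, nrow(meta),
                   dimnames = list(paste0("g", 1:n), meta$sample))
  list(counts = counts,
       meta = meta[, c("sample", "experiment", "time", "replicate")])
}
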