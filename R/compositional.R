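#' Log-ratio transforms for compositional data
#'
#' A composition is a vector of `D` strictly positive parts carrying only
#' relative information; it lives on the simplex of vectors with a fixed
#' total `total` (kappa, 1 by default). `alr()` maps it to `D - 1`
#' unconstrained log ratios against a reference part, `clr()` to `D`
#' rank-deficient coordinates against the geometric mean, and `ilr()` to
#' `D - 1` orthonormal (pivot) coordinates that preserve Aitchison
#' distances. All three are scale invariant: multiplying the parts by any
#' positive constant does not change the coordinates.
#'
#' @param x numeric vector of strictly positive parts.
#' @param ref index of the reference part (dropped from the output).
#'   Time-course profiles use the first time point T0 as reference, hence
#'   the default 1, although the textbook formulation uses the last part.
#' @return `alr()` and `ilr()` return a numeric vector of length `D - 1`;
#'   `clr()` returns a vector of length `D` summing to zero.
#' @examples
#' alr(c(0.2, 0.3, 0.5), ref = 3)
#' alr_inv(c(log(2), log(3)), ref = 1)
#' @export
alr <- function(x, ref = 1L) {
  check_parts(x)
  ref <- check_ref(ref, length(x))
  log(x[-ref] / x[ref])
}

#' Inverse additive log-ratio transform
#'
#' Reinserts the reference part and maps log-ratio coordinates back to the
#' simplex. Computed with max-subtraction so that coordinates of any
#' magnitude are handled without overflow.
#'
#' @param z numeric vector of `D - 1` finite log-ratio coordinates.
#' @param ref index at which the reference part is reinserted.
#' @param total the simplex constant kappa the output should sum to.
#' @return composition of length `length(z) + 1` summing to `total`.
#' @export
alr_inv <- function(z, ref = 1L, total = 1) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z)))
    stop("log-ratio coordinates must be finite numbers")
  D <- length(z) + 1L
  ref <- check_ref(ref, D)
  lx <- numeric(D)
  lx[-ref] <- z
  lx <- lx - max(lx)
  p <- exp(lx)
  total * p / sum(p)
}

#' @rdname alr
#' @export
clr <- function(x) {
  check_parts(x)
  lx <- log(x)
  lx - mean(lx)
}

#' @rdname alr
#' @export
ilr <- function(x) {
  check_parts(x)
  drop(clr(x) %*% t(pivot_basis(length(x))))
}

#' Pivot-coordinate contrast basis
#'
#' Orthonormal basis of the clr hyperplane used by [ilr()]. Row `l`
#' contrasts part `l` against the geometric mean of the later parts:
#' `z_l = sqrt((D-l)/(D-l+1)) * ln(x_l / gmean(x_(l+1):x_D))`.
#'
#' @param D number of parts.
#' @return a `(D-1) x D` matrix `V` with `V %*% t(V) = I` and zero row sums.
#' @export
pivot_basis <- function(D) {
  stopifnot(D >= 2)
  V <- matrix(0, D - 1L, D)
  for (l in seq_len(D - 1L)) {
    m <- D - l
    V[l, l] <- sqrt(m / (m + 1))
    V[l, (l + 1L):D] <- -sqrt(m / (m + 1)) / m
  }
  V
}

#' Replace zeros by an additive pseudo-count
#'
#' Adds `const` to every part and renormalises to `total`, the usual
#' rounded-zero treatment before a log-ratio transform. An all-zero input
#' becomes the uniform composition.
#'
#' @param x numeric vector of non-negative parts.
#' @param const positive constant added to every part.
#' @param total the simplex constant of the output.
#' @return strictly positive composition summing to `total`.
#' @export
zero_replace <- function(x, const = 1, total = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("parts must be non-negative numbers")
  if (!is.numeric(const) || length(const) != 1L || const <= 0)
    stop("'const' must be a single positive number")
  y <- x + const
  total * y / sum(y)
}

#' Additive log-ratio coordinates of a profile tensor
#'
#' Applies [alr()] along the time axis of a profile tensor, separately for
#' every gene and experiment, producing for each gene a J x (T-1) matrix of
#' log ratios against the reference time point (T0 by default). This is the
#' input representation for [matmix()].
#'
#' @param profiles a `profile_tensor` (gene x time x experiment array of
#'   strictly positive profiles summing to 1 over time) as returned by
#'   [average_replicates()], or any such array.
#' @param ref_time index of the reference time point, default 1 (T0).
#' @return an `alr_tensor`: a gene x experiment x (T-1) array; columns are
#'   the non-reference time points in chronological order. Attributes
#'   `ref_time` and `time_labels` record the transform.
#' @export
profiles_to_alr <- function(profiles, ref_time = 1L) {
  P <- unclass(profiles)
  stopifnot(is.array(P), length(dim(P)) == 3L)
  if (any(P <= 0))
    stop("profiles must be strictly positive; apply zero_replace() or use a ",
         "positive pseudo-count when computing profiles")
  n <- dim(P)[1L]; Tt <- dim(P)[2L]; J <- dim(P)[3L]
  ref_time <- check_ref(ref_time, Tt)
  Y <- array(NA_real_, c(n, Tt - 1L, J))
  for (j in seq_len(J))
    Y[, , j] <- log(P[, -ref_time, j]) - log(P[, ref_time, j])
  # reorder to gene x experiment x time
  Y <- aperm(Y, c(1L, 3L, 2L))
  dn <- dimnames(P)
  dimnames(Y) <- list(dn[[1L]], dn[[3L]], dn[[2L]][-ref_time])
  structure(Y, class = "alr_tensor", ref_time = ref_time,
            time_labels = dn[[2L]])
}

#' Map an alr tensor back to profiles
#'
#' Row-wise inverse of [profiles_to_alr()]; used to express fitted cluster
#' centres in the original profile space.
#'
#' @param Y gene x experiment x (T-1) array of alr coordinates.
#' @param ref_time index where the reference time point is reinserted.
#' @return gene x time x experiment array of profiles summing to 1.
#' @export
alr_to_profiles <- function(Y, ref_time = attr(Y, "ref_time") %||% 1L) {
  Y <- unclass(Y)
  stopifnot(is.array(Y), length(dim(Y)) == 3L)
  n <- dim(Y)[1L]; J <- dim(Y)[2L]; Tc <- dim(Y)[3L]
  P <- array(NA_real_, c(n, Tc + 1L, J))
  for (i in seq_len(n))
    for (j in seq_len(J))
      P[i, , j] <- alr_inv(Y[i, j, ], ref = ref_time)
  dn <- dimnames(Y)
  dimnames(P) <- list(dn[[1L]], NULL, dn[[2L]])
  structure(P, class = "profile_tensor")
}

check_parts <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x))
    stop("a composition needs at least two numeric parts")
  if (any(x < 1e-300))
    stop("all parts must be strictly positive (>= 1e-300); ",
         "use zero_replace() for rounded zeros")
  invisible(x)
}

check_ref <- function(ref, D) {
  ref <- as.integer(ref)
  if (length(ref) != 1L || is.na(ref) || ref < 1L || ref > D)
    stop("reference index must be in 1..", D)
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a
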