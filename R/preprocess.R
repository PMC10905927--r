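#' Assemble a count tensor from a count matrix and sample metadata
#'
#' Organises a genes x samples matrix of raw read counts into a four-way
#' array indexed by gene, time point, experiment and replicate, using a
#' metadata table that assigns each sample column an experiment label, a
#' time point and a replicate index. Time points are sorted; the smallest
#' becomes the reference T0.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param meta data frame with columns `sample`, `experiment`, `time`,
#'   `replicate`; `sample` must match the column names of `counts`, and the
#'   design must be complete (every time x experiment x replicate cell
#'   observed exactly once).
#' @return a `count_tensor`: gene x time x experiment x replicate array
#'   with dimnames, plus attribute `meta`.
#' @export
count_tensor <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  need <- c("sample", "experiment", "time", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(colnames(counts)))
    stop("count matrix needs sample column names")
  if (!setequal(colnames(counts), meta$sample) ||
      anyDuplicated(meta$sample))
    stop("metadata samples must match count columns one-to-one")
  times <- sort(unique(meta$time))
  exps <- unique(meta$experiment)
  reps <- sort(unique(meta$replicate))
  n <- nrow(counts)
  X <- array(NA_real_, c(n, length(times), length(exps), length(reps)),
             dimnames = list(rownames(counts), as.character(times),
                             as.character(exps), as.character(reps)))
  for (s in seq_len(nrow(meta))) {
    ti <- match(meta$time[s], times)
    ji <- match(meta$experiment[s], exps)
    ri <- match(meta$replicate[s], reps)
    if (!all(is.na(X[, ti, ji, ri])))
      stop("duplicate sample for time ", meta$time[s], ", experiment ",
           meta$experiment[s], ", replicate ", meta$replicate[s])
    X[, ti, ji, ri] <- counts[, meta$sample[s]]
  }
  if (anyNA(X))
    stop("incomplete design: every time x experiment x replicate cell ",
         "needs exactly one sample")
  structure(X, class = "count_tensor", meta = meta)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors correcting for sequencing depth: the factor
#' for a sample is the median, over genes with strictly positive counts in
#' all samples, of that sample's count divided by the gene's across-sample
#' geometric mean. Factors are rescaled to have geometric mean exactly 1,
#' so that relative depths, not absolute ones, are encoded.
#'
#' @param counts non-negative genes x samples matrix (at least one gene
#'   must be positive in every sample).
#' @return named positive vector, one factor per sample, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative")
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(which(colSums(counts) == 0), collapse = ", "))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has strictly positive counts in every sample; ",
         "median-of-ratios size factors are undefined")
  lg <- rowMeans(log(counts[pos, , drop = FALSE]))
  s <- apply(counts[pos, , drop = FALSE], 2L,
             function(col) exp(stats::median(log(col) - lg)))
  s <- s / exp(mean(log(s)))
  s
}

#' Normalised expression profiles
#'
#' For every gene, experiment and replicate, divides the counts by the
#' sample size factors and converts the time course to proportions:
#' `p_t = (x_t/s_t + c) / (sum_t x_t/s_t + c * T)`. Each profile is a
#' strictly positive vector over the T time points summing to 1 — the
#' compositional representation that later feeds the log-ratio transform.
#' The pseudo-count `c` guards against zeros; a gene with no reads at all
#' in an experiment gets the uniform profile.
#'
#' @param x a `count_tensor`.
#' @param size_factors named vector of per-sample size factors as returned
#'   by [estimate_size_factors()], or `NULL` to estimate them from `x`.
#' @param pseudo the constant `c`: a positive number (default 1), or
#'   `"half-min"` for half the smallest positive size-factor-corrected
#'   count. `pseudo = 0` is allowed only when all counts are positive.
#' @return gene x time x experiment x replicate array of class
#'   `profile_tensor_reps` with attribute `pseudo`.
#' @export
normalized_profiles <- function(x, size_factors = NULL, pseudo = 1) {
  stopifnot(inherits(x, "count_tensor"))
  meta <- attr(x, "meta")
  d <- dim(x)
  if (is.null(size_factors)) {
    cm <- count_matrix(x)
    size_factors <- estimate_size_factors(cm)
  }
  # size factor array indexed like (time, experiment, replicate)
  s <- array(NA_real_, d[2:4])
  tl <- dimnames(x)[[2L]]; el <- dimnames(x)[[3L]]; rl <- dimnames(x)[[4L]]
  for (k in seq_len(nrow(meta))) {
    s[match(as.character(meta$time[k]), tl),
      match(as.character(meta$experiment[k]), el),
      match(as.character(meta$replicate[k]), rl)] <-
      size_factors[[meta$sample[k]]]
  }
  if (anyNA(s)) stop("size factors do not cover every sample")
  xs <- sweep(unclass(x), 2:4, s, `/`)
  if (identical(pseudo, "half-min")) {
    posv <- xs[xs > 0]
    if (!length(posv)) stop("all counts are zero; cannot set 'half-min'")
    pseudo <- min(posv) / 2
  }
  if (!is.numeric(pseudo) || length(pseudo) != 1L || pseudo < 0)
    stop("'pseudo' must be a single non-negative number or \"half-min\"")
  Tt <- d[2L]
  tot <- apply(xs, c(1L, 3L, 4L), sum)   # gene x exp x rep
  if (pseudo == 0 && any(tot == 0)) {
    bad <- which(tot == 0, arr.ind = TRUE)[1L, ]
    stop("gene ", dimnames(x)[[1L]][bad[1L]], " has zero counts in ",
         "experiment ", el[bad[2L]], " (replicate ", rl[bad[3L]],
         "); a positive pseudo-count is required")
  }
  P <- array(NA_real_, d, dimnames = dimnames(x))
  for (t in seq_len(Tt))
    P[, t, , ] <- (xs[, t, , ] + pseudo) / (tot + pseudo * Tt)
  structure(P, class = "profile_tensor_reps", pseudo = pseudo)
}

#' Average profiles over biological replicates
#'
#' Entrywise arithmetic mean over the replicate axis; means of unit-sum
#' vectors still sum to 1, so the result is again a valid profile tensor.
#'
#' @param p a `profile_tensor_reps` (gene x time x experiment x replicate),
#'   or a list of gene x time x experiment arrays with identical dimnames.
#' @return `profile_tensor`: gene x time x experiment array.
#' @export
average_replicates <- function(p) {
  if (is.list(p)) {
    d <- dim(p[[1L]])
    if (!all(vapply(p, function(a) identical(dim(a), d), logical(1))))
      stop("replicate arrays differ in shape")
    P <- Reduce(`+`, lapply(p, unclass)) / length(p)
    dimnames(P) <- dimnames(p[[1L]])
  } else {
    stopifnot(is.array(p), length(dim(p)) == 4L)
    pseudo <- attr(p, "pseudo")
    P <- apply(unclass(p), 1:3, mean)
    dimnames(P) <- dimnames(p)[1:3]
  }
  structure(P, class = "profile_tensor",
            pseudo = attr(p, "pseudo") %||% attr(p[[1L]], "pseudo"))
}

#' Keep a subset of genes
#'
#' Restricts a profile tensor to a set of gene identifiers, typically the
#' differentially expressed genes from an external analysis. Original gene
#' order is preserved; identifiers not present are reported with a warning.
#'
#' @param p a `profile_tensor` (or `profile_tensor_reps`).
#' @param keep character vector of gene ids to retain.
#' @return tensor of the same class with the matching genes only.
#' @export
filter_genes <- function(p, keep) {
  ids <- dimnames(p)[[1L]]
  unknown <- setdiff(keep, ids)
  if (length(unknown))
    warning("ignoring ", length(unknown), " unknown gene id(s): ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
  sel <- ids %in% keep
  if (!any(sel))
    stop("no gene of 'keep' is present in the tensor")
  cl <- class(p); ats <- attributes(p)
  q <- if (length(dim(p)) == 4L) unclass(p)[sel, , , , drop = FALSE]
       else unclass(p)[sel, , , drop = FALSE]
  attr(q, "pseudo") <- ats$pseudo
  class(q) <- cl
  q
}

#' Flatten a count tensor back to a genes x samples matrix
#'
#' @param x a `count_tensor`.
#' @return the original count matrix, columns named as in the metadata.
#' @export
count_matrix <- function(x) {
  stopifnot(inherits(x, "count_tensor"))
  meta <- attr(x, "meta")
  tl <- dimnames(x)[[2L]]; el <- dimnames(x)[[3L]]; rl <- dimnames(x)[[4L]]
  cm <- sapply(seq_len(nrow(meta)), function(k)
    unclass(x)[, match(as.character(meta$time[k]), tl),
               match(as.character(meta$experiment[k]), el),
               match(as.character(meta$replicate[k]), rl)])
  colnames(cm) <- meta$sample
  rownames(cm) <- dimnames(x)[[1L]]
  cm
}
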