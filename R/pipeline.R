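# End-to-end drivers mirroring the four workflow steps: preprocess,
# cluster, evaluate, simulate. Each takes a run_config(), writes its
# artifacts plus a YAML snapshot of the config into the output directory,
# and is deterministic under a fixed config and seed. A thin command-line
# wrapper lives at inst/cli/threewayclust.R.

#' Assemble a pipeline run configuration
#'
#' All fields have documented defaults; a YAML snapshot is written to the
#' output directory by every `run_*()` step so a run can be reproduced
#' from its outputs alone.
#'
#' @param counts,metadata,gene_list,out_dir file paths (the gene list —
#'   one id per line, e.g. externally determined differentially expressed
#'   genes — is optional).
#' @param pseudo pseudo-count `c` for the profiles (number or
#'   `"half-min"`).
#' @param ref_time index of the reference time point (1 = T0).
#' @param column_structure `"ar1"` (default, the workflow's choice) or
#'   `"full"`.
#' @param k_range component counts to compare.
#' @param criterion `"ICL"` or `"BIC"`.
#' @param n_starts,tol,max_iter EM controls.
#' @param seed integer seed for all randomness.
#' @param plots logical, write diagnostic figures.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts = NULL, metadata = NULL, gene_list = NULL,
                       out_dir = "threewayclust_out", pseudo = 1,
                       ref_time = 1L,
                       column_structure = c("ar1", "full"),
                       k_range = 1:15, criterion = "ICL",
                       n_starts = 10L, tol = 1e-8, max_iter = 500L,
                       seed = 1L, plots = TRUE) {
  cfg <- list(counts = counts, metadata = metadata, gene_list = gene_list,
              out_dir = out_dir, pseudo = pseudo,
              ref_time = as.integer(ref_time),
              column_structure = match.arg(column_structure),
              k_range = as.integer(k_range), criterion = criterion,
              n_starts = as.integer(n_starts), tol = tol,
              max_iter = as.integer(max_iter), seed = as.integer(seed),
              plots = isTRUE(plots))
  class(cfg) <- "run_config"
  cfg
}

snapshot_config <- function(cfg, name) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir,
                                           paste0(name, "_config.yaml")))
}

#' Read a run configuration from YAML
#' @param path YAML file as written by [snapshot_config] / by hand.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v[!vapply(v, is.null, logical(1))])
}

#' Step 1 — preprocess counts into averaged normalised profiles
#'
#' Reads the count and metadata tables, estimates median-of-ratios size
#' factors, computes normalised expression profiles per replicate,
#' averages replicates, optionally filters to the supplied gene list, and
#' writes `profiles.tsv` (long format), `size_factors.tsv` and the config
#' snapshot.
#'
#' @param cfg a [run_config()] with `counts` and `metadata` set.
#' @return the averaged `profile_tensor`, invisibly.
#' @export
run_preprocess <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  counts <- read_counts(cfg$counts)
  meta <- read_metadata(cfg$metadata)
  ct <- count_tensor(counts, meta)
  sf <- estimate_size_factors(count_matrix(ct))
  pr <- normalized_profiles(ct, size_factors = sf, pseudo = cfg$pseudo)
  P <- average_replicates(pr)
  if (!is.null(cfg$gene_list)) {
    keep <- readLines(cfg$gene_list)
    keep <- keep[nzchar(keep)]
    P <- filter_genes(P, keep)
  }
  snapshot_config(cfg, "preprocess")
  write_profiles_tsv(P, file.path(cfg$out_dir, "profiles.tsv"))
  utils::write.table(
    data.frame(sample = names(sf), size_factor = sf),
    file.path(cfg$out_dir, "size_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  message("preprocess: n = ", dim(P)[1L], " genes, T = ", dim(P)[2L],
          " time points, J = ", dim(P)[3L], " experiments, R = ",
          dim(pr)[4L], " replicates (c = ", attr(pr, "pseudo"), ")")
  invisible(P)
}

#' Step 2+3 — transform to alr coordinates and fit/select the mixture
#'
#' Reads `profiles.tsv` from the output directory, applies the alr
#' transform with the configured reference time point, runs
#' [matmix_select()] over `k_range` (for AR1: general-correlation fits
#' refined under the restriction), and writes the selected model
#' (`model.json`), the criterion table (`criteria.tsv`) and the MAP
#' assignments (`assignments.tsv`).
#'
#' @param cfg a [run_config()].
#' @return the `matmix_select` object, invisibly.
#' @export
run_cluster <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  P <- read_profiles_tsv(file.path(cfg$out_dir, "profiles.tsv"))
  Y <- profiles_to_alr(P, ref_time = cfg$ref_time)
  sel <- matmix_select(Y, cfg$k_range,
                       column_structure = cfg$column_structure,
                       criterion = cfg$criterion, seed = cfg$seed,
                       n_starts = cfg$n_starts, tol = cfg$tol,
                       max_iter = cfg$max_iter)
  snapshot_config(cfg, "cluster")
  write_matmix_json(sel$best, file.path(cfg$out_dir, "model.json"))
  utils::write.table(sel$table, file.path(cfg$out_dir, "criteria.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = dimnames(P)[[1L]], cluster = sel$best$labels,
               posterior_max = apply(sel$best$tau, 1L, max)),
    file.path(cfg$out_dir, "assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  message("cluster: selected K = ", sel$best$K, " by ", cfg$criterion,
          " (", cfg$column_structure, ")")
  invisible(sel)
}

#' Step 4 — diagnostics of the selected partition
#'
#' Recomputes posteriors of the stored model on the stored profiles,
#' writes `diagnostics.tsv` (gene, cluster, posterior_max, dbsi, scaled
#' centre distance), the dbsi information plot and the cluster map (PNG),
#' and — when `compare_labels` is supplied — the adjusted Rand index and
#' contingency table against that alternative partition.
#'
#' @param cfg a [run_config()].
#' @param compare_labels optional path to a TSV with columns `gene` and
#'   `cluster` holding an alternative partition.
#' @return list with the `dbsi` object, distances, and (optionally) `ari`
#'   and `contingency`, invisibly.
#' @export
run_evaluate <- function(cfg, compare_labels = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  model_path <- file.path(cfg$out_dir, "model.json")
  if (!file.exists(model_path))
    stop("no model.json in ", cfg$out_dir, "; run run_cluster() first")
  model <- read_matmix_json(model_path)
  P <- read_profiles_tsv(file.path(cfg$out_dir, "profiles.tsv"))
  Y <- profiles_to_alr(P, ref_time = cfg$ref_time)
  tau <- predict(model, Y)
  labels <- map_classify(tau)
  db <- dbsi(tau)
  db$labels <- labels
  cd <- center_distance(P, model, labels, ref_time = cfg$ref_time)
  snapshot_config(cfg, "evaluate")
  utils::write.table(
    data.frame(gene = dimnames(P)[[1L]], cluster = labels,
               posterior_max = apply(tau, 1L, max), dbsi = db$values,
               distance = cd$distance),
    file.path(cfg$out_dir, "diagnostics.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(dbsi = db, distance = cd$distance)
  if (cfg$plots) {
    sil <- if (model$K >= 2L) silhouette_width(Y, labels) else NULL
    grDevices::png(file.path(cfg$out_dir, "dbsi_plot.png"), 900, 500)
    plot_dbsi(db, sil)
    grDevices::dev.off()
    cm <- cluster_map_data(db, cd$distance, labels)
    grDevices::png(file.path(cfg$out_dir, "cluster_map.png"), 900, 700)
    plot_cluster_map(cm)
    grDevices::dev.off()
  }
  if (!is.null(compare_labels)) {
    alt <- utils::read.delim(compare_labels)
    alt <- alt$cluster[match(dimnames(P)[[1L]], alt$gene)]
    out$ari <- adjusted_rand(labels, alt)
    out$contingency <- cluster_contingency(labels, alt)
    utils::write.table(as.data.frame.matrix(out$contingency),
                       file.path(cfg$out_dir, "contingency.tsv"),
                       sep = "\t", quote = FALSE)
    message("evaluate: ARI against comparison partition = ",
            format(out$ari, digits = 3))
  }
  message("evaluate: overall average dbsi = ",
          format(mean(db$values), digits = 3))
  invisible(out)
}

#' Run the scaled-down simulation study and write its result tables
#'
#' @param cfg a [run_config()]; `seed`, `k_range` and `out_dir` are used.
#' @param ... overrides passed to [run_simulation_study()].
#' @return the `simstudy` object, invisibly.
#' @export
run_simulate <- function(cfg, ...) {
  stopifnot(inherits(cfg, "run_config"))
  st <- run_simulation_study(k_range = cfg$k_range, seed = cfg$seed, ...)
  snapshot_config(cfg, "simulate")
  utils::write.table(st$results, file.path(cfg$out_dir,
                                           "simulation_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(st$summary, file.path(cfg$out_dir,
                                           "simulation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(st)
}

## ---- file formats -----------------------------------------------------

#' Read a delimited count matrix (first column gene id, rest samples)
#' @param path TSV/CSV file; the delimiter is sniffed from the header.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in the count table")
  rownames(m) <- df[[1L]]
  m
}

#' Read the sample metadata table (sample, experiment, time, replicate)
#' @param path TSV/CSV file.
#' @return data frame with the four required columns.
#' @export
read_metadata <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample", "experiment", "time", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  df
}

sniff_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
}

#' Write / read profiles as long-format TSV (gene, experiment, time, value)
#' @param P a `profile_tensor`.
#' @param path output file.
#' @export
write_profiles_tsv <- function(P, path) {
  dn <- dimnames(P)
  long <- expand.grid(gene = dn[[1L]], time = dn[[2L]],
                      experiment = dn[[3L]], stringsAsFactors = FALSE)
  long$value <- as.vector(unclass(P))
  long <- long[, c("gene", "experiment", "time", "value")]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  genes <- unique(long$gene)
  times <- unique(long$time)
  exps <- unique(long$experiment)
  P <- array(NA_real_, c(length(genes), length(times), length(exps)),
             dimnames = list(genes, as.character(times),
                             as.character(exps)))
  P[cbind(match(long$gene, genes), match(long$time, times),
          match(long$experiment, exps))] <- long$value
  if (anyNA(P)) stop("profiles TSV does not cover the full ",
                     "gene x time x experiment grid")
  structure(P, class = "profile_tensor")
}

#' Serialise a fitted or constructed mixture model to JSON
#'
#' Plain-text round trip of everything needed to reuse the model:
#' dimensions, structure, sizes, means, variances, correlations (or AR1
#' parameters), seed, log-likelihood and parameter count. Posterior
#' matrices are not stored; recompute them with [predict.matmix()].
#'
#' @param model a `matmix` object.
#' @param path output JSON file.
#' @export
write_matmix_json <- function(model, path) {
  stopifnot(inherits(model, "matmix"))
  obj <- list(K = model$K, J = model$J, Tc = model$Tc,
              column_structure = model$column_structure,
              pi = model$pi,
              M = lapply(model$M, function(m) as.data.frame(unname(m))),
              sigma2 = as.data.frame(unname(model$sigma2)),
              Psi = lapply(model$Psi, function(p)
                as.data.frame(unname(p))),
              rho = model$rho, loglik = model$loglik, nu = model$nu,
              converged = model$converged, n_iter = model$n_iter,
              seed = model$seed,
              experiment_labels = model$dimnames[[2L]],
              time_labels = model$dimnames[[3L]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_matmix_json
#' @export
read_matmix_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- o$K
  M <- lapply(seq_len(K), function(k) {
    m <- as.matrix(as.data.frame(o$M[[k]]))
    dimnames(m) <- list(o$experiment_labels, o$time_labels)
    m
  })
  Psi <- lapply(seq_len(K), function(k)
    unname(as.matrix(as.data.frame(o$Psi[[k]]))))
  model <- matmix_model(pi = o$pi, M = M,
                        sigma2 = as.matrix(as.data.frame(o$sigma2)),
                        Psi = Psi)
  model$column_structure <- o$column_structure
  model$rho <- o$rho
  model$loglik <- o$loglik
  model$nu <- o$nu
  model$converged <- o$converged
  model$n_iter <- o$n_iter
  model$seed <- o$seed
  model
}
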