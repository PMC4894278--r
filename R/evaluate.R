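# Cross-validated estimation of data-source importance and the end-to-end
# pipeline driver used by the command-line interface.

#' Enumerate non-empty subsets of source names
#'
#' @param names Character vector of source names.
#' @return List of character vectors, ordered by subset size then
#'   lexicographically; `2^n - 1` elements.
#' @export
source_subsets <- function(names) {
  stopifnot(length(names) >= 1L)
  names <- sort(names, method = "radix")
  out <- list()
  for (size in seq_along(names)) {
    cmb <- utils::combn(names, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Rank matched so that r * (m + sum n_i) is approximately constant across
# subsets, relative to using `rank` on the full source set.
.matched_rank <- function(rank, m, n_all, n_subset) {
  max(1L, as.integer(round(rank * (m + sum(n_all)) / (m + sum(n_subset)))))
}

#' Estimate the predictive value of data-source subsets
#'
#' For each requested subset of sources, fits the factor model under
#' k-fold cross-validation (folds stratified by class) and scores the
#' held-out fold by AUC.  To compare subsets fairly, the factorization
#' rank of each subset is scaled so the total parameter count
#' `r * (m + sum_i n_i)` approximately matches that of the full source set
#' at the reference rank.
#'
#' @param sources Named list of [data_source] objects.
#' @param target Binary target vector.
#' @param subsets List of source-name vectors; defaults to all non-empty
#'   subsets.
#' @param folds Number of cross-validation folds (default 3).
#' @param rank Reference rank for the full subset.
#' @param alpha Orthogonality trade-off used for every fit.
#' @param seed Integer seed controlling folds and fits.
#' @param ... Passed on to [ionmf()].
#' @return Data frame with one row per subset: `subset`, `rank`,
#'   `mean_auc`, `se`.
#' @export
evaluate_subsets <- function(sources, target, subsets = NULL, folds = 3,
                             rank = 10, alpha = 1, seed = 1, ...) {
  sources <- as_data_sources(sources)
  m <- nrow(sources[[1L]]$values)
  target <- check_target(target, m, require_nonzero = TRUE)
  if (folds < 2L) stop_input("need at least 2 folds")
  if (is.null(subsets)) subsets <- source_subsets(names(sources))
  n_all <- vapply(sources, function(s) ncol(s$values), 0L)

  # class-stratified fold assignment
  set.seed(seed)
  fold <- integer(m)
  for (cls in unique(target)) {
    idx <- sample(which(target == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }

  rows <- list()
  for (sub in subsets) {
    sub <- sort(unique(sub), method = "radix")
    missing <- setdiff(sub, names(sources))
    if (length(missing))
      stop_input("unknown source(s): %s", paste(missing, collapse = ", "))
    n_sub <- n_all[sub]
    if (sum(n_sub) == 0L) {
      warning(sprintf("subset %s has no features; skipped",
                      paste(sub, collapse = "+")))
      next
    }
    r_sub <- .matched_rank(rank, m, n_all, n_sub)
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      src_tr <- lapply(sources[sub], function(s)
        data_source(s$values[tr, , drop = FALSE], s$name, s$feature_labels))
      src_te <- lapply(sources[sub], function(s)
        data_source(s$values[!tr, , drop = FALSE], s$name,
                    s$feature_labels))
      fit <- ionmf(src_tr, target[tr], rank = r_sub, alpha = alpha,
                   seed = seed + 13L * f, ...)
      proj <- ionmf_project(fit, src_te)
      aucs[f] <- auc_score(proj$Y_hat, target[!tr] > 0)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(subset = paste(sub, collapse = "+"), rank = r_sub,
                 mean_auc = mean(aucs), se = sd(aucs) / sqrt(folds),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# -- pipeline ------------------------------------------------------------

read_config <- function(path) {
  if (!file.exists(path)) stop_input("no such config file: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")))
  names(out) <- vapply(kv, function(p) trimws(p[[1L]]), "")
  # coerce obvious numerics/logicals
  lapply(out, function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
}

.pipeline_defaults <- function() {
  list(rank = 10, alpha = 1, alpha_grid = NULL, max_iter = 100, tol = 1e-6,
       n_restarts = 3, seed = 1, k = 4, window = 50, test_fraction = 1 / 3,
       cap_positives = 10000, pool_cap = 100000, n_negatives = 40000,
       min_distance = 15, threshold = 1.96, top_n_motifs = 10,
       evaluate = FALSE, out_dir = "ionmf_run")
}

#' Run the crosslink-site modelling pipeline end to end
#'
#' Reads genomic inputs (or simulates a planted dataset), samples and
#' splits sites, builds the feature matrices, fits the factor model,
#' scores the held-out split, summarizes modules and motifs, and writes
#' all artifacts plus a JSON run manifest (package version, seed, resolved
#' configuration, input checksums) into `out_dir`.  Given the same
#' configuration and seed, the run is deterministic: manifests of two runs
#' differ only in their timestamp.
#'
#' Configuration keys (defaults in parentheses): `simulate` (FALSE) to use
#' the planted simulator instead of genomic inputs; input paths `sites`,
#' `genome`, `gtf`, `other_sites`, `structure`, `go`; model settings
#' `rank` (10), `alpha` (1), `alpha_grid` (unset; comma-separated values
#' switch on internal selection), `max_iter` (100), `tol` (1e-6),
#' `n_restarts` (3), `seed` (1); featurization `k` (4), `window` (50),
#' `min_distance` (15), `cap_positives` (10000), `pool_cap` (100000),
#' `n_negatives` (40000); `test_fraction` (1/3), `threshold` (1.96),
#' `top_n_motifs` (10), `evaluate` (FALSE), `out_dir`.
#'
#' @param config Named list or path to a `key=value` file.
#' @return Invisibly, a list with the fitted `model`, the `sites` table,
#'   the test `auc` and the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- modifyList(.pipeline_defaults(), config)
  simulate <- isTRUE(cfg$simulate)

  input_keys <- c("sites", "genome", "gtf", "other_sites", "structure", "go")
  inputs <- cfg[intersect(input_keys, names(cfg))]
  if (!simulate) {
    if (is.null(cfg$sites) || is.null(cfg$genome))
      stop_input("config must provide 'sites' and 'genome' (or simulate=TRUE)")
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing))
      stop_input("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  window <- window_spec(cfg$window, cfg$window)
  seed <- as.integer(cfg$seed)

  if (simulate) {
    sim <- simulate_multiview(m = cfg$m %||% 1000, rank = cfg$rank,
                              seed = seed)
    m <- length(sim$target)
    set.seed(seed + 1L)
    test <- sample.int(m, round(cfg$test_fraction * m))
    take <- function(src, idx) lapply(src, function(s)
      data_source(s$values[idx, , drop = FALSE], s$name, s$feature_labels))
    src_tr <- take(sim$sources, setdiff(seq_len(m), test))
    src_te <- take(sim$sources, test)
    y_tr <- sim$target[setdiff(seq_len(m), test)]
    y_te <- sim$target[test]
    sites <- data.frame(chrom = "sim", position = seq_len(m) - 1L,
                        strand = "+", label = sim$target,
                        split = ifelse(seq_len(m) %in% test, "test",
                                       "train"))
    sites_te <- sites[sites$split == "test", ]
  } else {
    all_sites <- read_crosslink_bed(cfg$sites)
    other <- if (!is.null(cfg$other_sites))
      read_crosslink_bed(cfg$other_sites) else NULL
    ann <- if (!is.null(cfg$gtf)) read_annotation(cfg$gtf) else NULL
    gene_df <- if (!is.null(ann)) {
      g <- ann[as.character(ann$type) == "gene"]
      data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                 start = GenomicRanges::start(g) - 1L,
                 end = GenomicRanges::end(g),
                 strand = as.character(GenomicRanges::strand(g)),
                 gene_id = g$gene_id, stringsAsFactors = FALSE)
    } else NULL
    pos <- select_peak_sites(all_sites, min_distance = cfg$min_distance,
                             cap = cfg$cap_positives,
                             pool_cap = cfg$pool_cap, seed = seed)
    if (is.null(gene_df))
      stop_input("config must provide 'gtf' for negative sampling")
    interacting <- rbind(all_sites, other)
    neg <- sample_negatives(gene_df, interacting, n = cfg$n_negatives,
                            seed = seed + 1L)
    pos <- assign_gene_ids(pos, gene_df)
    tab <- make_site_table(pos, neg)
    tab <- split_by_gene(tab, cfg$test_fraction, seed = seed + 2L)
    sources <- build_feature_matrices(
      tab, genome = cfg$genome, annotation = ann, other_sites = other,
      structure_track = cfg$structure, gene_terms = cfg$go, k = cfg$k,
      window = window)
    tr <- tab$split == "train"
    if (!any(tab$label[tr] == 1) || !any(tab$label[!tr] == 1))
      stop_input("train/test split left a split without positive sites")
    take <- function(idx) lapply(sources, function(s)
      data_source(s$values[idx, , drop = FALSE], s$name, s$feature_labels))
    src_tr <- take(which(tr))
    src_te <- take(which(!tr))
    y_tr <- tab$label[tr]
    y_te <- tab$label[!tr]
    sites <- tab
    sites_te <- tab[!tr, ]
  }

  alpha <- cfg$alpha
  sel <- NULL
  if (!is.null(cfg$alpha_grid)) {
    grid <- as.numeric(strsplit(as.character(cfg$alpha_grid), ",")[[1L]])
    sel <- select_alpha(src_tr, y_tr, grid = grid, rank = cfg$rank,
                        seed = seed, max_iter = cfg$max_iter,
                        n_restarts = 1)
    alpha <- sel$alpha
  }
  model <- ionmf(src_tr, y_tr, rank = cfg$rank, alpha = alpha,
                 max_iter = cfg$max_iter, tol = cfg$tol,
                 n_restarts = cfg$n_restarts, seed = seed)
  proj <- ionmf_project(model, src_te)
  auc <- if (length(unique(y_te > 0)) == 2L)
    auc_score(proj$Y_hat, y_te > 0) else NA_real_

  paths <- list(model = file.path(cfg$out_dir, "model"),
                predictions = file.path(cfg$out_dir, "predictions.tsv"),
                modules = file.path(cfg$out_dir, "module_summary.tsv"),
                motifs = file.path(cfg$out_dir, "motifs.tsv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  write_model(model, paths$model)
  write_predictions(sites_te, proj$Y_hat, paths$predictions)

  summ <- module_summary(model, labels = y_tr, threshold = cfg$threshold)
  write.table(summ, paths$modules, sep = "\t", quote = FALSE,
              row.names = FALSE)

  motif_tab <- NULL
  if (!is.null(model$H$KMER)) {
    ord <- rank_modules(assign_modules(model$W, cfg$threshold,
                                       subset = y_tr > 0))
    top_mod <- ord[1L]
    motifs <- assemble_motifs(head(kmer_weights(model, top_mod), 200L),
                              top_n = cfg$top_n_motifs)
    if (length(motifs))
      motif_tab <- data.frame(
        module = top_mod,
        consensus = vapply(motifs, `[[`, "", "consensus"),
        offset = vapply(motifs, `[[`, 0, "start_offset"),
        score = vapply(motifs, `[[`, 0, "score"))
  }
  if (!is.null(motif_tab))
    write.table(motif_tab, paths$motifs, sep = "\t", quote = FALSE,
                row.names = FALSE)

  eval_tab <- NULL
  if (isTRUE(cfg$evaluate)) {
    eval_tab <- evaluate_subsets(src_tr, y_tr, rank = cfg$rank,
                                 alpha = alpha, seed = seed,
                                 max_iter = cfg$max_iter, n_restarts = 1)
    paths$evaluation <- file.path(cfg$out_dir, "evaluation.tsv")
    write.table(eval_tab, paths$evaluation, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  checksums <- if (!simulate)
    as.list(tools::md5sum(unlist(inputs))) else list()
  manifest <- list(
    package = "ionmf",
    version = as.character(utils::packageVersion("ionmf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg[order(names(cfg))],
    alpha_used = alpha,
    input_checksums = checksums,
    test_auc = auc)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(model = model, sites = sites, auc = auc, paths = paths,
                 alpha_selection = sel, evaluation = eval_tab))
}
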