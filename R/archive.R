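# Plain-text model and feature archives: a directory of full-precision
# TSV matrices plus a JSON metadata file.  "%.17g" formatting makes the
# round trip lossless for doubles.

write_matrix_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(colnames(x)))
    writeLines(paste(c("#labels", colnames(x)), collapse = "\t"), con)
  rn <- rownames(x) %||% rep("", nrow(x))
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rn[i], sprintf("%.17g", x[i, ])), collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  labels <- NULL
  if (length(lines) && startsWith(lines[1L], "#labels")) {
    labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rn <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  x <- do.call(rbind, vals)
  if (is.null(x)) x <- matrix(numeric(0), 0L, length(labels %||% 0))
  if (!is.null(labels)) colnames(x) <- labels
  if (any(nzchar(rn))) rownames(x) <- rn
  x
}

#' Save a fitted model as a plain-text archive
#'
#' Writes `W`, every `H_i` (with its feature labels), `H_Y`, the objective
#' trace and a JSON metadata file (`rank`, `alpha`, `seed`, source names,
#' convergence report) into a directory.  The archive is plain text and
#' round-trips losslessly through [read_model()].
#'
#' @param model A fitted [ionmf] model.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  if (!inherits(model, "ionmf")) stop_input("'model' must be an ionmf model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(model$W, file.path(dir, "W.tsv"))
  for (nm in names(model$H)) {
    H <- model$H[[nm]]
    rownames(H) <- model$feature_labels[[nm]] %||% rownames(H)
    write_matrix_tsv(H, file.path(dir, paste0("H_", nm, ".tsv")))
  }
  if (!is.null(model$H_Y))
    write_matrix_tsv(model$H_Y, file.path(dir, "H_Y.tsv"))
  meta <- list(rank = model$rank, alpha = model$alpha, eps = model$eps,
               seed = model$seed, sources = names(model$H),
               criterion = model$criterion, tol = model$tol,
               source_scale = as.list(model$source_scale %||%
                                        setNames(rep(1, length(model$H)),
                                                 names(model$H))),
               has_target = !is.null(model$H_Y))
  if (!is.null(model$report)) {
    meta$report <- model$report[c("iterations_run", "chosen_restart",
                                  "n_restarts", "converged", "final_delta")]
    write_matrix_tsv(as.matrix(model$report$objective_trace),
                     file.path(dir, "trace.tsv"))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model archive written by [write_model()]
#'
#' @param dir Archive directory.
#' @return An [ionmf] model.
#' @export
read_model <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_input("no model archive at %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  W <- read_matrix_tsv(file.path(dir, "W.tsv"))
  H <- lapply(meta$sources, function(nm)
    read_matrix_tsv(file.path(dir, paste0("H_", nm, ".tsv"))))
  names(H) <- meta$sources
  H_Y <- if (isTRUE(meta$has_target))
    read_matrix_tsv(file.path(dir, "H_Y.tsv")) else NULL
  model <- ionmf_model(W, H, H_Y, alpha = as.numeric(meta$alpha),
                       eps = as.numeric(meta$eps),
                       seed = if (is.null(meta$seed)) NA
                              else as.integer(meta$seed))
  model$criterion <- meta$criterion
  model$tol <- if (!is.null(meta$tol)) as.numeric(meta$tol)
  model$source_scale <- unlist(meta$source_scale)
  if (!is.null(meta$report)) {
    model$report <- meta$report
    for (fld in c("iterations_run", "chosen_restart", "n_restarts"))
      model$report[[fld]] <- as.integer(model$report[[fld]])
    model$report$final_delta <- as.numeric(model$report$final_delta)
    trace_path <- file.path(dir, "trace.tsv")
    if (file.exists(trace_path))
      model$report$objective_trace <-
        as.data.frame(read_matrix_tsv(trace_path))
  }
  model
}

#' Save feature matrices as a plain-text archive
#'
#' One TSV per source block plus metadata; round-trips through
#' [read_sources()].
#'
#' @param sources Named list of [data_source] objects.
#' @param dir Target directory.
#' @export
write_sources <- function(sources, dir) {
  sources <- as_data_sources(sources)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sources))
    write_matrix_tsv(sources[[nm]]$values,
                     file.path(dir, paste0("X_", nm, ".tsv")))
  jsonlite::write_json(list(sources = names(sources)),
                       file.path(dir, "sources.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a feature archive written by [write_sources()]
#'
#' @param dir Archive directory.
#' @return Named list of [data_source] objects.
#' @export
read_sources <- function(dir) {
  meta_path <- file.path(dir, "sources.json")
  if (!file.exists(meta_path)) stop_input("no feature archive at %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  out <- lapply(meta$sources, function(nm) {
    x <- read_matrix_tsv(file.path(dir, paste0("X_", nm, ".tsv")))
    data_source(x, nm)
  })
  names(out) <- meta$sources
  out
}

#' Write prediction scores as TSV
#'
#' @param sites Site table aligned with the scores.
#' @param scores Numeric affinity scores.
#' @param path Output path.
#' @export
write_predictions <- function(sites, scores, path) {
  if (nrow(sites) != length(scores))
    stop_input("sites and scores differ in length")
  out <- data.frame(chrom = sites$chrom, position = sites$position,
                    strand = sites$strand, score = scores)
  out <- out[order(out$chrom, out$position, out$strand), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
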