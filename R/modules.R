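# Module discovery: column-wise z-scores of the coefficient matrix assign
# samples to modules; modules are ranked by how many positive samples they
# contain; per-module basis columns expose the characteristic features.

#' Assign samples to modules by column-wise z-scores
#'
#' Each entry of the coefficient matrix `W` is converted to the z-score of
#' its column (column mean, population standard deviation).  A sample
#' belongs to module `p` when its z-score in column `p` exceeds
#' `threshold`; memberships may overlap across modules.  Columns with zero
#' variance assign no samples: a module whose weights are constant carries
#' no enrichment signal (dead modules are routine at high orthogonality
#' penalties).
#'
#' @param W Coefficient matrix (`m x r`) or a fitted [ionmf] model.
#' @param threshold z-score cutoff; the default 1.96 marks samples in the
#'   upper ~2.5% tail of a column.
#' @param subset Optional row indices (or logical mask) of the designated
#'   samples over which per-module counts are taken -- typically the
#'   positive class.  Defaults to all rows.
#' @return An object of class `"module_assignment"`: list with `membership`
#'   (`m x r` logical), `counts` (per-module sample counts over `subset`),
#'   `threshold` and `subset`.
#' @examples
#' W <- cbind(a = c(1, 1, 1, 10), b = c(5, 0, 0, 0))
#' assign_modules(W)$membership
#' @export
assign_modules <- function(W, threshold = 1.96, subset = NULL) {
  if (inherits(W, "ionmf")) W <- W$W
  W <- as.matrix(W)
  if (ncol(W) < 1L) stop_input("W must have at least one column")
  if (any(W < 0)) stop_input("W must be non-negative")
  m <- nrow(W)
  if (is.null(subset)) subset <- seq_len(m)
  if (is.logical(subset)) subset <- which(subset)
  mu <- colMeans(W)
  sigma <- sqrt(colMeans(sweep(W, 2L, mu)^2))  # population SD
  z <- sweep(sweep(W, 2L, mu), 2L, ifelse(sigma > 0, sigma, Inf), "/")
  membership <- z > threshold
  dimnames(membership) <- dimnames(W)
  counts <- colSums(membership[subset, , drop = FALSE])
  structure(list(membership = membership, counts = as.integer(counts),
                 threshold = threshold, subset = subset),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d samples x %d modules (z > %g)\n",
              nrow(x$membership), ncol(x$membership), x$threshold))
  cat("  counts over designated samples:",
      paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Rank modules by positive-sample counts
#'
#' Orders modules by descending count `C_r` of designated samples assigned
#' to them; ties are broken by ascending module index.  When `labels` is
#' supplied, counts are recomputed over the positive-labelled samples,
#' which is the ranking used to surface the modules that describe
#' crosslinked sites.
#'
#' @param assignment A [assign_modules()] result.
#' @param labels Optional binary label vector aligned with the rows of `W`;
#'   counts are then taken over `labels == 1`.
#' @return Integer permutation of `1:r` (most populated module first).
#' @examples
#' a <- list(membership = NULL, counts = c(5L, 9L, 2L))
#' class(a) <- "module_assignment"
#' rank_modules(a)  # 2 1 3
#' @export
rank_modules <- function(assignment, labels = NULL) {
  if (!inherits(assignment, "module_assignment"))
    stop_input("'assignment' must come from assign_modules()")
  counts <- assignment$counts
  if (!is.null(labels)) {
    if (length(labels) != nrow(assignment$membership))
      stop_input("labels length %d does not match %d samples",
                 length(labels), nrow(assignment$membership))
    counts <- colSums(assignment$membership[as.logical(labels), ,
                                            drop = FALSE])
  }
  order(-counts, seq_along(counts))
}

#' Per-module feature profile
#'
#' Extracts column `module` of every basis matrix `H_i`: the characteristic
#' feature weights of that module in each data source.  Positional labels
#' are split back into `(feature, offset)` pairs for display.
#'
#' @param model A fitted [ionmf] model.
#' @param module Module index in `1:rank`.
#' @return An object of class `"module_profile"`: list with `module` and
#'   `profiles`, a named list (per source) of data frames with columns
#'   `label`, `feature`, `offset`, `weight`.
#' @export
module_profile <- function(model, module) {
  if (!inherits(model, "ionmf")) stop_input("'model' must be an ionmf model")
  if (module < 1L || module > model$rank)
    stop_input("module index %d outside 1..%d", module, model$rank)
  profiles <- lapply(names(model$H), function(nm) {
    H <- model$H[[nm]]
    labels <- rownames(H) %||% paste0("f", seq_len(nrow(H)))
    out <- parse_feature_labels(labels)
    out$weight <- H[, module]
    out
  })
  names(profiles) <- names(model$H)
  structure(list(module = module, profiles = profiles),
            class = "module_profile")
}

#' @export
print.module_profile <- function(x, n = 5, ...) {
  cat(sprintf("<module_profile> module %d\n", x$module))
  for (nm in names(x$profiles)) {
    p <- x$profiles[[nm]]
    top <- head(p[order(-p$weight), ], n)
    cat(sprintf("  %s top features: %s\n", nm,
                paste(sprintf("%s (%.3g)", top$label, top$weight),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Hoyer sparseness of a vector
#'
#' `(sqrt(n) - ||v||_1 / ||v||_2) / (sqrt(n) - 1)`: 0 for a constant
#' vector, 1 for a one-hot vector, monotone in how peaked the vector is,
#' and invariant to positive rescaling.
#'
#' @param v Numeric vector, length >= 2, not all zero.
#' @return Sparseness in `[0, 1]`.
#' @examples
#' hoyer_sparseness(c(0, 0, 0, 1))  # 1
#' hoyer_sparseness(c(1, 1, 1, 1))  # 0
#' @export
hoyer_sparseness <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  if (n < 2L) stop_input("sparseness needs a vector of length >= 2")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stop_input("sparseness of the zero vector is undefined")
  (sqrt(n) - sum(abs(v)) / l2) / (sqrt(n) - 1)
}

#' Mean pairwise angle between basis columns
#'
#' Mean over all column pairs of `acos(cosine similarity)` in degrees.
#' For non-negative columns the angle lies in `[0, 90]`; values near 90
#' indicate an orthogonal (non-overlapping) basis.
#'
#' @param H Numeric matrix with at least two columns and no zero column.
#' @return Mean pairwise angle in degrees.
#' @examples
#' mean_pairwise_angle(diag(2))            # 90
#' mean_pairwise_angle(cbind(c(1, 0), c(1, 1)))  # 45
#' @export
mean_pairwise_angle <- function(H) {
  H <- as.matrix(H)
  if (ncol(H) < 2L) stop_input("need at least two columns")
  nrm <- sqrt(colSums(H^2))
  if (any(nrm == 0)) stop_input("zero columns have no direction")
  G <- crossprod(sweep(H, 2L, nrm, "/"))
  G <- pmin(pmax(G, -1), 1)
  mean(acos(G[upper.tri(G)])) * 180 / pi
}

#' Summarize a fitted model's modules
#'
#' One row per module: positive-sample count `C_r`, membership count over
#' all samples, and Hoyer sparseness of each source's basis column;
#' modules are ordered as by [rank_modules()].  The attribute `"angles"`
#' carries the mean pairwise basis angle per source.
#'
#' @param model A fitted [ionmf] model.
#' @param labels Optional binary labels marking positive samples.
#' @param threshold z-score cutoff passed to [assign_modules()].
#' @return A data frame of module diagnostics.
#' @export
module_summary <- function(model, labels = NULL, threshold = 1.96) {
  asg <- assign_modules(model$W, threshold = threshold,
                        subset = if (!is.null(labels)) as.logical(labels))
  ord <- rank_modules(asg, labels)
  sp <- sapply(names(model$H), function(nm)
    apply(model$H[[nm]], 2L, function(col)
      if (all(col == 0)) NA_real_ else hoyer_sparseness(col)))
  if (is.null(dim(sp))) sp <- matrix(sp, nrow = 1L,
                                     dimnames = list(NULL, names(model$H)))
  out <- data.frame(module = ord,
                    count = asg$counts[ord],
                    members_all = colSums(asg$membership)[ord])
  for (nm in names(model$H))
    out[[paste0("sparseness_", nm)]] <- sp[ord, nm]
  attr(out, "angles") <- vapply(model$H, function(H) {
    if (ncol(H) < 2L || any(colSums(H^2) == 0)) NA_real_
    else mean_pairwise_angle(H)
  }, 0)
  out
}
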