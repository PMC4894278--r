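# Integrative orthogonality-regularized NMF: shared coefficient matrix W,
# one basis matrix H_i per data source, optional single-column target Y with
# basis H_Y.  Objective
#   J(W, H) = sum_i ( ||X_i - W H_i^T||_F^2 + alpha ||H_i^T H_i - I||_F^2 )
#             [+ ||Y - W H_Y^T||_F^2]
# minimized by elementwise multiplicative updates.  No orthogonality penalty
# is applied to H_Y, which holds a single basis row.

# -- validation ----------------------------------------------------------

check_model_sources <- function(model, sources, target = NULL) {
  r <- model$rank
  for (nm in names(sources)) {
    if (is.null(model$H[[nm]]))
      stop_input("model has no basis matrix for source '%s' (expected: %s)",
                 nm, paste(names(model$H), collapse = ", "))
    n_model <- nrow(model$H[[nm]])
    n_data <- ncol(sources[[nm]]$values)
    if (n_model != n_data)
      stop_input("source '%s': %d feature columns but model expects %d",
                 nm, n_data, n_model)
  }
  m <- nrow(sources[[1L]]$values)
  if (nrow(model$W) != m)
    stop_input("W has %d rows but sources have %d", nrow(model$W), m)
  if (!is.null(target) && length(target) != m)
    stop_input("target length %d does not match %d sample rows",
               length(target), m)
  invisible(TRUE)
}

check_target <- function(target, m = NULL, require_nonzero = FALSE) {
  if (is.null(target)) return(NULL)
  target <- as.numeric(target)
  if (anyNA(target) || any(!is.finite(target)) || any(target < 0))
    stop_input("target values must be finite and non-negative")
  if (!is.null(m) && length(target) != m)
    stop_input("target length %d does not match %d sample rows",
               length(target), m)
  if (require_nonzero && all(target == 0))
    stop_input("target has no non-zero entries; nothing to fit against")
  target
}

# -- objective -----------------------------------------------------------

#' Evaluate the iONMF objective
#'
#' Computes the total cost of a factor model on a set of data sources:
#' the approximation term `sum_i ||X_i - W H_i'||_F^2` (plus
#' `||Y - W H_Y'||_F^2` when a target is supplied) and the orthogonality
#' term `alpha * sum_i ||H_i' H_i - I||_F^2`.  The single-column target
#' basis contributes no orthogonality penalty.
#'
#' @param model A fitted or hand-built [ionmf] model.
#' @param sources List of [data_source] objects (or matrices) matching the
#'   model's sources by name.
#' @param target Optional non-negative target vector of length `m`.
#' @return A list with elements `total`, `approx` and `ortho`;
#'   `total == approx + ortho`.
#' @examples
#' W <- matrix(1, 2, 1); H <- matrix(1, 2, 1)
#' m <- ionmf_model(W, list(A = H), alpha = 3)
#' ionmf_objective(m, list(A = matrix(1, 2, 2)))  # approx 0, ortho 3
#' @export
ionmf_objective <- function(model, sources, target = NULL) {
  sources <- as_data_sources(sources)
  target <- check_target(target, nrow(sources[[1L]]$values))
  check_model_sources(model, sources, target)
  W <- model$W
  approx <- 0
  ortho <- 0
  Ir <- diag(model$rank)
  for (nm in names(sources)) {
    H <- model$H[[nm]]
    approx <- approx + sum((sources[[nm]]$values - W %*% t(H))^2)
    ortho <- ortho + sum((crossprod(H) - Ir)^2)
  }
  ortho <- model$alpha * ortho
  if (!is.null(target))
    approx <- approx + sum((target - W %*% t(model$H_Y))^2)
  list(total = approx + ortho, approx = approx, ortho = ortho)
}

# -- multiplicative update rules (cores operate on plain matrices) -------

.step_w <- function(W, Xs, Hs, Y, HY, eps) {
  num <- 0
  den <- 0
  for (i in seq_along(Xs)) {
    num <- num + Xs[[i]] %*% Hs[[i]]
    den <- den + W %*% crossprod(Hs[[i]])
  }
  if (!is.null(Y)) {
    num <- num + Y %*% HY
    den <- den + W %*% crossprod(HY)
  }
  W * num / (den + eps)
}

.step_h <- function(H, X, W, WtW, alpha, eps) {
  num <- crossprod(X, W) + alpha * H
  den <- H %*% WtW + 2 * alpha * (H %*% crossprod(H))
  H * num / (den + eps)
}

.step_hy <- function(HY, Y, W, WtW, eps) {
  HY * crossprod(Y, W) / (HY %*% WtW + eps)
}

#' Multiplicative update of the shared coefficient matrix W
#'
#' One elementwise update
#' `W <- W * (sum_i X_i H_i + Y H_Y) / (sum_i W H_i' H_i + W H_Y' H_Y + eps)`.
#' Exact factorizations are fixed points and zero entries stay zero.
#'
#' @inheritParams ionmf_objective
#' @return The updated `m x r` matrix `W`.
#' @export
ionmf_update_w <- function(model, sources, target = NULL) {
  sources <- as_data_sources(sources)
  target <- check_target(target, nrow(sources[[1L]]$values))
  check_model_sources(model, sources, target)
  Xs <- lapply(sources, `[[`, "values")
  Hs <- model$H[names(sources)]
  Y <- if (!is.null(target)) matrix(target, ncol = 1L) else NULL
  W <- .step_w(model$W, Xs, Hs, Y, model$H_Y, model$eps)
  if (anyNA(W) || any(!is.finite(W)))
    stop_numeric("non-finite entries produced while updating W")
  W
}

#' Multiplicative update of one basis matrix H_i
#'
#' One elementwise update
#' `H <- H * (X' W + alpha H) / (H W' W + 2 alpha H H' H + eps)`.
#' With `alpha = 0` this is the classic multiplicative NMF basis update.
#'
#' @inheritParams ionmf_objective
#' @param source Name (or index) of the source whose basis is updated.
#' @return The updated `n_i x r` matrix.
#' @export
ionmf_update_h <- function(model, source, sources) {
  sources <- as_data_sources(sources)
  check_model_sources(model, sources)
  nm <- if (is.character(source)) source else names(sources)[source]
  if (is.null(sources[[nm]]))
    stop_input("unknown source '%s'", as.character(source))
  H <- .step_h(model$H[[nm]], sources[[nm]]$values, model$W,
               crossprod(model$W), model$alpha, model$eps)
  if (anyNA(H) || any(!is.finite(H)))
    stop_numeric("non-finite entries produced while updating H['%s']", nm)
  H
}

#' Multiplicative update of the target basis H_Y
#'
#' One elementwise update `H_Y <- H_Y * (Y' W) / (H_Y W' W + eps)`.  The
#' target basis is a single row (one basis weight per module) and carries no
#' orthogonality penalty.
#'
#' @inheritParams ionmf_objective
#' @return The updated `1 x r` matrix.
#' @export
ionmf_update_hy <- function(model, target) {
  target <- check_target(target, nrow(model$W))
  Y <- matrix(target, ncol = 1L)
  HY <- .step_hy(model$H_Y, Y, model$W, crossprod(model$W), model$eps)
  if (anyNA(HY) || any(!is.finite(HY)))
    stop_numeric("non-finite entries produced while updating H_Y")
  HY
}

# -- model container -----------------------------------------------------

#' Assemble an iONMF factor model from matrices
#'
#' Builds the model container used by [ionmf_objective()] and the update
#' rules; [ionmf()] returns the same structure after fitting.
#'
#' @param W Non-negative `m x r` coefficient matrix.
#' @param H Named list of non-negative `n_i x r` basis matrices.
#' @param H_Y Optional non-negative `1 x r` target basis matrix.
#' @param alpha Non-negative orthogonality trade-off.
#' @param eps Denominator stabilizer added to every update denominator.
#' @param seed Integer seed recorded with the model.
#' @return An object of class `"ionmf"`.
#' @export
ionmf_model <- function(W, H, H_Y = NULL, alpha = 1, eps = 1e-9, seed = NA) {
  W <- as.matrix(W)
  H <- lapply(H, as.matrix)
  r <- ncol(W)
  if (is.null(names(H)) || any(!nzchar(names(H))))
    stop_input("'H' must be a named list of basis matrices")
  for (nm in names(H))
    if (ncol(H[[nm]]) != r)
      stop_input("H['%s'] has %d columns; expected rank %d", nm,
                 ncol(H[[nm]]), r)
  mats <- c(list(W = W), H, if (!is.null(H_Y)) list(H_Y = H_Y))
  for (nm in names(mats))
    if (anyNA(mats[[nm]]) || any(!is.finite(mats[[nm]])) || any(mats[[nm]] < 0))
      stop_input("model matrix '%s' must be non-negative and finite", nm)
  if (!is.null(H_Y)) {
    H_Y <- matrix(as.numeric(H_Y), nrow = 1L)
    if (ncol(H_Y) != r)
      stop_input("H_Y must have one weight per module (rank %d)", r)
  }
  structure(list(W = W, H = H, H_Y = H_Y, rank = r, alpha = alpha,
                 eps = eps, seed = seed,
                 feature_labels = lapply(H, rownames),
                 report = NULL),
            class = "ionmf")
}

#' @export
print.ionmf <- function(x, ...) {
  cat(sprintf("iONMF factor model: rank %d, alpha %g\n", x$rank, x$alpha))
  cat(sprintf("  %d samples; sources: %s\n", nrow(x$W),
              paste(sprintf("%s (%d)", names(x$H),
                            vapply(x$H, nrow, 0L)), collapse = ", ")))
  if (!is.null(x$H_Y)) cat("  target basis: yes\n")
  if (!is.null(x$report))
    cat(sprintf("  fit: %d iterations, converged = %s, restart %d/%d\n",
                x$report$iterations_run, x$report$converged,
                x$report$chosen_restart, x$report$n_restarts))
  invisible(x)
}

# -- fitting -------------------------------------------------------------

# One optimization run from a single random initialization.
.ionmf_run <- function(Xs, Y, rank, alpha, max_iter, tol, eps, relative,
                       seed, verbose = FALSE) {
  m <- nrow(Xs[[1L]])
  set.seed(seed)
  W <- matrix(runif(m * rank), m, rank)
  Hs <- lapply(Xs, function(X) matrix(runif(ncol(X) * rank), ncol(X), rank))
  HY <- if (!is.null(Y)) matrix(runif(rank), 1L, rank) else NULL
  Ir <- diag(rank)

  objective <- function() {
    approx <- 0
    ortho <- 0
    for (i in seq_along(Xs)) {
      approx <- approx + sum((Xs[[i]] - W %*% t(Hs[[i]]))^2)
      ortho <- ortho + sum((crossprod(Hs[[i]]) - Ir)^2)
    }
    if (!is.null(Y)) approx <- approx + sum((Y - W %*% t(HY))^2)
    c(total = approx + alpha * ortho, approx = approx,
      ortho = alpha * ortho)
  }

  trace <- matrix(NA_real_, max_iter, 3L,
                  dimnames = list(NULL, c("total", "approx", "ortho")))
  J_prev <- objective()[["total"]]
  if (!is.finite(J_prev))
    stop_numeric("objective is non-finite at initialization (seed %d)", seed)
  converged <- FALSE
  last_delta <- NA_real_
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    W <- .step_w(W, Xs, Hs, Y, HY, eps)
    WtW <- crossprod(W)
    for (i in seq_along(Xs))
      Hs[[i]] <- .step_h(Hs[[i]], Xs[[i]], W, WtW, alpha, eps)
    if (!is.null(Y)) HY <- .step_hy(HY, Y, W, crossprod(W), eps)
    o <- objective()
    if (!is.finite(o[["total"]]))
      stop_numeric("objective became non-finite at iteration %d (seed %d)",
                   iter, seed)
    trace[iter, ] <- o
    iters <- iter
    delta <- abs(J_prev - o[["total"]])
    if (relative) delta <- delta / max(J_prev, .Machine$double.eps)
    last_delta <- delta
    if (verbose)
      message(sprintf("iter %4d  J = %.6g  delta = %.3g", iter,
                      o[["total"]], delta))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    J_prev <- o[["total"]]
  }
  list(W = W, H = Hs, H_Y = HY, trace = trace[seq_len(iters), , drop = FALSE],
       iterations = iters, converged = converged, last_delta = last_delta)
}

#' Fit an iONMF factor model
#'
#' Jointly factorizes multiple non-negative data source matrices with a
#' shared coefficient matrix `W` and per-source basis matrices `H_i`,
#' optionally together with a single-column crosslink target `Y` and its
#' basis `H_Y`.  All matrices are initialized uniformly on `[0, 1]` and
#' refined with multiplicative updates cycled as `W`, each `H_i` in source
#' order, then `H_Y`, until the change in the total objective between
#' consecutive iterations falls below `tol` or `max_iter` is reached.
#' The fit is repeated from `n_restarts` random initializations (restart
#' `k` uses seed `seed + k`) and the model with the lowest *approximation*
#' term is kept.
#'
#' The convergence test compares the change in the objective relative to
#' its current value by default (`criterion = "relative"`), which makes
#' `tol` independent of the data scale; `criterion = "absolute"` compares
#' the raw change.
#'
#' @param sources Named list of [data_source] objects or non-negative
#'   matrices sharing the same rows.
#' @param target Optional non-negative target vector (binary class labels
#'   by default; raw cDNA counts are equally valid).
#' @param rank Factorization rank `r` (number of modules).
#' @param alpha Orthogonality/approximation trade-off `alpha >= 0`.
#' @param max_iter Maximum number of update cycles per restart.
#' @param tol Convergence tolerance on the objective change.
#' @param n_restarts Number of random restarts.
#' @param seed Base integer seed; restart `k` is seeded with `seed + k`.
#' @param eps Stabilizer added to every update denominator.
#' @param criterion `"relative"` (default) or `"absolute"` objective-change
#'   convergence test.
#' @param normalize If `TRUE`, each source is divided by its Frobenius norm
#'   before fitting (scales are stored in the model and re-applied at
#'   prediction time).  Off by default: sources are used as encoded.
#' @param verbose Print the per-iteration objective.
#' @return An object of class `"ionmf"` (see [ionmf_model()]) whose
#'   `report` element holds the objective trace (`total`, `approx`,
#'   `ortho` per iteration), `iterations_run`, `chosen_restart` and
#'   `converged` for the selected restart.
#' @examples
#' sim <- simulate_multiview(m = 120, rank = 4,
#'                           source_sizes = c(30, 40), seed = 1)
#' fit <- ionmf(sim$sources, sim$target, rank = 4, max_iter = 50, seed = 1)
#' fit
#' @export
ionmf <- function(sources, target = NULL, rank = 10, alpha = 1,
                  max_iter = 100, tol = 1e-6, n_restarts = 3, seed = 1,
                  eps = 1e-9, criterion = c("relative", "absolute"),
                  normalize = FALSE, verbose = FALSE) {
  criterion <- match.arg(criterion)
  sources <- as_data_sources(sources)
  m <- nrow(sources[[1L]]$values)
  n_total <- sum(vapply(sources, function(s) ncol(s$values), 0L))
  if (rank < 1L) stop_input("rank must be >= 1")
  if (rank >= min(m, n_total))
    stop_input("rank %d must be < min(m = %d, total features = %d)",
               rank, m, n_total)
  if (tol <= 0) stop_input("tol must be > 0")
  if (n_restarts < 1L) stop_input("n_restarts must be >= 1")
  target <- check_target(target, m, require_nonzero = TRUE)

  scale <- vapply(sources, function(s) {
    if (normalize) sqrt(sum(s$values^2)) else 1
  }, 0)
  scale[scale == 0] <- 1
  Xs <- lapply(seq_along(sources),
               function(i) sources[[i]]$values / scale[i])
  names(Xs) <- names(sources)
  Y <- if (!is.null(target)) matrix(target, ncol = 1L) else NULL

  best <- NULL
  best_approx <- Inf
  chosen <- NA_integer_
  for (k in seq_len(n_restarts)) {
    run <- .ionmf_run(Xs, Y, rank, alpha, max_iter, tol, eps,
                      relative = (criterion == "relative"),
                      seed = seed + k, verbose = verbose)
    approx_k <- run$trace[run$iterations, "approx"]
    if (approx_k < best_approx) {
      best_approx <- approx_k
      best <- run
      chosen <- k
    }
  }

  for (nm in names(best$H))
    rownames(best$H[[nm]]) <- sources[[nm]]$feature_labels
  model <- ionmf_model(best$W, best$H, best$H_Y, alpha = alpha, eps = eps,
                       seed = seed)
  model$criterion <- criterion
  model$tol <- tol
  model$source_scale <- scale
  model$report <- list(
    objective_trace = as.data.frame(best$trace),
    iterations_run = best$iterations,
    chosen_restart = chosen,
    n_restarts = n_restarts,
    converged = best$converged,
    final_delta = best$last_delta
  )
  model
}

# -- hyperparameter selection --------------------------------------------

#' Select the orthogonality trade-off by internal resampling
#'
#' Repeats an 80%/20% split of the training rows `n_resamples` times; for
#' each grid value fits the model on the 80% part, projects the held-out
#' 20% with fixed bases and scores it by AUC against the target.  The grid
#' member with the highest mean validation AUC is returned, ties broken
#' toward the larger (more orthogonal) value.
#'
#' @inheritParams ionmf
#' @param grid Non-negative candidate values; default is the logarithmic
#'   grid `10^(-3:3)`.
#' @param n_resamples Number of 80/20 resamples (default 3).
#' @param train_fraction Fraction of rows used for fitting in each resample.
#' @param max_attempts Resampling attempts per split before giving up when a
#'   validation part ends up single-class.
#' @param ... Further arguments passed on to [ionmf()] (e.g. `max_iter`,
#'   `n_restarts`).
#' @return A list of class `"alpha_selection"` with elements `alpha` (the
#'   chosen value) and `auc_table` (per-grid-point mean validation AUC and
#'   standard error).
#' @export
select_alpha <- function(sources, target, grid = 10^(-3:3), rank = 10,
                         n_resamples = 3, train_fraction = 0.8, seed = 1,
                         max_attempts = 10, ...) {
  if (length(grid) == 0L || any(grid < 0))
    stop_input("'grid' must be a non-empty vector of non-negative values")
  sources <- as_data_sources(sources)
  m <- nrow(sources[[1L]]$values)
  target <- check_target(target, m, require_nonzero = TRUE)

  auc_mat <- matrix(NA_real_, n_resamples, length(grid))
  for (rep in seq_len(n_resamples)) {
    idx_val <- NULL
    for (attempt in seq_len(max_attempts)) {
      set.seed(seed + 97L * rep + attempt)
      cand <- sample.int(m, max(1L, round((1 - train_fraction) * m)))
      if (length(unique(target[cand] > 0)) == 2L &&
          length(unique(target[-cand] > 0)) == 2L) {
        idx_val <- cand
        break
      }
    }
    if (is.null(idx_val))
      stop_input(paste0("could not draw a validation split with both ",
                        "classes in %d attempts"), max_attempts)
    src_tr <- lapply(sources, function(s)
      data_source(s$values[-idx_val, , drop = FALSE], s$name,
                  s$feature_labels))
    src_va <- lapply(sources, function(s)
      data_source(s$values[idx_val, , drop = FALSE], s$name,
                  s$feature_labels))
    for (g in seq_along(grid)) {
      fit <- ionmf(src_tr, target[-idx_val], rank = rank, alpha = grid[g],
                   seed = seed + 1000L * rep, ...)
      proj <- ionmf_project(fit, src_va)
      auc_mat[rep, g] <- auc_score(proj$Y_hat, as.integer(target[idx_val] > 0))
    }
  }
  mean_auc <- colMeans(auc_mat)
  se <- apply(auc_mat, 2L, sd) / sqrt(n_resamples)
  chosen <- max(grid[mean_auc == max(mean_auc)])
  structure(list(alpha = chosen,
                 auc_table = data.frame(alpha = grid, mean_auc = mean_auc,
                                        se = se)),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("selected alpha = %g\n", x$alpha))
  print(x$auc_table, row.names = FALSE)
  invisible(x)
}
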