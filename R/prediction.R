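# Projection of new samples into a learned factor space: the basis
# matrices H_i stay fixed and only the new coefficient rows W_hat are
# estimated, with the same multiplicative rule used in training (no target
# term, no basis updates).  Scores are Y_hat = W_hat H_Y'.

# Deterministic seed derived from the printed numeric content of one sample
# row, so that identical rows always start from the identical initialization
# no matter where they appear in the matrix.
.row_content_seed <- function(key, base_seed) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147480009
  as.integer((h + 7919 * (base_seed %% 262144)) %% 2147483629)
}

#' Project new samples into a fitted factor space
#'
#' Estimates coefficient rows `W_hat` for new samples by iterating
#' `W_hat <- W_hat * (sum_i X_hat_i H_i) / (sum_i W_hat H_i' H_i + eps)`
#' with the model's basis matrices held fixed, then scores each row as
#' `Y_hat = W_hat H_Y'`.  Each row's initialization is drawn uniformly on
#' `[0, 1]` from a seed derived from the row's content and the model seed,
#' and each row is iterated until its own reconstruction residual stops
#' changing (same `criterion` as training), so duplicated rows receive
#' identical scores and the result is invariant to row order.
#'
#' Rows are processed in blocks of `block_size` to keep memory flat when
#' scoring genome-scale position lists.
#'
#' @param model A fitted [ionmf] model.
#' @param test_sources Named list of [data_source] objects (or matrices)
#'   matching the training sources by name and column count.
#' @param max_iter Maximum update iterations.
#' @param tol Convergence tolerance on the per-row residual change.
#' @param block_size Number of rows processed per block.
#' @return An object of class `"ionmf_projection"`: a list with `W_hat`
#'   (non-negative coefficients, one row per test sample), `Y_hat`
#'   (non-negative affinity scores, `NULL` when the model has no target
#'   basis) and `iterations_run`.
#' @examples
#' sim <- simulate_multiview(m = 150, rank = 4,
#'                           source_sizes = c(30, 40), seed = 2)
#' fit <- ionmf(sim$sources, sim$target, rank = 4, max_iter = 60, seed = 1)
#' tr <- lapply(sim$sources, function(s) s$values[1:20, ])
#' proj <- ionmf_project(fit, tr)
#' head(proj$Y_hat)
#' @export
ionmf_project <- function(model, test_sources, max_iter = 100, tol = 1e-6,
                          block_size = 10000) {
  if (!inherits(model, "ionmf")) stop_input("'model' must be an ionmf model")
  test_sources <- as_data_sources(test_sources)
  for (nm in names(test_sources)) {
    if (is.null(model$H[[nm]]))
      stop_input("unknown source '%s'; the model was fitted on: %s",
                 nm, paste(names(model$H), collapse = ", "))
    n_model <- nrow(model$H[[nm]])
    if (ncol(test_sources[[nm]]$values) != n_model) {
      lab <- model$feature_labels[[nm]]
      hint <- if (!is.null(lab))
        sprintf(" (expected labels: %s%s)",
                paste(head(lab, 4L), collapse = ", "),
                if (length(lab) > 4L) ", ..." else "")
      else ""
      stop_input("source '%s': %d feature columns but model expects %d%s",
                 nm, ncol(test_sources[[nm]]$values), n_model, hint)
    }
  }
  scale <- model$source_scale
  Xs <- lapply(names(test_sources), function(nm) {
    s <- if (!is.null(scale) && !is.na(scale[nm])) scale[nm] else 1
    test_sources[[nm]]$values / s
  })
  names(Xs) <- names(test_sources)
  Hs <- model$H[names(Xs)]
  HtH <- lapply(Hs, crossprod)
  r <- model$rank
  eps <- model$eps %||% 1e-9
  relative <- !identical(model$criterion, "absolute")
  base_seed <- if (is.na(model$seed)) 0L else as.integer(model$seed)

  m_hat <- nrow(Xs[[1L]])
  W_hat <- matrix(0, m_hat, r)
  iterations_run <- 0L
  blocks <- split(seq_len(m_hat), ceiling(seq_len(m_hat) / block_size))
  for (idx in blocks) {
    # work on the distinct row contents only (in canonical order), so
    # duplicated rows provably receive identical coefficients and the
    # result does not depend on row order
    key <- apply(do.call(cbind, lapply(Xs, function(X)
      X[idx, , drop = FALSE])), 1L, function(row)
      paste(sprintf("%.17g", row), collapse = ","))
    uk <- sort(unique(key), method = "radix")
    first <- idx[match(uk, key)]
    Xb <- lapply(Xs, function(X) X[first, , drop = FALSE])
    Wb <- matrix(0, length(uk), r)
    for (u in seq_along(uk)) {
      set.seed(.row_content_seed(uk[u], base_seed))
      Wb[u, ] <- runif(r)
    }
    row_residual <- function(rows) {
      res <- rep(0, length(rows))
      for (i in seq_along(Xb))
        res <- res + rowSums((Xb[[i]][rows, , drop = FALSE] -
                                Wb[rows, , drop = FALSE] %*% t(Hs[[i]]))^2)
      res
    }
    res_prev <- row_residual(seq_along(uk))
    active <- rep(TRUE, length(uk))
    for (iter in seq_len(max_iter)) {
      num <- 0
      den <- 0
      for (i in seq_along(Xb)) {
        num <- num + Xb[[i]][active, , drop = FALSE] %*% Hs[[i]]
        den <- den + Wb[active, , drop = FALSE] %*% HtH[[i]]
      }
      Wb[active, ] <- Wb[active, , drop = FALSE] * num / (den + eps)
      res <- row_residual(which(active))
      delta <- abs(res_prev[active] - res)
      if (relative) delta <- delta / pmax(res_prev[active],
                                          .Machine$double.eps)
      res_prev[active] <- res
      iterations_run <- max(iterations_run, iter)
      still <- delta >= tol
      active[active] <- still
      if (!any(active)) break
    }
    W_hat[idx, ] <- Wb[match(key, uk), , drop = FALSE]
  }
  if (anyNA(W_hat) || any(!is.finite(W_hat)))
    stop_numeric("non-finite coefficients produced during projection")
  Y_hat <- if (!is.null(model$H_Y))
    as.numeric(W_hat %*% t(model$H_Y)) else NULL
  structure(list(W_hat = W_hat, Y_hat = Y_hat,
                 iterations_run = iterations_run),
            class = "ionmf_projection")
}

#' @export
print.ionmf_projection <- function(x, ...) {
  cat(sprintf("<ionmf_projection> %d samples, %d iterations%s\n",
              nrow(x$W_hat), x$iterations_run,
              if (is.null(x$Y_hat)) " (no target scores)" else ""))
  invisible(x)
}

#' Predict crosslink affinity for new samples
#'
#' @param object A fitted [ionmf] model with a target basis.
#' @param newdata Named list of test source matrices (see
#'   [ionmf_project()]).
#' @param type `"response"` for affinity scores, `"coefficients"` for the
#'   projected coefficient matrix `W_hat`.
#' @param ... Passed on to [ionmf_project()].
#' @return A numeric score vector or a coefficient matrix.
#' @export
predict.ionmf <- function(object, newdata,
                          type = c("response", "coefficients"), ...) {
  type <- match.arg(type)
  proj <- ionmf_project(object, newdata, ...)
  if (type == "coefficients") return(proj$W_hat)
  if (is.null(proj$Y_hat))
    stop_input("model has no target basis; fit with a target to predict")
  proj$Y_hat
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop_input("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels))
    stop_input("scores and labels must not contain NA")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_input("both classes must be present to compute AUC")
  rk <- rank(scores)
  (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
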