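#' Replicated k-fold cross-validation plans
#'
#' Uniform random partitions of the individuals into `k` folds, repeated
#' `replicates` times; fold sizes differ by at most one. Reproducible from
#' the seed.
#'
#' @param ids individual identifiers.
#' @param k number of folds (default 10).
#' @param replicates number of independent replicate partitions
#'   (default 10).
#' @param seed integer RNG seed.
#' @return An object of class `FoldPlan`: list with `ids`, `k`,
#'   `replicates`, `seed` and `assignment`, a `replicates x n` integer
#'   matrix of fold indices.
#' @export
make_folds <- function(ids, k = 10L, replicates = 10L, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("k exceeds the number of individuals")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  assignment <- matrix(NA_integer_, replicates, n,
                       dimnames = list(NULL, ids))
  for (r in seq_len(replicates))
    assignment[r, sample.int(n)] <- rep.int(seq_len(k), sizes)
  structure(list(ids = ids, k = as.integer(k),
                 replicates = as.integer(replicates), seed = seed,
                 assignment = assignment),
            class = "FoldPlan")
}

#' Cross-validated predictive ability of a mixed model
#'
#' For every replicate and fold, variance components are re-estimated on
#' the training individuals only; the validation individuals' phenotypes
#' never enter the training fit. Validation predictions are obtained
#' through the relationship-matrix links,
#' `u_hat_val,k = s2_k K_k[val, train] P_train y_train`, the
#' cross-validated additive value is the additive effect and the total
#' genetic value the sum over all fitted effects. `r1` is the per-fold
#' Pearson correlation with the validation phenotypes; aggregates are the
#' mean and SD over all replicate-by-fold cells.
#'
#' @param y named numeric phenotype vector (names = ids).
#' @param kernels kernel set keyed by kind (see [fit_reml()]).
#' @param spec a [model_spec()].
#' @param plan a [make_folds()] plan on the same ids.
#' @param refit re-estimate variance components within every training fold
#'   (default TRUE, the honest protocol). `FALSE` freezes the components
#'   at a single full-data fit — faster, but the full-data fit has seen
#'   the validation phenotypes, so use it for sensitivity analysis only.
#' @param tol,max_iter passed to [fit_reml()].
#' @return An object of class `CVResult`: list with `cells` (data.frame:
#'   replicate, fold, n_val, r1_add, r1_total, converged), `summary`
#'   (means and SDs), `predictions` (per replicate, matrix of
#'   cross-validated add/total values), `n_failed`.
#' @export
cross_validate <- function(y, kernels, spec, plan, refit = TRUE,
                           tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(plan, "FoldPlan"))
  ids <- plan$ids
  if (is.null(names(y))) stop("y must be named by individual id")
  y <- y[ids]
  Kmats <- .spec_kernels(spec, kernels, ids)
  fit_full <- if (!refit)
    suppressWarnings(fit_reml(y, Kmats, tol = tol, max_iter = max_iter))
  n <- length(ids)
  cells <- list()
  pred_add <- matrix(NA_real_, plan$replicates, n,
                     dimnames = list(NULL, ids))
  pred_tot <- pred_add
  n_failed <- 0L
  for (r in seq_len(plan$replicates)) {
    fold_of <- plan$assignment[r, ]
    for (f in seq_len(plan$k)) {
      val <- which(fold_of == f)
      train <- which(fold_of != f)
      fit <- if (!refit) fit_full else tryCatch(
        suppressWarnings(fit_reml(y[train],
                 lapply(Kmats, function(K) K[train, train, drop = FALSE]),
                 tol = tol, max_iter = max_iter)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        n_failed <- n_failed + 1L
        warning(sprintf("replicate %d fold %d: training fit failed/non-converged; skipped",
                        r, f))
        next
      }
      theta <- fit$estimates
      # projection of the training data at the fitted components
      Vtr <- theta[["residual"]] * diag(length(train))
      for (k in names(Kmats))
        if (theta[[k]] > 0)
          Vtr <- Vtr + theta[[k]] * Kmats[[k]][train, train]
      Vinv <- chol2inv(chol(Vtr))
      X <- matrix(1, length(train), 1)
      ViX <- Vinv %*% X
      P <- Vinv - ViX %*% solve(crossprod(X, ViX), t(ViX))
      Py <- drop(P %*% y[train])
      u_val <- matrix(0, length(val), length(Kmats))
      for (j in seq_along(Kmats)) {
        k <- names(Kmats)[j]
        if (theta[[k]] > 0)
          u_val[, j] <- theta[[k]] *
            drop(Kmats[[k]][val, train, drop = FALSE] %*% Py)
      }
      add_j <- if ("add" %in% names(Kmats)) which(names(Kmats) == "add") else 1L
      a_vp <- u_val[, add_j]
      g_vp <- rowSums(u_val)
      pred_add[r, val] <- a_vp
      pred_tot[r, val] <- g_vp
      cells[[length(cells) + 1L]] <- data.frame(
        replicate = r, fold = f, n_val = length(val),
        r1_add = if (stats::sd(a_vp) > 0) stats::cor(a_vp, y[val]) else NA_real_,
        r1_total = if (stats::sd(g_vp) > 0) stats::cor(g_vp, y[val]) else NA_real_)
    }
  }
  cells <- do.call(rbind, cells)
  summ <- c(r1_add_mean = mean(cells$r1_add, na.rm = TRUE),
            r1_add_sd = stats::sd(cells$r1_add, na.rm = TRUE),
            r1_total_mean = mean(cells$r1_total, na.rm = TRUE),
            r1_total_sd = stats::sd(cells$r1_total, na.rm = TRUE))
  structure(list(cells = cells, summary = summ,
                 predictions = list(add = pred_add, total = pred_tot),
                 n_failed = n_failed, label = spec$label),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("Cross-validation [%s]: %d cells (%d failed)\n",
              x$label %||% "?", nrow(x$cells), x$n_failed))
  print(round(x$summary, 3))
  invisible(x)
}

#' Predictive accuracy from predictive ability
#'
#' `r2 = r1 / sqrt(heritability)`: the cross-validated correlation scaled
#' by the ceiling that heritability places on it. Use the narrow-sense
#' heritability with additive (EBV) predictions and the broad-sense
#' heritability with total genetic (EGV) predictions.
#'
#' @param r1 predictive ability (Pearson correlation).
#' @param heritability narrow- or broad-sense heritability in (0, 1].
#' @return `r1 / sqrt(heritability)`.
#' @examples
#' predictive_accuracy(0.42, 0.32)  # 0.74
#' @export
predictive_accuracy <- function(r1, heritability) {
  if (any(heritability <= 0)) stop("heritability must be positive")
  r1 / sqrt(heritability)
}

#' Spearman rank concordance between model predictions
#'
#' Pairwise Spearman rank correlations between prediction vectors (EBV vs
#' EBV or EGV vs EGV across models), computed on raw (unrounded) values.
#'
#' @param predictions named list of numeric vectors over the same
#'   individuals.
#' @return Symmetric matrix of Spearman correlations.
#' @export
spearman_concordance <- function(predictions) {
  if (length(predictions) < 2L) stop("need at least two prediction vectors")
  lens <- vapply(predictions, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("prediction vectors must cover the same individuals")
  if (any(vapply(predictions, stats::sd, numeric(1)) == 0))
    stop("constant prediction vector")
  stats::cor(do.call(cbind, predictions), method = "spearman")
}
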