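#' Model specifications for the PBLUP/GBLUP family
#'
#' Maps a model label to the ordered set of (effect name, kernel kind)
#' pairs it fits. All models include an overall-mean fixed effect only, and
#' all random-effect incidence matrices are identity (one adjusted record
#' per individual).
#'
#' @param label one of `"PBLUP-A"`, `"PBLUP-AD"`, `"GBLUP-A"`,
#'   `"GBLUP-AD"`, `"GBLUP-ADE"`.
#' @return A `model_spec` list with `label` and `effects` (named character
#'   vector: effect name -> kernel kind).
#' @examples
#' model_spec("GBLUP-ADE")$effects
#' @export
model_spec <- function(label = c("PBLUP-A", "PBLUP-AD", "GBLUP-A",
                                 "GBLUP-AD", "GBLUP-ADE")) {
  label <- match.arg(label)
  effects <- switch(label,
    "PBLUP-A"   = c(add = "A"),
    "PBLUP-AD"  = c(add = "A", dom = "D"),
    "GBLUP-A"   = c(add = "G_A"),
    "GBLUP-AD"  = c(add = "G_A", dom = "G_D"),
    "GBLUP-ADE" = c(add = "G_A", dom = "G_D", aa = "G_AA", ad = "G_AD",
                    dd = "G_DD"))
  structure(list(label = label, effects = effects), class = "model_spec")
}

# Pick the kernels a model needs out of a kernel set, as plain matrices
# named by effect, aligned to the given ids.
.spec_kernels <- function(spec, kernels, ids) {
  out <- lapply(spec$effects, function(kind) {
    K <- kernels[[kind]]
    if (is.null(K)) stop("kernel set lacks kind ", kind)
    if (length(setdiff(ids, rownames(K))))
      stop("kernel ", kind, " lacks some requested individuals")
    unclass(K)[ids, ids, drop = FALSE]
  })
  names(out) <- names(spec$effects)
  out
}

#' Fit a multi-kernel mixed model by average-information REML
#'
#' Fits `y = 1*beta + sum_k u_k + e` with `u_k ~ N(0, s2_k K_k)` and
#' `e ~ N(0, s2_e I)` by restricted maximum likelihood. The first
#' iterations use EM updates (guaranteed in the parameter space), then
#' average-information (AI) steps with step-halving; any AI step that
#' leaves the parameter space or decreases the restricted likelihood falls
#' back to EM. A component driven below `boundary_tol * var(y)` is fixed
#' at 0, flagged, and excluded from further updates (the convention used
#' when REML software reports components "fixed at the boundary").
#'
#' @param y numeric response (one adjusted record per individual), or a
#'   named vector whose names match the kernel ids.
#' @param kernels named list of symmetric n x n kernel matrices, one per
#'   random genetic effect (the residual identity kernel is implicit). May
#'   be [relationship_matrix()] objects or plain matrices; if `spec` is
#'   given, a full kernel set keyed by kind (`A`, `G_A`, ...) is expected
#'   and the model's kernels are selected from it.
#' @param spec optional [model_spec()]; when supplied, `kernels` is
#'   interpreted as a kernel set keyed by kind.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-8); parameter changes must also settle
#'   (relative change below 1e-6).
#' @param max_iter maximum REML iterations (default 100).
#' @param boundary_tol boundary threshold as a fraction of the phenotypic
#'   variance (default 1e-8).
#' @param aic_count `"free"` (default) counts only variance parameters not
#'   fixed at the boundary (residual included); `"all"` counts every
#'   variance parameter of the model.
#' @param verbose print the likelihood trajectory.
#' @return An object of class `VarianceComponents`: list with `estimates`
#'   (named, residual last), `se` (approximate, from the inverse AI matrix;
#'   0 for boundary-fixed components), `boundary` (logical flags), `logL`
#'   (restricted log-likelihood, constant included), `AIC`, `n_params`,
#'   `iterations`, `converged`, `trajectory`, `n`, `label`.
#' @export
fit_reml <- function(y, kernels, spec = NULL, tol = 1e-8, max_iter = 100L,
                     boundary_tol = 1e-8, aic_count = c("free", "all"),
                     verbose = FALSE) {
  aic_count <- match.arg(aic_count)
  if (!is.null(spec)) {
    ids <- names(y) %||% rownames(kernels[[spec$effects[[1L]]]])
    kernels <- .spec_kernels(spec, kernels, ids)
  } else {
    kernels <- lapply(kernels, unclass)
  }
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    stop("kernels must be a named list")
  n <- length(y)
  if (stats::var(y) == 0) stop("response is constant")
  for (nm in names(kernels)) {
    K <- kernels[[nm]]
    if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
      stop("kernel '", nm, "' is not an n x n matrix matching y")
    .warn_if_identity_like(K, nm)
  }
  vy <- stats::var(y)
  nk <- length(kernels)
  theta <- c(rep(vy / (2 * nk), nk), vy / 2)
  names(theta) <- c(names(kernels), "residual")
  free <- rep(TRUE, nk + 1L)
  bnd <- boundary_tol * vy

  Ks <- c(kernels, list(residual = diag(n)))
  X <- matrix(1, n, 1)
  eval_parts <- function(theta) {
    V <- matrix(0, n, n)
    for (k in seq_along(Ks)) if (theta[k] > 0) V <- V + theta[k] * Ks[[k]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    ViX <- Vinv %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vinv - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    logL <- -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1L] +
                    sum(y * Py) + (n - ncol(X)) * log(2 * pi))
    list(P = P, Py = Py, logL = logL)
  }

  parts <- eval_parts(theta)
  if (is.null(parts)) stop("initial variance matrix not positive definite")
  logL <- parts$logL
  trajectory <- logL
  converged <- FALSE
  iter <- 0L
  ai_inv <- NULL

  repeat {
    iter <- iter + 1L
    P <- parts$P; Py <- parts$Py
    trP <- vapply(Ks, function(K) sum(P * K), numeric(1))  # tr(PK), symmetric
    yPKPy <- vapply(Ks, function(K) drop(crossprod(Py, K %*% Py)), numeric(1))
    score <- -0.5 * (trP - yPKPy)

    # active-set release: a boundary-pinned component whose score turns
    # positive (likelihood increases into the interior) is freed again,
    # so the final active set satisfies the KKT conditions
    release <- !free & (score * vy / n > 1e-6)
    if (any(release)) {
      free[release] <- TRUE
      theta[release] <- pmax(bnd, 1e-6 * vy)
      parts <- eval_parts(theta)
      P <- parts$P; Py <- parts$Py
      logL <- parts$logL
      trP <- vapply(Ks, function(K) sum(P * K), numeric(1))
      yPKPy <- vapply(Ks, function(K) drop(crossprod(Py, K %*% Py)),
                      numeric(1))
      score <- -0.5 * (trP - yPKPy)
    }
    Wm <- vapply(Ks, function(K) drop(K %*% Py), numeric(n))
    PW <- P %*% Wm
    AI <- 0.5 * crossprod(Wm, PW)

    fidx <- which(free)
    theta_new <- theta
    used_em <- FALSE
    AIf <- AI[fidx, fidx, drop = FALSE]
    if (iter > 1L && length(fidx) &&
        !inherits(try(solve(AIf), silent = TRUE), "try-error")) {
      step <- solve(AIf, score[fidx])
      lambda <- 1
      repeat {
        cand <- theta
        # AI proposals that leave the parameter space are clamped to the
        # zero boundary (where the boundary rule below may pin them)
        cand[fidx] <- pmax(theta[fidx] + lambda * step, 0)
        cand_parts <- eval_parts(cand)
        if (!is.null(cand_parts) && cand_parts$logL >= logL - 1e-10) {
          theta_new <- cand
          parts_new <- cand_parts
          break
        }
        lambda <- lambda / 2
        if (lambda < 1 / 64) { used_em <- TRUE; break }
      }
    } else used_em <- TRUE

    if (used_em) {
      theta_new <- theta
      theta_new[fidx] <- theta[fidx] +
        theta[fidx]^2 * (yPKPy[fidx] - trP[fidx]) / n
      theta_new[fidx] <- pmax(theta_new[fidx], 0)
      parts_new <- eval_parts(theta_new)
      if (is.null(parts_new))
        stop("variance matrix became singular during EM update")
    }

    # boundary handling: pin tiny components at exactly zero
    hit <- free & theta_new < bnd
    if (any(hit)) {
      theta_new[hit] <- 0
      free[hit] <- FALSE
      if (!any(free)) stop("all variance components driven to the boundary")
      parts_new <- eval_parts(theta_new)
      if (is.null(parts_new))
        stop("variance matrix singular after boundary fixing")
    }

    dlogL <- parts_new$logL - logL
    dtheta <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-4 * vy))
    theta <- theta_new
    parts <- parts_new
    logL <- parts$logL
    trajectory <- c(trajectory, logL)
    if (verbose)
      message(sprintf("iter %3d logL %.8f (%s)", iter, logL,
                      if (used_em) "EM" else "AI"))
    if (abs(dlogL) < tol && dtheta < 1e-6) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  # approximate SEs from the inverse AI matrix at the optimum (free only)
  se <- rep(0, nk + 1L)
  names(se) <- names(theta)
  fidx <- which(free)
  if (length(fidx)) {
    P <- parts$P; Py <- parts$Py
    Wm <- vapply(Ks[fidx], function(K) drop(K %*% Py), numeric(n))
    Wm <- matrix(Wm, nrow = n)
    AI <- 0.5 * crossprod(Wm, P %*% Wm)
    ai_inv <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(ai_inv)) se[fidx] <- sqrt(pmax(diag(ai_inv), 0))
  }

  if (!converged)
    warning(sprintf("REML did not converge in %d iterations (last dlogL %.3g)",
                    max_iter, trajectory[length(trajectory)] -
                      trajectory[length(trajectory) - 1L]))

  n_params <- if (aic_count == "free") sum(free) else nk + 1L
  out <- list(estimates = theta, se = se,
              boundary = stats::setNames(!free, names(theta)),
              logL = logL, AIC = -2 * logL + 2 * n_params,
              n_params = n_params, iterations = iter,
              converged = converged, trajectory = trajectory,
              n = n, label = if (!is.null(spec)) spec$label else NULL,
              aic_count = aic_count)
  class(out) <- "VarianceComponents"
  out
}

# single-kernel models where the kernel is numerically proportional to the
# identity are confounded with the residual; report it
.warn_if_identity_like <- function(K, name) {
  dm <- mean(diag(K))
  off <- K
  diag(off) <- 0
  if (dm > 0 && max(abs(off)) < 1e-8 * dm &&
      stats::sd(diag(K)) < 1e-8 * dm)
    warning("kernel '", name, "' is numerically proportional to the ",
            "identity: its variance is not separable from the residual ",
            "(confounded model)")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat(sprintf("REML fit%s: n = %d, logL = %.3f, AIC = %.2f (%d param.)%s\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$n, x$logL, x$AIC, x$n_params,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  tab <- data.frame(estimate = round(x$estimates, 4),
                    se = round(x$se, 4),
                    boundary = ifelse(x$boundary, "at 0", ""))
  print(tab)
  invisible(x)
}

#' BLUP solutions and prediction error variances at fitted components
#'
#' Solves the mixed-model equations at the plugged-in variance components:
#' `u_hat_k = s2_k K_k P y`, with prediction error (co)variances from the
#' projection-matrix identities (`PEV_k = s2_k K_k - s2_k^2 K_k P K_k`;
#' cross-effect covariance `-s2_k s2_l K_k P K_l`), algebraically equal to
#' the corresponding blocks of the inverse mixed-model coefficient matrix.
#' The EGV is the sum of every fitted genetic effect; its SEP includes the
#' cross-effect covariances.
#'
#' @inheritParams fit_reml
#' @param vc a converged [fit_reml()] result on the same data.
#' @param fixed_mean fit an overall-mean fixed effect (default TRUE). Set
#'   FALSE only for pre-centered data with a known zero mean.
#' @return An object of class `PredictionResult`: list with `predictions`
#'   (data.frame: id, ebv, egv, sep_ebv, sep_egv), `effects` (matrix of
#'   per-effect BLUPs), `beta_hat`, and the `label` of the model.
#' @export
predict_blup <- function(y, kernels, vc, spec = NULL, fixed_mean = TRUE) {
  stopifnot(inherits(vc, "VarianceComponents"))
  if (!is.null(spec)) {
    ids <- names(y) %||% rownames(kernels[[spec$effects[[1L]]]])
    kernels <- .spec_kernels(spec, kernels, ids)
  } else {
    kernels <- lapply(kernels, unclass)
  }
  n <- length(y)
  theta <- vc$estimates
  eff_names <- setdiff(names(theta), "residual")
  if (!setequal(names(kernels), eff_names))
    stop("kernels must match the effects fitted in vc: ",
         paste(eff_names, collapse = ", "))
  kernels <- kernels[eff_names]
  V <- theta[["residual"]] * diag(n)
  for (k in eff_names) if (theta[[k]] > 0) V <- V + theta[[k]] * kernels[[k]]
  Vinv <- chol2inv(chol(V))
  if (fixed_mean) {
    X <- matrix(1, n, 1)
    ViX <- Vinv %*% X
    XtViX <- crossprod(X, ViX)
    beta_hat <- drop(solve(XtViX, crossprod(ViX, y)))
    P <- Vinv - ViX %*% solve(XtViX, t(ViX))
  } else {
    beta_hat <- 0
    P <- Vinv
  }
  Py <- drop(P %*% y)
  u <- matrix(0, n, length(eff_names), dimnames = list(names(y), eff_names))
  pev <- matrix(0, n, length(eff_names))
  KPy_cache <- list()
  PK_cache <- list()
  for (j in seq_along(eff_names)) {
    k <- eff_names[j]
    s2 <- theta[[k]]
    if (s2 > 0) {
      u[, j] <- s2 * drop(kernels[[k]] %*% Py)
      PKj <- P %*% kernels[[k]]
      PK_cache[[k]] <- PKj
      pev[, j] <- s2 * diag(kernels[[k]]) -
        s2^2 * colSums(t(kernels[[k]]) * PKj)
    }
  }
  # EGV PEV adds 2 * cross-effect covariances
  cross <- rep(0, n)
  active <- which(theta[eff_names] > 0)
  if (length(active) > 1L) {
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b) {
        ka <- eff_names[active[a]]; kb <- eff_names[active[b]]
        cov_ab <- -theta[[ka]] * theta[[kb]] *
          colSums(t(kernels[[ka]]) * PK_cache[[kb]])
        cross <- cross + 2 * cov_ab
      }
    }
  }
  egv_pev <- rowSums(pev) + cross
  add_j <- if ("add" %in% eff_names) which(eff_names == "add") else 1L
  ebv <- u[, add_j]
  egv <- rowSums(u)
  preds <- data.frame(id = names(y) %||% seq_len(n),
                      ebv = ebv, egv = egv,
                      sep_ebv = sqrt(pmax(pev[, add_j], 0)),
                      sep_egv = sqrt(pmax(egv_pev, 0)),
                      stringsAsFactors = FALSE)
  rownames(preds) <- NULL
  structure(list(predictions = preds, effects = u, beta_hat = beta_hat,
                 label = vc$label),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("BLUP predictions%s: %d individuals, beta_hat = %.4f\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$predictions), x$beta_hat))
  print(utils::head(x$predictions))
  if (nrow(x$predictions) > 6L) cat("...\n")
  invisible(x)
}

#' Goodness-of-fit correlations of a fitted model
#'
#' Pearson correlations between the full-data estimated additive values
#' (EBV) resp. total genetic values (EGV) and the adjusted phenotypes,
#' with the t statistic `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and its
#' two-sided p-value.
#'
#' @param pred a [predict_blup()] result.
#' @param y the phenotypes the model was fitted to.
#' @return data.frame with rows `additive` and `total` and columns `r`,
#'   `t`, `p`, `n`.
#' @export
goodness_of_fit <- function(pred, y) {
  stopifnot(inherits(pred, "PredictionResult"))
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  one <- function(v) {
    if (stats::sd(v) == 0 || stats::sd(y) == 0)
      stop("zero-variance input to goodness_of_fit")
    r <- stats::cor(v, y)
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
    c(r = r, t = t, p = p, n = n)
  }
  out <- rbind(additive = one(pred$predictions$ebv),
               total = one(pred$predictions$egv))
  as.data.frame(out)
}

#' Rank fitted models by AIC
#'
#' @param fits list of [fit_reml()] results on the same trait and
#'   individuals.
#' @param labels optional labels (default: each fit's own label).
#' @return data.frame with label, logL, n_params, AIC, delta_AIC, sorted
#'   best-first.
#' @export
model_comparison <- function(fits, labels = NULL) {
  if (is.null(labels))
    labels <- vapply(seq_along(fits), function(i)
      fits[[i]]$label %||% paste0("model", i), character(1))
  out <- data.frame(label = labels,
                    logL = vapply(fits, function(f) f$logL, numeric(1)),
                    n_params = vapply(fits, function(f) f$n_params,
                                      numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$AIC), ]
  out$delta_AIC <- out$AIC - out$AIC[1L]
  rownames(out) <- NULL
  out
}
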