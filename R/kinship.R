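#' Relationship (covariance-structure) matrices
#'
#' A `RelationshipMatrix` is a symmetric n x n kernel describing the
#' covariance structure of one genetic effect, tagged with its kind:
#' pedigree additive `A`, pedigree dominance `D`, genomic additive `G_A`,
#' genomic dominance `G_D`, or the first-order epistatic kernels `G_AA`,
#' `G_AD`, `G_DD`. Stored as a base matrix with `dimnames` = individual ids
#' and attributes `kind`, `psd_adjusted`, and (for genomic kinds) `scaling`
#' holding the denominator used.
#'
#' @param values symmetric numeric matrix.
#' @param kind one of `"A"`, `"D"`, `"G_A"`, `"G_D"`, `"G_AA"`, `"G_AD"`,
#'   `"G_DD"`.
#' @param ids individual identifiers (defaults to existing dimnames).
#' @param psd_adjusted logical; has a ridge been added by [ensure_psd()]?
#' @param scaling optional scaling constant used in construction.
#' @export
relationship_matrix <- function(values, kind, ids = rownames(values),
                                psd_adjusted = FALSE, scaling = NULL) {
  kinds <- c("A", "D", "G_A", "G_D", "G_AA", "G_AD", "G_DD")
  if (!kind %in% kinds)
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 0)
    stop("relationship matrix must be exactly symmetric")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("RelationshipMatrix", "matrix"),
            kind = kind, psd_adjusted = psd_adjusted, scaling = scaling)
}

#' @export
print.RelationshipMatrix <- function(x, ...) {
  cat(sprintf("RelationshipMatrix [%s]: %d x %d%s\n", attr(x, "kind"),
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "psd_adjusted"))) " (ridge-adjusted)" else ""))
  k <- min(5L, nrow(x))
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("...\n")
  invisible(x)
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular-method recursion in topological order: for individual `i` with
#' parents `g`, `h`, `A_ii = 1 + A_gh / 2` and `A_ij = (A_jg + A_jh) / 2`
#' for previously processed `j`; founders have diagonal 1 and are unrelated
#' to everyone processed before them.
#'
#' @param ped a [pedigree()] object.
#' @return A [relationship_matrix()] of kind `"A"`.
#' @export
pedigree_additive <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  NA_integer_, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {            # founder (validation forbids single parents)
      A[i, i] <- 1
    } else {
      if (i > 1L) {
        j <- seq_len(i - 1L)
        aij <- 0.5 * (A[s, j] + A[d, j])
        A[i, j] <- aij
        A[j, i] <- aij
      }
      A[i, i] <- 1 + 0.5 * A[s, d]
    }
  }
  relationship_matrix(A, "A", ids = ped$id)
}

#' Pedigree dominance relationship matrix (D)
#'
#' Classical full-sib dominance relationship: for individuals `i` (parents
#' `g`, `h`) and `j` (parents `k`, `l`),
#' `D_ij = (A_gk * A_hl + A_gl * A_hk) / 4`, and `D_ii = 1`. Pairs where
#' either member is a founder get 0. The formula is the classical
#' non-inbred one; when parental inbreeding/relatedness is present it is
#' still applied as printed, with a warning.
#'
#' @param ped a [pedigree()] object.
#' @param A optional precomputed [pedigree_additive()] matrix on the same
#'   individuals (computed if missing).
#' @return A [relationship_matrix()] of kind `"D"`.
#' @export
pedigree_dominance <- function(ped, A = NULL) {
  stopifnot(inherits(ped, "Pedigree"))
  if (is.null(A)) A <- pedigree_additive(ped)
  if (!identical(rownames(A), ped$id))
    stop("A must be computed on the same individuals, in the same order")
  Au <- unclass(A)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  nonf <- which(!is.na(ped$sire))
  D <- matrix(0, n, n)
  if (length(nonf)) {
    s <- idx[ped$sire[nonf]]
    d <- idx[ped$dam[nonf]]
    f <- Au[cbind(s, d)]
    if (any(f > 0))
      warning("related/inbred parents present; the classical non-inbred ",
              "dominance formula is applied as-is")
    D[nonf, nonf] <- (Au[s, s, drop = FALSE] * Au[d, d, drop = FALSE] +
                      Au[s, d, drop = FALSE] * Au[d, s, drop = FALSE]) / 4
  }
  diag(D) <- 1
  relationship_matrix(D, "D", ids = ped$id)
}

#' Genomic additive relationship matrix (VanRaden G)
#'
#' `G_A = Z Z' / (2 * sum(p_i * (1 - p_i)))` with `Z = M - P`, where `M` is
#' the 0/1/2 alternative-allele count matrix and `P` the matrix of column
#' scores `2 p_i`; `p_i` is the in-sample alternative allele frequency.
#'
#' @param geno a [genotype_matrix()] with no monomorphic loci.
#' @return A [relationship_matrix()] of kind `"G_A"` with attribute
#'   `scaling` = the denominator.
#' @export
genomic_additive <- function(geno) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  p <- geno$p
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic; G_A denominator is zero")
  if (any(!poly)) {
    warning(sprintf("excluding %d monomorphic locus/loci", sum(!poly)))
    p <- p[poly]
  }
  M <- geno$calls[, poly, drop = FALSE]
  Z <- sweep(M, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  relationship_matrix(tcrossprod(Z) / denom, "G_A", ids = geno$ids,
                      scaling = denom)
}

#' Genomic dominance relationship matrix (Vitezica G_D)
#'
#' `G_D = W W' / sum(4 p_i^2 q_i^2)` where the dominance design `W` codes
#' the alternative homozygote as `-2 q_i^2`, the heterozygote as
#' `2 p_i q_i`, and the reference homozygote as `-2 p_i^2` (`q_i = 1 - p_i`).
#'
#' @inheritParams genomic_additive
#' @return A [relationship_matrix()] of kind `"G_D"` with attribute
#'   `scaling` = the denominator.
#' @export
genomic_dominance <- function(geno) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  p <- geno$p
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic; G_D denominator is zero")
  if (any(!poly)) {
    warning(sprintf("excluding %d monomorphic locus/loci", sum(!poly)))
    p <- p[poly]
  }
  M <- geno$calls[, poly, drop = FALSE]
  q <- 1 - p
  W <- matrix(0, nrow(M), ncol(M))
  W <- W + (M == 2L) * rep(-2 * q^2, each = nrow(M))
  W <- W + (M == 1L) * rep(2 * p * q, each = nrow(M))
  W <- W + (M == 0L) * rep(-2 * p^2, each = nrow(M))
  denom <- sum(4 * p^2 * q^2)
  relationship_matrix(tcrossprod(W) / denom, "G_D", ids = geno$ids,
                      scaling = denom)
}

#' First-order epistatic kernels by Hadamard products
#'
#' `G_AA = (G_A . G_A) / (tr(G_A . G_A) / n)` and analogously for
#' `G_AD` (from `G_A . G_D`) and `G_DD` (from `G_D . G_D`), where `.` is
#' the elementwise (Hadamard) product. Each output has trace equal to n.
#'
#' @param GA,GD genomic additive and dominance [relationship_matrix()]
#'   objects on identical individuals.
#' @return Named list with elements `G_AA`, `G_AD`, `G_DD`.
#' @export
epistatic_kernels <- function(GA, GD) {
  if (!identical(rownames(GA), rownames(GD)))
    stop("G_A and G_D must share identical individual ids")
  n <- nrow(GA)
  one <- function(H, kind) {
    tr <- sum(diag(H))
    if (tr <= 0) stop("zero trace in Hadamard product for ", kind)
    relationship_matrix(H / (tr / n), kind, ids = rownames(GA),
                        scaling = tr / n)
  }
  GAu <- unclass(GA); GDu <- unclass(GD)
  list(G_AA = one(GAu * GAu, "G_AA"),
       G_AD = one(GAu * GDu, "G_AD"),
       G_DD = one(GDu * GDu, "G_DD"))
}

#' Ridge-adjust a kernel to positive definiteness
#'
#' If the smallest eigenvalue is below `threshold`, a diagonal ridge is
#' added, starting at `ridge` and escalating tenfold up to `max_ridge`,
#' until the adjusted matrix is comfortably invertible. The result carries
#' `psd_adjusted = TRUE` and the adjustment is reported with a message.
#'
#' @param K a [relationship_matrix()] (or plain symmetric matrix).
#' @param ridge starting ridge (default 1e-6).
#' @param threshold minimum acceptable smallest eigenvalue (default 1e-8).
#' @param max_ridge largest ridge tried before giving up (default 1e-2).
#' @return The (possibly adjusted) matrix, same class and kind.
#' @export
ensure_psd <- function(K, ridge = 1e-6, threshold = 1e-8, max_ridge = 1e-2) {
  ev_min <- min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= threshold) return(K)
  r <- ridge
  while (ev_min + r < max(threshold, r / 2) && r < max_ridge) r <- r * 10
  if (ev_min + r < threshold)
    stop("could not reach positive definiteness with ridge <= ", max_ridge)
  message(sprintf("ensure_psd: min eigenvalue %.3g; added ridge %.1e to %s",
                  ev_min, r, attr(K, "kind") %||% "matrix"))
  out <- unclass(K)
  diag(out) <- diag(out) + r
  if (inherits(K, "RelationshipMatrix"))
    relationship_matrix(out, attr(K, "kind"), ids = rownames(K),
                        psd_adjusted = TRUE, scaling = attr(K, "scaling"))
  else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the full set of kernels for a study
#'
#' Convenience constructor producing every relationship matrix needed by
#' the PBLUP/GBLUP model family, all on a shared id ordering.
#'
#' @param ped a [pedigree()] (for kinds `A`, `D`); may be `NULL` if only
#'   genomic kinds are requested.
#' @param geno a [genotype_matrix()] (for the genomic kinds); may be `NULL`.
#' @param kinds character vector of kinds to build (default: all that the
#'   supplied inputs allow).
#' @param ids optional id subset/ordering applied to every kernel (e.g.
#'   progeny only); defaults to the genotype ids if available, else the
#'   pedigree ids.
#' @param psd logical; ridge-adjust genomic kernels for invertibility
#'   (default TRUE).
#' @return Named list of [relationship_matrix()] objects.
#' @export
kernel_set <- function(ped = NULL, geno = NULL, kinds = NULL, ids = NULL,
                       psd = TRUE) {
  avail <- c(if (!is.null(ped)) c("A", "D"),
             if (!is.null(geno)) c("G_A", "G_D", "G_AA", "G_AD", "G_DD"))
  if (is.null(kinds)) kinds <- avail
  if (length(setdiff(kinds, avail)))
    stop("cannot build kinds ", paste(setdiff(kinds, avail), collapse = ", "),
         " from the supplied inputs")
  out <- list()
  if (any(c("A", "D") %in% kinds)) {
    A <- pedigree_additive(ped)
    if ("A" %in% kinds) out$A <- A
    if ("D" %in% kinds) out$D <- pedigree_dominance(ped, A)
  }
  if (any(c("G_A", "G_AA", "G_AD") %in% kinds)) GA <- genomic_additive(geno)
  if (any(c("G_D", "G_DD", "G_AD") %in% kinds)) GD <- genomic_dominance(geno)
  if ("G_A" %in% kinds) out$G_A <- GA
  if ("G_D" %in% kinds) out$G_D <- GD
  if (any(c("G_AA", "G_AD", "G_DD") %in% kinds)) {
    ep <- epistatic_kernels(GA, GD)
    for (k in intersect(c("G_AA", "G_AD", "G_DD"), kinds)) out[[k]] <- ep[[k]]
  }
  if (!is.null(ids)) {
    out <- lapply(out, function(K) {
      if (length(setdiff(ids, rownames(K))))
        stop("requested ids absent from kernel ", attr(K, "kind"))
      relationship_matrix(unclass(K)[ids, ids], attr(K, "kind"), ids = ids,
                          psd_adjusted = attr(K, "psd_adjusted"),
                          scaling = attr(K, "scaling"))
    })
  }
  if (psd) {
    genomic <- intersect(names(out), c("G_A", "G_D", "G_AA", "G_AD", "G_DD"))
    out[genomic] <- lapply(out[genomic], ensure_psd)
  }
  out
}
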