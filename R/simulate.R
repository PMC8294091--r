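#' Simulation configuration for a partial-diallel study
#'
#' Defaults emulate the study design this package targets: 40 founder
#' parents crossed in a partial diallel giving 184 full-sib families and
#' 695 progeny, genotyped at 6,344 unlinked SNPs whose founder alternative
#' allele frequencies are drawn uniformly on
#' `[founder_freq_min, founder_freq_max]`.
#'
#' @param n_parents number of founder parents (default 40).
#' @param n_families number of distinct full-sib families (default 184);
#'   must not exceed `n_parents * (n_parents - 1) / 2`.
#' @param n_progeny total progeny across families (default 695); family
#'   sizes are balanced (they differ by at most one).
#' @param n_loci number of unlinked biallelic loci (default 6344).
#' @param founder_freq_min,founder_freq_max bounds of the uniform law for
#'   founder alternative-allele frequencies (defaults 0.05, 0.95).
#' @param maf_floor minor allele frequency floor applied when realized
#'   frequencies are filtered downstream (default 0.01).
#' @param variance_targets named numeric vector
#'   `c(add, dom, aa, ad, dd, residual)` of target variance components on
#'   the trait scale (defaults emulate a growth trait with additive,
#'   additive-by-additive and residual variation: 300, 0, 140, 0, 0, 1360).
#' @param trait_mean phenotype-scale population mean (default 100).
#' @param seed integer seed; every simulation function derives its RNG
#'   state deterministically from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_parents = 40, n_families = 184, n_progeny = 695,
                       n_loci = 6344,
                       founder_freq_min = 0.05, founder_freq_max = 0.95,
                       maf_floor = 0.01,
                       variance_targets = c(add = 300, dom = 0, aa = 140,
                                            ad = 0, dd = 0, residual = 1360),
                       trait_mean = 100, seed = 1L) {
  stopifnot(n_parents >= 2, n_families >= 1, n_progeny >= n_families,
            n_loci >= 1, founder_freq_min > 0, founder_freq_max < 1,
            founder_freq_min <= founder_freq_max)
  if (n_families > n_parents * (n_parents - 1) / 2)
    stop("n_families exceeds the number of distinct parent pairs")
  req <- c("add", "dom", "aa", "ad", "dd", "residual")
  if (!all(req %in% names(variance_targets)))
    stop("variance_targets must name: ", paste(req, collapse = ", "))
  variance_targets <- variance_targets[req]
  if (any(variance_targets < 0)) stop("variance targets must be >= 0")
  structure(list(n_parents = as.integer(n_parents),
                 n_families = as.integer(n_families),
                 n_progeny = as.integer(n_progeny),
                 n_loci = as.integer(n_loci),
                 founder_freq_min = founder_freq_min,
                 founder_freq_max = founder_freq_max,
                 maf_floor = maf_floor,
                 variance_targets = variance_targets,
                 trait_mean = trait_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a partial-diallel pedigree
#'
#' Samples `n_families` distinct unordered parent pairs among the founders
#' and allocates `n_progeny` to them as evenly as possible (sizes differ by
#' at most one; the families receiving the extra progeny are the first in
#' sampled order).
#'
#' @param config a [sim_config()].
#' @return A [pedigree()] with founders `P001...` first and progeny
#'   `F1_0001...` after, carrying a `families` attribute (data.frame of
#'   sire, dam, size).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_parents
  parents <- sprintf("P%03d", seq_len(np))
  pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  take <- sample.int(nrow(pairs), config$n_families)
  fam <- data.frame(sire = parents[pairs[take, 1L]],
                    dam  = parents[pairs[take, 2L]],
                    stringsAsFactors = FALSE)
  base <- config$n_progeny %/% config$n_families
  extra <- config$n_progeny %% config$n_families
  fam$size <- base + as.integer(seq_len(config$n_families) <= extra)
  progeny <- sprintf("F1_%04d", seq_len(config$n_progeny))
  ped <- pedigree(id = c(parents, progeny),
                  sire = c(rep(NA, np), rep(fam$sire, fam$size)),
                  dam  = c(rep(NA, np), rep(fam$dam, fam$size)))
  attr(ped, "families") <- fam
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder genotypes are drawn per locus as two independent alleles at the
#' locus's founder frequency; each progeny receives one allele from each
#' parent, the transmitted allele chosen uniformly at random per parent and
#' locus (loci unlinked). Founder frequencies are drawn uniformly on the
#' configured interval.
#'
#' @param ped a topologically ordered [pedigree()].
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] (no MAF filtering applied here; realized
#'   monomorphic loci, if any, are retained and must be filtered before
#'   kernel construction).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "Pedigree"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(ped)
  m <- config$n_loci
  pfound <- stats::runif(m, config$founder_freq_min, config$founder_freq_max)
  idx <- seq_len(n)
  names(idx) <- ped$id
  calls <- matrix(0L, n, m, dimnames = list(ped$id, sprintf("snp%05d", 1:m)))
  founder <- is_founder(ped)
  nf <- sum(founder)
  calls[founder, ] <- matrix(stats::rbinom(nf * m, 2L, rep(pfound, each = nf)),
                             nf, m)
  # one allele from each parent; heterozygous parents transmit either
  # allele with probability 1/2
  transmit <- function(g) {
    (g == 2L) + (g == 1L) * (stats::runif(length(g)) < 0.5)
  }
  for (i in which(!founder)) {
    gs <- calls[idx[ped$sire[i]], ]
    gd <- calls[idx[ped$dam[i]], ]
    calls[i, ] <- transmit(gs) + transmit(gd)
  }
  genotype_matrix(calls)
}

#' Simulate adjusted phenotypes with a specified genetic architecture
#'
#' Draws the additive, dominance, and epistatic genetic values jointly from
#' zero-mean multivariate normal laws with covariances
#' `s2_add * G_A`, `s2_dom * G_D`, `s2_aa * G_AA`, `s2_ad * G_AD`,
#' `s2_dd * G_DD` (mutually independent), computed from the simulated
#' genotypes of the phenotyped individuals, adds i.i.d. residual noise, and
#' assembles `phenotype = trait_mean + add + dom + aa + ad + dd + residual`
#' exactly. Because the generating covariances are the same kernels the
#' GBLUP models fit, parameter recovery is well-posed.
#'
#' @param geno a [genotype_matrix()] covering at least the phenotyped ids.
#' @param ped the [pedigree()]; phenotypes are generated for the progeny.
#' @param config a [sim_config()].
#' @param ids individuals to phenotype (default: the non-founders).
#' @return A list with `phenotypes` (data.frame id, trait), `truth`
#'   (data.frame of the drawn components per individual) and
#'   `realized_variance` (named sample variances of each component).
#' @export
simulate_phenotypes <- function(geno, ped, config, ids = NULL) {
  stopifnot(inherits(geno, "GenotypeMatrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(ids)) ids <- ped$id[!is_founder(ped)]
  vt <- config$variance_targets
  sub <- genotype_matrix(geno$calls[ids, , drop = FALSE],
                         maf_threshold = config$maf_floor)
  n <- length(ids)
  comp <- matrix(0, n, 5,
                 dimnames = list(ids, c("add", "dom", "aa", "ad", "dd")))
  need_GA <- any(vt[c("add", "aa", "ad")] > 0)
  need_GD <- any(vt[c("dom", "ad", "dd")] > 0)
  GA <- if (need_GA) genomic_additive(sub) else NULL
  GD <- if (need_GD) genomic_dominance(sub) else NULL
  kernels <- list(add = GA, dom = GD)
  if (any(vt[c("aa", "ad", "dd")] > 0)) {
    ep <- epistatic_kernels(GA %||% genomic_additive(sub),
                            GD %||% genomic_dominance(sub))
    kernels[c("aa", "ad", "dd")] <- ep
  }
  # ridge-adjust only the kernels actually drawn from
  for (k in names(kernels))
    if (!is.null(kernels[[k]]) && vt[[k]] > 0)
      kernels[[k]] <- ensure_psd(kernels[[k]])
  for (k in c("add", "dom", "aa", "ad", "dd")) {
    if (vt[[k]] > 0) {
      U <- chol(unclass(kernels[[k]]))
      comp[, k] <- sqrt(vt[[k]]) * drop(crossprod(U, stats::rnorm(n)))
    }
  }
  resid <- stats::rnorm(n, 0, sqrt(vt[["residual"]]))
  y <- config$trait_mean + rowSums(comp) + resid
  truth <- data.frame(id = ids, comp, residual = resid, phenotype = y,
                      stringsAsFactors = FALSE)
  realized <- c(apply(comp, 2, stats::var), residual = stats::var(resid))
  list(phenotypes = data.frame(id = ids, trait = y, stringsAsFactors = FALSE),
       truth = truth,
       realized_variance = realized)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return List with `pedigree`, `genotypes`, `phenotypes`, `truth`,
#'   `realized_variance`, and the `config` used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(geno, ped, config)
  list(pedigree = ped, genotypes = geno, phenotypes = ph$phenotypes,
       truth = ph$truth, realized_variance = ph$realized_variance,
       config = config)
}
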