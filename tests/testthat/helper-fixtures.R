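# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a small but structured diallel dataset with additive + epistatic signal
small_study <- function() {
  fixture("small_study", function() {
    cfg <- sim_config(n_parents = 12, n_families = 24, n_progeny = 240,
                      n_loci = 600, seed = 42,
                      variance_targets = c(add = 300, dom = 0, aa = 140,
                                           ad = 0, dd = 0, residual = 1360))
    dat <- simulate_dataset(cfg)
    ids <- dat$phenotypes$id
    ks <- suppressWarnings(suppressMessages(
      kernel_set(ped = dat$pedigree, geno = dat$genotypes, ids = ids)))
    dat$kernels <- ks
    dat$y <- stats::setNames(dat$phenotypes$trait, ids)
    dat
  })
}

# a random multi-generation pedigree (founders + two descendant layers),
# guaranteed free of half-parent records
random_pedigree <- function(n_founders = 12, n_gen = 4, per_gen = 12,
                            seed = 99) {
  set.seed(seed)
  id <- sprintf("G0_%02d", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  pool <- id
  for (g in seq_len(n_gen)) {
    for (i in seq_len(per_gen)) {
      par <- sample(pool, 2)
      id <- c(id, sprintf("G%d_%02d", g, i))
      sire <- c(sire, par[1])
      dam <- c(dam, par[2])
    }
    pool <- c(pool, utils::tail(id, per_gen))
  }
  pedigree(id, sire, dam)
}
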