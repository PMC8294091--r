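test_that("pedigree A: founders, full sibs, selfing", {
  founders <- pedigree(c("a", "b", "c"), rep(NA, 3), rep(NA, 3))
  expect_equal(unclass(pedigree_additive(founders)), diag(3),
               ignore_attr = TRUE)

  ped <- pedigree(c("g", "h", "i", "j", "s"),
                  c(NA, NA, "g", "g", "g"),
                  c(NA, NA, "h", "h", "g"))
  A <- suppressWarnings(pedigree_additive(ped))
  expect_equal(A["i", "j"], 0.5)          # full sibs, unrelated parents
  expect_equal(A["s", "s"], 1.5)          # selfed offspring of g
  expect_equal(A["i", "i"], 1)
})

test_that("pedigree A equals twice the recursive kinship oracle", {
  ped <- random_pedigree(n_founders = 12, n_gen = 4, per_gen = 12, seed = 7)
  expect_identical(nrow(ped), 60L)
  A <- suppressWarnings(pedigree_additive(ped))
  expect_equal(unclass(A), kinship_oracle(ped), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pedigree D: full sibs 0.25, half sibs 0, founders 0", {
  ped <- pedigree(c("g", "h", "l", "i", "j", "k"),
                  c(NA, NA, NA, "g", "g", "g"),
                  c(NA, NA, NA, "h", "h", "l"))
  D <- pedigree_dominance(ped)
  expect_equal(D["i", "j"], 0.25)   # full sibs
  expect_equal(D["i", "k"], 0)      # half sibs (share g only)
  expect_equal(D["g", "i"], 0)      # founder pair member
  expect_true(all(diag(unclass(D)) == 1))
})

test_that("pedigree D matches direct formula evaluation on a
           double-first-cousin pedigree", {
  # two sib pairs from unrelated founders, crossed so that the cousins
  # share both parental sibships
  ped <- pedigree(
    c("f1", "f2", "f3", "f4", "s1", "s2", "d1", "d2", "c1", "c2"),
    c(NA, NA, NA, NA, "f1", "f1", "f3", "f3", "s1", "s2"),
    c(NA, NA, NA, NA, "f2", "f2", "f4", "f4", "d1", "d2"))
  A <- suppressWarnings(pedigree_additive(ped))
  D <- suppressWarnings(pedigree_dominance(ped, A))
  expect_equal(unclass(D), dominance_oracle(ped, unclass(A)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(D["c1", "c2"], (0.5 * 0.5 + 0 * 0) / 4)  # 1/16
})

test_that("A and D entries are dyadic rationals on non-inbred pedigrees", {
  ped <- pedigree(c("a", "b", "c", "d", "x", "y", "z"),
                  c(NA, NA, NA, NA, "a", "a", "x"),
                  c(NA, NA, NA, NA, "b", "c", "y"))
  A <- pedigree_additive(ped)
  D <- suppressWarnings(pedigree_dominance(ped, A))
  expect_true(all(unclass(A) * 2^10 == round(unclass(A) * 2^10)))
  expect_true(all(unclass(D) * 2^10 == round(unclass(D) * 2^10)))
})

test_that("genomic additive matrix matches the hand-computed example", {
  g <- genotype_matrix(rbind(a = 0L, b = 2L))  # one locus, p = 0.5
  GA <- genomic_additive(g)
  expect_equal(unclass(GA), rbind(c(2, -2), c(-2, 2)), ignore_attr = TRUE)
  expect_equal(attr(GA, "scaling"), 0.5)

  # identical calls everywhere: monomorphic, hard error
  mono <- genotype_matrix(rbind(a = c(2L, 2L), b = c(2L, 2L)))
  expect_error(genomic_additive(mono), "monomorphic")
})

test_that("genomic dominance matrix matches the hand-computed example", {
  g <- genotype_matrix(rbind(a = 1L, b = 0L))  # one locus, p = 0.25
  GD <- genomic_dominance(g)
  expect_equal(unclass(GD), rbind(c(1, -1 / 3), c(-1 / 3, 1 / 9)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(GD, "scaling"), 0.140625)
})

test_that("dominance design column means vanish at exact HWE proportions", {
  # 25 / 50 / 25 genotypes at p = 0.5: counts match p^2, 2pq, q^2 exactly
  calls <- matrix(rep(c(0L, 1L, 2L), times = c(25, 50, 25)), ncol = 1)
  g <- genotype_matrix(calls)
  p <- g$p
  w <- ifelse(calls == 2, -2 * (1 - p)^2,
              ifelse(calls == 1, 2 * p * (1 - p), -2 * p^2))
  expect_equal(mean(w), 0, tolerance = 1e-15)
})

test_that("G_A and G_D have mean diagonal near 1 in an HWE population", {
  set.seed(77)
  g <- hwe_genotypes(500, runif(2000, 0.1, 0.9))
  expect_lt(abs(mean(diag(unclass(genomic_additive(g)))) - 1), 0.03)
  expect_lt(abs(mean(diag(unclass(genomic_dominance(g)))) - 1), 0.05)
})

test_that("genomic kernels are invariant to reference/alternative swaps", {
  set.seed(78)
  g <- hwe_genotypes(30, runif(100, 0.2, 0.8))
  flip <- sample(100, 40)
  calls2 <- g$calls
  calls2[, flip] <- 2L - calls2[, flip]
  g2 <- genotype_matrix(calls2)
  expect_equal(unclass(genomic_additive(g)), unclass(genomic_additive(g2)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(genomic_dominance(g)),
               unclass(genomic_dominance(g2)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("epistatic kernels: identity, hand example, trace normalization", {
  I5 <- relationship_matrix(diag(5), "G_A")
  I5d <- relationship_matrix(diag(5), "G_D")
  ep <- epistatic_kernels(I5, I5d)
  for (k in names(ep))
    expect_equal(unclass(ep[[k]]), diag(5), ignore_attr = TRUE)

  GA <- relationship_matrix(rbind(c(2, -2), c(-2, 2)), "G_A")
  ep2 <- epistatic_kernels(GA, relationship_matrix(diag(2), "G_D"))
  expect_equal(unclass(ep2$G_AA), matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("epistatic kernels equal the double-loop oracle on random input", {
  set.seed(83)
  GA <- crossprod(matrix(rnorm(400), 20))
  GD <- crossprod(matrix(rnorm(400), 20))
  ids <- sprintf("i%02d", 1:20)
  ep <- epistatic_kernels(relationship_matrix(GA, "G_A", ids),
                          relationship_matrix(GD, "G_D", ids))
  oracle <- function(P, Q) {
    H <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) H[i, j] <- P[i, j] * Q[i, j]
    H / (sum(diag(H)) / 20)
  }
  expect_equal(unclass(ep$G_AA), oracle(GA, GA), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(ep$G_AD), oracle(GA, GD), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(ep$G_DD), oracle(GD, GD), ignore_attr = TRUE,
               tolerance = 1e-12)
  for (k in names(ep))
    expect_lt(abs(sum(diag(unclass(ep[[k]]))) - 20) / 20, 1e-8)
})

test_that("ensure_psd leaves PD matrices alone and repairs deficient ones", {
  I3 <- relationship_matrix(diag(3), "A")
  out <- ensure_psd(I3)
  expect_false(attr(out, "psd_adjusted"))
  expect_equal(unclass(out), diag(3), ignore_attr = TRUE)

  ones <- relationship_matrix(matrix(1, 3, 3), "G_A")
  fixed <- suppressMessages(ensure_psd(ones))
  expect_true(attr(fixed, "psd_adjusted"))
  ev <- eigen(unclass(fixed), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6 * (1 - 1e-9))

  # rank-deficient G from more individuals than loci becomes invertible
  set.seed(91)
  g <- hwe_genotypes(10, runif(5, 0.3, 0.7))
  G <- suppressMessages(ensure_psd(genomic_additive(g)))
  expect_true(attr(G, "psd_adjusted"))
  expect_no_error(solve(unclass(G)))
})

test_that("kernel_set builds consistent, id-aligned kernels", {
  dat <- small_study()
  ks <- dat$kernels
  expect_setequal(names(ks), c("A", "D", "G_A", "G_D", "G_AA", "G_AD",
                               "G_DD"))
  for (k in names(ks))
    expect_identical(rownames(ks[[k]]), dat$phenotypes$id)
  expect_true(all(diag(unclass(ks$D)) == 1))
})
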