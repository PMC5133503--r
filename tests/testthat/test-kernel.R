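test_that("boundary-mixture p-values match the closed forms", {
  expect_equal(mixturePvalue(2.706), 0.05, tolerance = 1e-4 / 0.05)
  expect_equal(mixturePvalue(3.841), 0.025, tolerance = 1e-4 / 0.025)
  expect_equal(mixturePvalue(0), 1)
  expect_true(all(mixturePvalue(c(0.001, 1, 10)) <= 0.5))
  expect_error(mixturePvalue(-1), "negative")
})

test_that("the local kinship kernel reflects genotype sharing", {
  sim <- smallSim(seed = 51, nPed = 3, total = 60, varFrac = NA,
                  region = list(m = 12, varFrac = 0, nCausal = 0))
  gr <- range(variants(sim$genos)[grep("region",
                                       names(variants(sim$genos)))])
  names(gr) <- "reg"
  gk <- buildLocalKinship(sim$genos, gr)
  expect_equal(gk@m, 12L)
  K <- kernelMatrix(gk)
  # duplicated genotypes give identical kernel rows
  D <- dosages(sim$genos)
  i <- rownames(D)[1]
  D2 <- D
  D2[2, grep("region", colnames(D))] <- D2[1, grep("region", colnames(D))]
  g2 <- GenotypeMatrix(D2, variants(sim$genos))
  K2 <- kernelMatrix(buildLocalKinship(g2, gr))
  expect_equal(unname(K2[1, -(1:2)]), unname(K2[2, -(1:2)]),
               tolerance = 1e-10)

  # invariant to variant order and to REF/ALT flips
  idx <- grep("region", colnames(D))
  D3 <- D[, c(setdiff(seq_len(ncol(D)), idx), rev(idx))]
  g3 <- GenotypeMatrix(D3, variants(sim$genos)[colnames(D3)])
  expect_equal(kernelMatrix(buildLocalKinship(g3, gr)), K, tolerance = 1e-12)
  D4 <- D
  D4[, idx[1:4]] <- 2 - D4[, idx[1:4]]
  g4 <- GenotypeMatrix(D4, variants(sim$genos))
  expect_equal(kernelMatrix(buildLocalKinship(g4, gr)), K, tolerance = 1e-12)
})

test_that("kernel construction rejects empty or monomorphic regions", {
  sim <- smallSim(seed = 52, nPed = 2, total = 30)
  empty <- GenomicRanges::GRanges("22", IRanges::IRanges(1, 2))
  expect_error(buildLocalKinship(sim$genos, empty), "no variants")
  D <- dosages(sim$genos)
  D[, ] <- 0
  gmono <- GenotypeMatrix(D, variants(sim$genos))
  expect_error(buildLocalKinship(gmono), "monomorphic")
})

test_that("unrelated founders at HWE give near-zero mean relatedness", {
  set.seed(9)
  n <- 150
  m <- 2000
  ped <- singletonPed(n)
  p <- runif(m, 0.1, 0.5)
  D <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(D) <- pedIds(ped)
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(seq_len(m) * 10, width = 1))
  names(gr) <- paste0("v", seq_len(m))
  gk <- buildLocalKinship(GenotypeMatrix(D, gr))
  K <- kernelMatrix(gk)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.01)
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
})

test_that("gene-centric models nest and produce valid mixture p-values", {
  sim <- smallSim(seed = 53, nPed = 4, total = 120, varFrac = NA,
                  region = list(m = 20, varFrac = 0.1, nCausal = 4))
  gr <- range(variants(sim$genos)[grep("region",
                                       names(variants(sim$genos)))])
  names(gr) <- "reg"
  gk <- buildLocalKinship(sim$genos, gr)
  res <- geneCentricTest(gk, sim$phen, sim$ped, covariates = NULL,
                         model = c("single", "average", "constrained",
                                   "unconstrained"))
  expect_equal(nrow(res), 4L)
  expect_true(all(res$llAlt >= res$llNull - 1e-6))
  # free per-trait kernel loadings nest the shared ones
  expect_gte(res$llAlt[res$model == "unconstrained"],
             res$llAlt[res$model == "constrained"] - 1e-6)
  expect_true(all(res$h2geff >= 0 & res$h2geff <= 1))
  one <- res$model != "unconstrained"
  expect_true(all(res$df[one] == 1))
  expect_equal(res$df[res$model == "unconstrained"], 3)
  expect_true(all(res$p[res$stat > 0 & one] <= 0.5))
})

test_that("under a null region the statistic has boundary mass at zero", {
  hits0 <- 0
  nrep <- 40
  for (s in seq_len(nrep)) {
    sim <- smallSim(seed = 600 + s, nPed = 4, total = 120, varFrac = NA,
                    region = list(m = 15, varFrac = 0, nCausal = 0))
    gr <- range(variants(sim$genos)[grep("region",
                                         names(variants(sim$genos)))])
    names(gr) <- "reg"
    gk <- buildLocalKinship(sim$genos, gr)
    res <- geneCentricTest(gk, sim$phen, sim$ped, covariates = NULL,
                           model = "average")
    if (res$stat < 1e-6) hits0 <- hits0 + 1
    expect_true(res$p == 1 || res$p <= 0.5)
  }
  # asymptotically half the null fits sit on the boundary
  expect_gt(hits0 / nrep, 0.25)
})

test_that("the regional variance estimate grows with the simulated signal", {
  levels <- c(0.0, 0.06, 0.15)
  means <- sapply(seq_along(levels), function(li) {
    v <- levels[li]
    est <- sapply(1:12, function(s) {
      sim <- smallSim(seed = 700 + 40 * li + s, nPed = 4, total = 160,
                      varFrac = NA,
                      region = list(m = 15, varFrac = v,
                                    nCausal = if (v > 0) 3 else 0))
      gr <- range(variants(sim$genos)[grep("region",
                                           names(variants(sim$genos)))])
      names(gr) <- "reg"
      gk <- buildLocalKinship(sim$genos, gr)
      geneCentricTest(gk, sim$phen, sim$ped, covariates = NULL,
                      model = "average")$h2geff
    })
    mean(est)
  })
  expect_true(all(diff(means) > 0))
})
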