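test_that("the default pedigree preset matches the study design", {
  ped <- simPedigrees(seed = 1)
  df <- pedData(ped)
  expect_equal(length(unique(df$famid)), 20L)
  expect_equal(nrow(df), 849L)
  # 3-4 generations: a grandchild of a founder exists in every family
  depth <- function(sub) {
    g <- setNames(rep(1L, nrow(sub)), sub$id)
    for (i in seq_len(nrow(sub)))
      if (!is.na(sub$father[i]))
        g[sub$id[i]] <- g[sub$father[i]] + 1L
    max(g)
  }
  depths <- vapply(split(df, df$famid), depth, integer(1))
  expect_true(all(depths >= 3))
  expect_true(all(depths <= 4))
})

test_that("pedigree generation is deterministic given the seed", {
  p1 <- simPedigrees(5, 80, seed = 3)
  p2 <- simPedigrees(5, 80, seed = 3)
  expect_identical(pedData(p1), pedData(p2))
})

test_that("trio-sized templates give all-founder parents", {
  ped <- simPedigrees(5, 15, seed = 2)
  expect_equal(length(pedIds(ped)), 15L)
  expect_equal(length(founders(ped)), 10L)
})

test_that("gene dropping obeys Mendelian transmission and frequencies", {
  ped <- singletonPed(40)
  d <- geneDrop(ped, maf = 0.5, n = 5000, seed = 4)
  expect_equal(mean(d), 1, tolerance = 3 * sqrt(0.5 / (40 * 5000)) * 2)

  # child dosage is consistent with parental alleles: a parent with
  # dosage 0 cannot transmit the alternate allele
  fam <- trioPed()
  dd <- geneDrop(fam, maf = 0.3, n = 3000, seed = 5)
  expect_true(all(dd["kid", dd["dad", ] == 0 & dd["mum", ] == 0] == 0))
  expect_true(all(dd["kid", dd["dad", ] == 2 & dd["mum", ] == 2] == 2))
  expect_true(all(dd["kid", ] >= (dd["dad", ] == 2) + (dd["mum", ] == 2)))

  # full sibs share half their alleles on average: dosage correlation ~ 0.5
  sib <- Pedigree(rep("s", 4), c("f", "m", "a", "b"),
                  c(NA, NA, "f", "f"), c(NA, NA, "m", "m"),
                  c("1", "2", "1", "2"))
  ds <- geneDrop(sib, maf = 0.3, n = 10000, seed = 6)
  expect_equal(cor(ds["a", ], ds["b", ]), 0.5, tolerance = 0.05)
})

test_that("variant effects follow the variance-fraction formula", {
  cfg <- simConfig(causal = data.frame(maf = 0.2, varFrac = 0.0278))
  beta <- longvc:::.truthBetas(cfg)
  expect_equal(unname(beta["causal_1"]),
               sqrt(0.0278 / (2 * 0.2 * 0.8)), tolerance = 1e-12)
  expect_equal(unname(beta["causal_1"]), 0.295, tolerance = 0.002)
})

test_that("infeasible configurations are rejected", {
  expect_error(simConfig(causal = data.frame(maf = 0.2, varFrac = 0.7),
                         h2 = 0.4), "variance budget")
  expect_error(simConfig(causal = data.frame(maf = 0.7, varFrac = 0.01)),
               "maf")
  expect_error(simPedigrees(5, 10), "trio")
})

test_that("simulated variance decomposition matches the configuration", {
  # empirical R2 of trait on a causal dosage ~ configured fraction
  v <- 0.08
  set.seed(99)
  r2 <- replicate(25, {
    sim <- smallSim(seed = sample.int(1e6, 1), nPed = 4, total = 200,
                    varFrac = v, maf = 0.3)
    y <- traitMatrix(sim$phen)[, 1]
    g <- dosages(sim$genos)[, "causal_1"]
    summary(lm(y ~ g))$r.squared
  })
  expect_equal(mean(r2), v, tolerance = 0.2)  # Monte-Carlo slack, 25 draws

  # polygenic + environmental share: total phenotypic variance ~ sigma2Total
  sim <- smallSim(seed = 13, nPed = 8, total = 480, varFrac = NA, h2 = 0.4)
  vtot <- var(traitMatrix(sim$phen)[, 1]) /
    (1 + 0.3^2 * 0.25 + 0.25^2 * 0.16)  # minus covariate contributions
  expect_equal(unname(vtot), 1, tolerance = 0.35)
})

test_that("replicates are byte-identical under the same seed", {
  cfg <- simConfig(nPedigrees = 2, totalSize = 40,
                   causal = data.frame(maf = 0.3, varFrac = 0.05))
  a <- simReplicate(cfg, seed = 123)
  b <- simReplicate(cfg, seed = 123)
  expect_identical(traitMatrix(a$phen), traitMatrix(b$phen))
  expect_identical(dosages(a$genos), dosages(b$genos))
  expect_identical(a$truth$beta, b$truth$beta)
})

test_that("visits are exchangeable when parameters are time-constant", {
  cfg <- simConfig(nPedigrees = 4, totalSize = 120, mu = c(0, 0, 0),
                   causal = data.frame(maf = numeric(0),
                                       varFrac = numeric(0)),
                   nullVariants = 1, rhoG = 1, rhoE = 0.4)
  rep <- simReplicate(cfg, seed = 55)
  f1 <- fitVC(rep$phen, rep$ped)
  Yp <- traitMatrix(rep$phen)[, c(2, 3, 1)]
  php <- LongPhenotypes(Yp, covariates = covariates(rep$phen),
                        pedigree = rep$ped)
  f2 <- fitVC(php, rep$ped)
  expect_equal(logLik(f1), logLik(f2), tolerance = 1e-3)
})
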