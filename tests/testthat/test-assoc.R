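test_that("chi-square LRT p-values match the textbook quantiles", {
  expect_equal(lrtPvalue(3.841, 1), 0.05, tolerance = 1e-4 / 0.05)
  expect_equal(lrtPvalue(7.815, 3), 0.05, tolerance = 1e-4 / 0.05)
  expect_equal(lrtPvalue(0, 1), 1)
  expect_equal(lrtPvalue(-1e-8, 1), 1)  # optimizer slack clipped
  expect_error(lrtPvalue(-0.5, 1), "negative")
})

test_that("identical repeated measurements reduce the average test to a single visit", {
  sim <- smallSim(seed = 21, nPed = 3, total = 75, k = 1, varFrac = 0.08)
  y <- traitMatrix(sim$phen)[, 1]
  Y3 <- cbind(y, y, y)
  rownames(Y3) <- names(y)
  ph3 <- LongPhenotypes(Y3, covariates = covariates(sim$phen),
                        pedigree = sim$ped)
  r3 <- assocTest(sim$genos, ph3, sim$ped, covariates = NULL,
                  tests = "average", variantIds = "causal_1")
  r1 <- assocTest(sim$genos, sim$phen, sim$ped, covariates = NULL,
                  tests = "average", variantIds = "causal_1")
  expect_equal(r3$stat, r1$stat, tolerance = 1e-5)
  expect_equal(r3$beta, r1$beta, tolerance = 1e-4)
})

test_that("p-values are invariant to allele-label flips", {
  sim <- smallSim(seed = 23, nPed = 3, total = 90, varFrac = 0.06)
  r1 <- assocTest(sim$genos, sim$phen, sim$ped, covariates = NULL,
                  variantIds = "causal_1")
  flipped <- sim$genos
  flipped@dosage[, "causal_1"] <- 2 - flipped@dosage[, "causal_1"]
  r2 <- assocTest(flipped, sim$phen, sim$ped, covariates = NULL,
                  variantIds = "causal_1")
  for (tst in c("constrained", "unconstrained", "average")) {
    expect_equal(r1$p[r1$test == tst], r2$p[r2$test == tst],
                 tolerance = 1e-4)
  }
  expect_equal(r1$beta[r1$test == "constrained"],
               -r2$beta[r2$test == "constrained"], tolerance = 1e-3)
})

test_that("monomorphic variants yield a flagged p = 1 row, not an error", {
  sim <- smallSim(seed = 25, nPed = 2, total = 40)
  mono <- sim$genos
  mono@dosage[, "null_1"] <- 0
  r <- assocTest(mono, sim$phen, sim$ped, covariates = NULL,
                 variantIds = "null_1")
  expect_equal(nrow(r), 3L)
  expect_true(all(r$p == 1))
  expect_true(all(r$flag == "monomorphic"))
})

test_that("covariate screening keeps real effects and drops null ones", {
  # strong sex effect (~5% of variance at sd 0.45), zero smoking effect
  cfg <- simConfig(nPedigrees = 20, totalSize = 850,
                   causal = data.frame(maf = numeric(0),
                                       varFrac = numeric(0)),
                   nullVariants = 1, sexEffect = 0.45, smokeEffect = 0,
                   ageEffect = 0)
  rep <- simReplicate(cfg, seed = 77)
  sc <- screenCovariates(rep$phen, rep$ped)
  expect_true(sc$selected[sc$candidate == "sex"])
  expect_false(sc$selected[sc$candidate == "smoke"])
  expect_true("sex" %in% colnames(attr(sc, "matrix")))

  # a candidate identical to the trait is degenerate but legal: p ~ 0
  cand <- cbind(self = rowMeans(traitMatrix(rep$phen)))
  rownames(cand) <- rownames(traitMatrix(rep$phen))
  sc2 <- screenCovariates(rep$phen, rep$ped, candidates = cand)
  expect_lt(sc2$p[1], 1e-10)

  # constant candidates are skipped with a warning
  cand2 <- cbind(flat = rep(1, nrow(cand)))
  rownames(cand2) <- rownames(cand)
  expect_warning(sc3 <- screenCovariates(rep$phen, rep$ped,
                                         candidates = cand2), "constant")
  expect_true(is.na(sc3$p[1]))
})

test_that("screening retains null candidates at roughly the nominal rate", {
  cfg <- simConfig(nPedigrees = 6, totalSize = 240,
                   causal = data.frame(maf = numeric(0),
                                       varFrac = numeric(0)),
                   nullVariants = 1, ageEffect = 0, sexEffect = 0,
                   smokeEffect = 0)
  set.seed(2)
  ped <- simPedigrees(cfg$nPedigrees, cfg$totalSize)
  phi <- kinshipMatrix(ped)
  hits <- tested <- 0
  for (r in 1:80) {
    rep <- simReplicate(cfg, seed = 2 + 7919 * r, ped = ped, phi = phi)
    cand <- as.matrix(covariates(rep$phen)[, c("age", "smoke")])
    sc <- screenCovariates(rep$phen, ped, candidates = cand)
    hits <- hits + sum(sc$selected)
    tested <- tested + sum(!is.na(sc$p))
  }
  # 160 null candidate tests at alpha = 0.05
  expect_gte(hits, qbinom(0.005, tested, 0.05))
  expect_lte(hits, qbinom(0.995, tested, 0.05))
})

test_that("replicate tallies use strict thresholds and flag missing cells", {
  pv <- data.frame(replicate = rep(1:200, 2),
                   variant = rep(c("v1", "v2"), each = 200),
                   test = "constrained",
                   p = c(rep(1e-10, 200), rep(0.5, 200)))
  tl <- tallyReplicates(pv)
  expect_equal(tl$count[tl$variant == "v1"], rep(200L, 3),
               ignore_attr = TRUE)
  expect_equal(tl$count[tl$variant == "v2"], rep(0L, 3),
               ignore_attr = TRUE)

  # a p exactly at the threshold is not counted
  pv2 <- data.frame(replicate = 1, variant = "v", test = "t", p = 1e-3)
  expect_equal(tallyReplicates(pv2, thresholds = 1e-3)$count, 0L)

  # missing replicate cells: warning, counted as non-significant
  pv3 <- data.frame(replicate = c(1, 2, 1), variant = c("a", "a", "b"),
                    test = "t", p = 1e-9)
  expect_warning(tl3 <- tallyReplicates(pv3, thresholds = 1e-3),
                 "non-significant")
  expect_equal(tl3$count[tl3$variant == "b"], 1L)
  expect_equal(tl3$replicates[1], 2L)
})

test_that("a zero-replicate study returns an empty tally without error", {
  cfg <- simConfig(nPedigrees = 2, totalSize = 20)
  st <- runStudy(cfg, nReplicates = 0, seed = 1)
  expect_equal(nrow(st$tally), 0L)
  expect_equal(st$failures, 0L)
})

test_that("study seeds make replicates reproducible end to end", {
  cfg <- simConfig(nPedigrees = 2, totalSize = 40,
                   causal = data.frame(maf = 0.3, varFrac = 0.05),
                   nullVariants = 1)
  s1 <- runStudy(cfg, tests = "constrained", nReplicates = 2, seed = 9,
                 covariates = NULL)
  s2 <- runStudy(cfg, tests = "constrained", nReplicates = 2, seed = 9,
                 covariates = NULL)
  expect_identical(s1$pvals, s2$pvals)
  s3 <- runStudy(cfg, tests = "constrained", nReplicates = 2, seed = 10,
                 covariates = NULL)
  expect_false(identical(s1$pvals$p, s3$pvals$p))
})
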