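test_that("buildCovariance reproduces closed-form cases", {
  # two unrelated individuals, k = 1, sigma_g = sigma_e = 1: Omega = 2 I
  ped2 <- singletonPed(2)
  phi <- kinshipMatrix(ped2)
  p1 <- vcParameters(sigmaG = 1, sigmaE = 1)
  expect_equal(buildCovariance(p1, phi), 2 * diag(2), ignore_attr = TRUE)

  # parent-offspring pair, k = 1: off-diagonal 2 * 0.25 * sigma_g^2
  po <- Pedigree(rep("f", 3), c("a", "b", "c"), c(NA, NA, "a"),
                 c(NA, NA, "b"), c("1", "2", "1"))
  phi3 <- kinshipMatrix(po)[c("a", "c"), c("a", "c")]
  om <- buildCovariance(vcParameters(sigmaG = 2, sigmaE = 1), phi3)
  expect_equal(om[1, 2], 2 * 0.25 * 4)

  # non-PD request errors with the offending eigenvalue
  bad <- vcParameters(G = matrix(0), E = matrix(0))
  expect_error(buildCovariance(bad, phi3[1, 1, drop = FALSE]),
               "positive definite")
})

test_that("with zero cross-time correlation the problem decouples", {
  sim <- smallSim(seed = 2, nPed = 2, total = 40, k = 2, rhoG = 0,
                  rhoE = 0, varFrac = NA)
  Y <- traitMatrix(sim$phen)
  phi <- kinshipMatrix(sim$ped)[rownames(Y), rownames(Y)]
  pars <- vcParameters(sigmaG = c(0.6, 0.7), sigmaE = c(0.8, 0.75),
                       mu = c(0, 0.1))
  joint <- vcLoglik(pars, Y, phi)
  u1 <- vcLoglik(vcParameters(sigmaG = 0.6, sigmaE = 0.8, mu = 0),
                 Y[, 1, drop = FALSE], phi)
  u2 <- vcLoglik(vcParameters(sigmaG = 0.7, sigmaE = 0.75, mu = 0.1),
                 Y[, 2, drop = FALSE], phi)
  expect_equal(joint, u1 + u2, tolerance = 1e-10)
})

test_that("log-likelihood matches a hand-computed normal density", {
  # 3 unrelated individuals, k = 1, known parameters: independent normals
  ped <- singletonPed(3)
  y <- cbind(c(1.2, -0.5, 0.3))
  rownames(y) <- pedIds(ped)
  pars <- vcParameters(sigmaG = 0.7, sigmaE = 1.1, mu = 0.2)
  ll <- vcLoglik(pars, y, kinshipMatrix(ped))
  byhand <- sum(dnorm(y, mean = 0.2, sd = sqrt(0.7^2 + 1.1^2), log = TRUE))
  expect_equal(ll, byhand, tolerance = 1e-10)
})

test_that("log-likelihood matches an independent dense MVN oracle", {
  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    k <- sample(1:3, 1)
    ped <- simPedigrees(1, n, seed = 1000 + i)
    phi <- kinshipMatrix(ped)
    G <- randPD(k, 0.6)
    E <- randPD(k, 0.9)
    Y <- matrix(rnorm(n * k), n, k, dimnames = list(pedIds(ped), NULL))
    X <- matrix(rnorm(n), n, 1, dimnames = list(pedIds(ped), "x"))
    beta <- matrix(rnorm(k), 1, k)
    g <- rbinom(n, 2, 0.3)
    mu <- rnorm(k)
    bS <- rnorm(1)
    if (i %% 3 == 0) Y[sample(n * k, max(1, n %/% 3))] <- NA  # MAR deletion
    pars <- vcParameters(G = G, E = E, mu = mu, beta = beta, betaSNV = bS)
    ll <- vcLoglik(pars, Y, phi, X = X, g = g)
    oracle <- denseLoglikOracle(Y, phi, G, E, mu = mu, X = X, beta = beta,
                                g = g, betaSNV = bS)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("the fitted likelihood is reproduced by the fixed-parameter evaluator", {
  sim <- smallSim(seed = 4, nPed = 3, total = 90)
  fit <- fitVC(sim$phen, sim$ped, covariates = c("age", "sex"))
  X <- as.matrix(covariates(sim$phen)[, c("age", "sex")])
  ll <- vcLoglik(fittedParams(fit), traitMatrix(sim$phen),
                 kinshipMatrix(sim$ped), X = X)
  expect_equal(logLik(fit), ll, tolerance = 1e-6)
})

test_that("rotated and dense-matrix fitting paths agree at k = 1", {
  # the fast path diagonalizes per pedigree; the dense path builds the full
  # covariance and deletes missing cells -- both must find the same optimum
  for (s in 1:8) {
    sim <- smallSim(seed = 200 + s, nPed = 2, total = 50, k = 1,
                    varFrac = NA, rhoG = 1, rhoE = 1)
    Y <- traitMatrix(sim$phen)
    prep <- longvc:::.prepareVC(Y, NULL, sim$ped)
    fast <- longvc:::.fitEngine(prep, "none")
    prep2 <- prep
    prep2$complete <- FALSE
    slow <- longvc:::.fitEngine(prep2, "none", init = fast$theta)
    expect_equal(fast$ll, slow$ll, tolerance = 1e-6)
  }
})

test_that("boundary data (no genetic variance) reaches the iid closed form", {
  set.seed(31)
  ped <- simPedigrees(4, 200, seed = 31)  # related, but the trait is iid
  n <- 200
  y <- cbind(rnorm(n, mean = 1, sd = 2))
  rownames(y) <- pedIds(ped)
  phen <- LongPhenotypes(y, covariates = NULL)
  fit <- fitVC(phen, ped)
  # iid-normal ML: sigma2_hat = mean squared deviation
  s2 <- mean((y - mean(y))^2)
  llOLS <- -0.5 * n * (log(2 * pi * s2) + 1)
  expect_lt(abs(logLik(fit) - llOLS), 1e-3)
  expect_lt(h2(fit), 0.1)
})

test_that("model nesting is monotone in maximized likelihood", {
  for (s in 1:6) {
    sim <- smallSim(seed = 300 + s, nPed = 3, total = 90)
    g <- dosages(sim$genos)[, "causal_1"]
    res <- assocTest(sim$genos, sim$phen, sim$ped, covariates = NULL,
                     variantIds = c("causal_1", "null_1"))
    for (v in unique(res$variant)) {
      sub <- res[res$variant == v, ]
      llN <- sub$llNull[sub$test == "constrained"]
      llC <- sub$llAlt[sub$test == "constrained"]
      llU <- sub$llAlt[sub$test == "unconstrained"]
      expect_gte(llC, llN - 1e-6)
      expect_gte(llU, llC - 1e-6)
    }
  }
})

test_that("likelihood is invariant to individual order and covariate scale", {
  sim <- smallSim(seed = 17, nPed = 3, total = 75)
  X <- as.matrix(covariates(sim$phen)[, c("age", "sex")])
  f1 <- fitVC(sim$phen, sim$ped, covariates = X)
  # permute phenotype rows
  set.seed(5)
  p <- sample(nrow(traitMatrix(sim$phen)))
  Yp <- traitMatrix(sim$phen)[p, ]
  php <- LongPhenotypes(Yp, covariates = covariates(sim$phen)[p, ],
                        pedigree = sim$ped)
  f2 <- fitVC(php, sim$ped, covariates = X[p, ])
  expect_equal(logLik(f1), logLik(f2), tolerance = 1e-6)
  # rescale a covariate: logL unchanged, beta rescales inversely
  X10 <- X
  X10[, "age"] <- X10[, "age"] * 10
  f3 <- fitVC(sim$phen, sim$ped, covariates = X10)
  expect_equal(logLik(f1), logLik(f3), tolerance = 1e-6)
  expect_equal(fittedParams(f1)@beta["age", ],
               10 * fittedParams(f3)@beta["age", ], tolerance = 1e-3)
})

test_that("degenerate designs and traits raise errors", {
  sim <- smallSim(seed = 8, nPed = 2, total = 40)
  X <- cbind(zero = rep(0, 40))
  rownames(X) <- rownames(traitMatrix(sim$phen))
  expect_error(fitVC(sim$phen, sim$ped, covariates = X), "rank deficient")
  Yc <- matrix(5, 40, 3, dimnames = list(rownames(traitMatrix(sim$phen)), NULL))
  phc <- LongPhenotypes(Yc, pedigree = sim$ped)
  expect_error(fitVC(phc, sim$ped), "zero variance")
})

test_that("parameters are recovered on moderately sized data", {
  # 10 replicates, n = 240, h2 = 0.4, rhoG = 1 (time-stable genetics)
  h2s <- rhos <- numeric(10)
  for (s in 1:10) {
    sim <- smallSim(seed = 400 + s, nPed = 6, total = 240, varFrac = NA,
                    h2 = 0.4, rhoG = 1, rhoE = 0.4)
    fit <- fitVC(sim$phen, sim$ped, covariates = c("age", "sex", "smoke"))
    h2s[s] <- mean(h2(fit))
    rg <- vcCorrelations(fit)$rhoG
    rhos[s] <- mean(rg[upper.tri(rg)])
  }
  expect_lt(abs(mean(h2s) - 0.4), 0.1)
  expect_gt(mean(rhos, na.rm = TRUE), 0.85)
})
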