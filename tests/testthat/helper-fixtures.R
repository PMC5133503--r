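# shared in-code fixtures for the test suite

# trio: two founders and one child
trioPed <- function() {
  Pedigree(famid = rep("t1", 3), id = c("dad", "mum", "kid"),
           father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
           sex = c("male", "female", "female"))
}

# three-generation family of 8: grandparents, two children (one married in),
# three grandchildren
threeGenPed <- function() {
  Pedigree(famid = rep("f", 8),
           id = c("gf", "gm", "a", "b", "sp", "c1", "c2", "c3"),
           father = c(NA, NA, "gf", "gf", NA, "a", "a", "a"),
           mother = c(NA, NA, "gm", "gm", NA, "sp", "sp", "sp"),
           sex = c("1", "2", "1", "2", "2", "1", "2", "1"))
}

# n unrelated singleton founders (for HWE-style checks)
singletonPed <- function(n) {
  Pedigree(famid = paste0("s", seq_len(n)), id = paste0("i", seq_len(n)),
           father = rep(NA_character_, n), mother = rep(NA_character_, n),
           sex = rep("unknown", n))
}

# small simulated dataset for fitting tests
smallSim <- function(seed = 1, nPed = 4, total = 160, k = 3, h2 = 0.4,
                     rhoG = 0.8, rhoE = 0.3, varFrac = 0.05, maf = 0.3,
                     region = NULL) {
  causal <- if (is.na(varFrac)) data.frame(maf = numeric(0),
                                           varFrac = numeric(0))
    else data.frame(maf = maf, varFrac = varFrac)
  cfg <- simConfig(nPedigrees = nPed, totalSize = total, k = k,
                   causal = causal, nullVariants = 2, h2 = h2, rhoG = rhoG,
                   rhoE = rhoE, region = region)
  simReplicate(cfg, seed = seed)
}

# independent dense MVN log-likelihood, written from scratch: builds the
# stacked covariance by explicit kronecker products and evaluates the
# normal density via determinant() and solve() (no Cholesky, no package
# internals shared with the implementation under test)
denseLoglikOracle <- function(Y, phi, G, E, mu = NULL, X = NULL, beta = NULL,
                              g = NULL, betaSNV = NULL, K = NULL, u = NULL) {
  n <- nrow(Y); k <- ncol(Y)
  M <- matrix(0, n, k)
  if (!is.null(mu)) M <- M + matrix(mu, n, k, byrow = TRUE)
  if (!is.null(X) && !is.null(beta)) M <- M + X %*% beta
  if (!is.null(g) && !is.null(betaSNV))
    M <- M + outer(g, rep(betaSNV, length.out = k))
  Om <- kronecker(2 * phi, G) + kronecker(diag(n), E)
  if (!is.null(K)) Om <- Om + kronecker(K, tcrossprod(rep(u, length.out = k)))
  r <- as.vector(t(Y - M))
  obs <- !is.na(r)
  r <- r[obs]; Om <- Om[obs, obs]
  ld <- as.numeric(determinant(Om, logarithm = TRUE)$modulus)
  -0.5 * (sum(obs) * log(2 * pi) + ld + drop(crossprod(r, solve(Om, r))))
}

# random positive-definite covariance of dimension k
randPD <- function(k, scale = 1) {
  A <- matrix(rnorm(k * k), k)
  scale * (crossprod(A) / k + diag(k) * 0.2)
}
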