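#' @include AllClasses.R vc-fit.R
NULL

#' Construct variance-component parameters
#'
#' Either give the covariance matrices `G` and `E` directly, or per-trait
#' standard deviations plus cross-time-point correlations from which
#' `G = D_g R_g D_g` and `E = D_e R_e D_e` are assembled.
#'
#' @param sigmaG,sigmaE numeric(k), additive-genetic and environmental
#'   standard deviations per time point (ignored when `G`/`E` given).
#' @param rhoG,rhoE correlation across time points: scalar
#'   (equicorrelation), full k x k matrix, or `NULL` (identity).
#' @param G,E optional covariance matrices, overriding the above.
#' @param mu numeric(k) per-time-point intercepts.
#' @param beta covariate coefficient matrix (covariates x k), optional.
#' @param betaSNV SNV effect: length 0, 1 (shared) or k.
#' @param sigmaGeff kernel-effect SDs: length 0, 1 (shared) or k.
#' @return A [VCParameters-class].
#' @examples
#' p <- vcParameters(sigmaG = rep(0.6, 3), rhoG = 1,
#'                   sigmaE = rep(0.8, 3), rhoE = 0.4)
#' p
#' @export
vcParameters <- function(sigmaG = NULL, rhoG = NULL, sigmaE = NULL,
                         rhoE = NULL, G = NULL, E = NULL, mu = NULL,
                         beta = NULL, betaSNV = numeric(0),
                         sigmaGeff = numeric(0)) {
  mkcov <- function(sig, rho) {
    k <- length(sig)
    R <- if (is.null(rho)) diag(k)
    else if (is.matrix(rho)) rho
    else matrix(rho, k, k) + (1 - rho) * diag(k)
    diag(sig, k) %*% R %*% diag(sig, k)
  }
  if (is.null(G)) G <- mkcov(sigmaG, rhoG)
  if (is.null(E)) E <- mkcov(sigmaE, rhoE)
  k <- nrow(G)
  if (is.null(mu)) mu <- rep(0, k)
  if (is.null(beta)) beta <- matrix(0, 0, k)
  methods::new("VCParameters", mu = as.numeric(mu), beta = as.matrix(beta),
               betaSNV = as.numeric(betaSNV), G = as.matrix(G),
               E = as.matrix(E), sigmaGeff = as.numeric(sigmaGeff))
}

#' Assemble the stacked trait covariance matrix
#'
#' `Omega = 2 Phi (x) G + I (x) E (+ K (x) u u')` over cells ordered
#' individual-major with the time point innermost; rows/columns of missing
#' (individual, time point) cells are deleted when a missingness mask is
#' given.
#'
#' @param params a [VCParameters-class].
#' @param phi kinship matrix (from [kinshipMatrix()]) over the analysis
#'   individuals.
#' @param kernel optional [GeneKernel-class] (or plain K matrix) over the
#'   same individuals; requires `sigmaGeff` in `params`.
#' @param mask optional logical n x k matrix (or stacked vector), `TRUE`
#'   for observed cells.
#' @return Covariance matrix over the observed cells; an error names the
#'   offending eigenvalue if the result is not positive definite.
#' @export
buildCovariance <- function(params, phi, kernel = NULL, mask = NULL) {
  k <- length(params@mu)
  n <- nrow(phi)
  Om <- kronecker(2 * phi, params@G) + kronecker(diag(n), params@E)
  if (!is.null(kernel)) {
    if (!length(params@sigmaGeff))
      stop("kernel given but params carry no sigmaGeff")
    K <- if (methods::is(kernel, "GeneKernel")) kernelMatrix(kernel) else kernel
    u <- rep(params@sigmaGeff, length.out = k)
    Om <- Om + kronecker(K, tcrossprod(u))
  }
  if (!is.null(mask)) {
    obs <- if (is.matrix(mask)) as.vector(t(mask)) else as.logical(mask)
    Om <- Om[obs, obs, drop = FALSE]
  }
  ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("covariance not positive definite (min eigenvalue %.3g)",
                 min(ev)))
  Om
}

#' Log-likelihood of a variance-component model at fixed parameters
#'
#' Evaluates the multivariate-normal log density of the stacked trait
#' vector under the mean model `mu_t + X beta[, t] + g betaSNV_t` and the
#' covariance from [buildCovariance()]. Missing trait cells are dropped
#' (missing-at-random row/column deletion).
#'
#' @param params a [VCParameters-class].
#' @param Y trait matrix (individuals x time points) with id rownames.
#' @param phi kinship matrix over the same individuals, id dimnames.
#' @param X optional covariate matrix (no intercept column) aligned to `Y`.
#' @param g optional dosage vector aligned to `Y`.
#' @param kernel optional [GeneKernel-class] or K matrix.
#' @return Scalar log-likelihood.
#' @export
vcLoglik <- function(params, Y, phi, X = NULL, g = NULL, kernel = NULL) {
  if (is.null(dim(Y))) Y <- cbind(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  ids <- rownames(Y)
  if (!is.null(ids) && !is.null(rownames(phi))) phi <- phi[ids, ids]
  mu <- matrix(params@mu, n, k, byrow = TRUE)
  if (!is.null(X) && ncol(params@beta) == k && nrow(params@beta) > 0)
    mu <- mu + as.matrix(X) %*% params@beta
  if (!is.null(g) && length(params@betaSNV))
    mu <- mu + outer(as.numeric(g), rep(params@betaSNV, length.out = k))
  Rm <- Y - mu
  obs <- !is.na(Rm)
  Om <- buildCovariance(params, phi, kernel = kernel, mask = obs)
  r <- as.vector(t(Rm))[as.vector(t(obs))]
  ch <- chol(Om)
  w <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w^2))
}

#' Maximum-likelihood fit of a pedigree variance-component model
#'
#' Fits the multivariate (or univariate / time-averaged) measured-genotype
#' variance-component model by profile maximum likelihood: mean-model
#' coefficients are solved by GLS at each step while the covariance
#' parameters are optimized on a log-Cholesky scale with box constraints.
#' Boundary solutions (a genetic variance at ~0, a correlation at ~1) are
#' flagged rather than treated as errors.
#'
#' @param phen a [LongPhenotypes-class].
#' @param ped a [Pedigree-class] containing every phenotyped individual.
#' @param covariates covariate matrix (id rownames), character vector of
#'   column names in `covariates(phen)`, or `NULL` for none.
#' @param visits which trait columns to model: integer vector, `"all"`
#'   (default) or `"average"` (per-individual mean of non-missing visits).
#' @param genotype optional named dosage vector (one variant); missing
#'   dosages are mean-imputed.
#' @param mode SNV mean-effect structure: `"none"` (null model),
#'   `"shared"` (one beta for all time points) or `"free"` (per-time-point
#'   betas).
#' @param kernel optional [GeneKernel-class] adding a region variance
#'   component.
#' @param kernelConstraint `"shared"` (equal per-trait kernel effect) or
#'   `"free"`.
#' @param init optional [VCFit-class] (or covariance parameter vector)
#'   used as warm start.
#' @return A [VCFit-class].
#' @export
fitVC <- function(phen, ped, covariates = NULL, visits = "all",
                  genotype = NULL, mode = c("none", "shared", "free"),
                  kernel = NULL, kernelConstraint = c("shared", "free"),
                  init = NULL) {
  mode <- match.arg(mode)
  kernelConstraint <- match.arg(kernelConstraint)
  Yfull <- traitMatrix(phen)
  Y <- if (identical(visits, "all")) Yfull
  else if (identical(visits, "average"))
    cbind(rowMeans(Yfull, na.rm = TRUE))
  else Yfull[, visits, drop = FALSE]
  rownames(Y) <- rownames(Yfull)
  if (ncol(Y) < 2L && mode == "free") mode <- "shared"
  X <- .resolveCovariates(covariates, phen)
  prep <- .prepareVC(Y, X, ped)
  g <- if (is.null(genotype)) NULL else {
    gv <- .imputeDosage(as.numeric(genotype)[match(prep$ids, names(genotype))])
    if (stats::sd(gv) == 0) stop("genotype is monomorphic in the analysis sample")
    names(gv) <- prep$ids
    gv
  }
  if (mode != "none" && is.null(g)) stop("mode != 'none' requires a genotype")
  Z <- if (is.null(kernel)) NULL else kernel@Z
  initTheta <- if (methods::is(init, "VCFit")) attr(init@logLik, "theta")
  else init
  fit <- .fitEngine(prep, mode = mode, g = g, Z = Z,
                    kernelShared = kernelConstraint == "shared",
                    init = initTheta)
  if (is.null(fit$theta)) stop("variance-component fit failed to evaluate")
  .asVCFit(fit, prep, mode)
}

.resolveCovariates <- function(covariates, phen) {
  if (is.null(covariates)) return(NULL)
  if (is.character(covariates)) {
    cv <- covariates(phen)
    miss <- setdiff(covariates, colnames(cv))
    if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
    m <- as.matrix(cv[, covariates, drop = FALSE])
    rownames(m) <- rownames(cv)
    m
  } else as.matrix(covariates)
}

## package an engine fit as a VCFit with VCParameters
.asVCFit <- function(fit, prep, mode) {
  k <- prep$k
  p0 <- ncol(prep$X1)
  beta <- fit$beta
  pg <- if (mode == "none") 0L else if (mode == "shared") 1L else k
  bm <- matrix(beta[seq_len(k * p0)], p0, k)
  mu <- bm[1L, ]
  bcov <- bm[-1L, , drop = FALSE]
  rownames(bcov) <- colnames(prep$X1)[-1L]
  betaSNV <- if (pg) beta[k * p0 + seq_len(pg)] else numeric(0)
  params <- methods::new("VCParameters", mu = mu, beta = bcov,
                         betaSNV = betaSNV, G = .symm(fit$G),
                         E = .symm(fit$E), sigmaGeff = fit$u)
  gn <- tryCatch(.gradNorm(fit$obj, fit$theta), error = function(e) NA_real_)
  ll <- fit$ll
  attr(ll, "theta") <- fit$theta
  methods::new("VCFit", params = params, logLik = ll,
               converged = fit$converged, boundary = fit$boundary,
               iterations = fit$iterations, gradNorm = gn,
               n = prep$n, k = as.integer(k))
}

.symm <- function(M) (M + t(M)) / 2

#' @describeIn VCFit-class maximized log-likelihood.
#' @param object a `VCFit`.
#' @param ... ignored.
#' @export
setMethod("logLik", "VCFit", function(object, ...) as.numeric(object@logLik))

#' @describeIn VCFit-class fitted [VCParameters-class].
#' @param x a `VCFit`.
#' @export
fittedParams <- function(x) x@params

#' Narrow-sense heritability per time point
#'
#' `diag(G) / (diag(G) + diag(E) + sigmaGeff^2)` from fitted or constructed
#' parameters.
#'
#' @param x a [VCParameters-class] or [VCFit-class].
#' @return numeric(k).
#' @export
h2 <- function(x) {
  p <- if (methods::is(x, "VCFit")) x@params else x
  k <- length(p@mu)
  u2 <- if (length(p@sigmaGeff)) rep(p@sigmaGeff, length.out = k)^2 else 0
  diag(p@G) / (diag(p@G) + diag(p@E) + u2)
}

#' Cross-time-point genetic and environmental correlations
#'
#' @param x a [VCParameters-class] or [VCFit-class].
#' @return List with correlation matrices `rhoG` and `rhoE`.
#' @export
vcCorrelations <- function(x) {
  p <- if (methods::is(x, "VCFit")) x@params else x
  list(rhoG = stats::cov2cor(p@G), rhoE = stats::cov2cor(p@E))
}
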