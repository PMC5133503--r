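#' @include vc-api.R
NULL

#' Boundary-mixture p-value for a single variance component
#'
#' The LRT statistic for one variance parameter tested at its
#' parameter-space boundary (sigma2 = 0) is asymptotically a 1/2:1/2
#' mixture of a point mass at 0 and a 1-df chi-square, so
#' `p = 0.5 P(chisq_1 > T)` for `T > 0`. A statistic of exactly 0 (null
#' boundary fit) is reported as p = 1 so boundary solutions are never
#' flagged as suggestive.
#'
#' @param stat LRT statistic(s), `>= 0` up to numerical slack.
#' @return p-value(s); always `<= 0.5` when `stat > 0`.
#' @examples
#' mixturePvalue(2.706)  # ~0.05
#' mixturePvalue(0)      # 1
#' @export
mixturePvalue <- function(stat) {
  if (any(stat < -1e-6, na.rm = TRUE))
    stop("negative LRT statistic beyond numerical slack")
  stat <- pmax(stat, 0)
  ifelse(stat > 0, 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE), 1)
}

#' Build a region-local empirical kinship matrix
#'
#' Standardized (VanRaden-type) genetic relationship matrix from the
#' biallelic variants inside one region:
#' `K = (1/m) sum_j (g_j - 2 p_j)(g_j - 2 p_j)' / (2 p_j (1 - p_j))`.
#' Missing dosages are mean-imputed before centering; monomorphic
#' variants are excluded. K is invariant to REF/ALT allele flips and to
#' variant order.
#'
#' @param genos a [GenotypeMatrix-class].
#' @param region [GenomicRanges::GRanges] of length 1 (its name becomes
#'   the region label); `NULL` uses every variant in `genos`.
#' @return A [GeneKernel-class].
#' @export
buildLocalKinship <- function(genos, region = NULL) {
  D <- dosages(genos)
  gr <- variants(genos)
  if (!is.null(region)) {
    if (length(region) != 1L) stop("give exactly one region")
    keep <- suppressWarnings(
      IRanges::overlapsAny(gr, region, ignore.strand = TRUE))
    if (!any(keep)) stop("no variants in region")
    D <- D[, keep, drop = FALSE]
  } else {
    region <- range(gr, ignore.strand = TRUE)
  }
  p <- colMeans(D, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all region variants are monomorphic")
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  m <- sum(poly)
  for (j in seq_len(m)) D[, j] <- .imputeDosage(D[, j], p[j])
  Z <- sweep(sweep(D, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p) * m), "/")
  K <- tcrossprod(Z)
  K <- (K + t(K)) / 2
  methods::new("GeneKernel", K = K, Z = Z, region = region, m = as.integer(m))
}

#' Gene-centric variance-component association test
#'
#' Adds a region variance component `h2_geff`, carried by the local
#' empirical kinship K from [buildLocalKinship()], on top of the polygenic
#' (2 Phi) and environmental components, and tests `sigma2_geff = 0` by
#' LRT. Four model variants are available:
#' \describe{
#'   \item{`single`}{univariate model on one designated time point.}
#'   \item{`average`}{univariate model on the per-individual mean over
#'     available time points.}
#'   \item{`constrained`}{multivariate model, one shared kernel effect
#'     for all time points.}
#'   \item{`unconstrained`}{multivariate model, free per-time-point
#'     kernel effects.}
#' }
#' The 1-parameter tests (single, average, constrained) use the 1/2:1/2
#' boundary-mixture null ([mixturePvalue()]); the unconstrained test uses
#' a conservative k-df chi-square.
#'
#' @param kernel a [GeneKernel-class].
#' @param phen a [LongPhenotypes-class].
#' @param ped a [Pedigree-class].
#' @param covariates as in [assocTest()].
#' @param model one or more of `"single"`, `"average"`, `"constrained"`,
#'   `"unconstrained"`.
#' @param visit time point used by the `single` model (default 1).
#' @param cache internal: precomputed relatedness structure for repeated
#'   calls on the same individuals.
#' @return data.frame with one row per model: `region`, `model`, `m`,
#'   `n`, `df`, `stat`, `p`, `h2geff` (per-trait mean),
#'   `h2geff_1..k` (unconstrained), `llNull`, `llAlt`, `converged`.
#' @export
geneCentricTest <- function(kernel, phen, ped, covariates = "auto",
                            model = c("single", "average", "constrained",
                                      "unconstrained"),
                            visit = 1L, cache = NULL) {
  model <- match.arg(model, several.ok = TRUE)
  X <- if (identical(covariates, "auto"))
    attr(screenCovariates(phen, ped, cache = cache), "matrix")
  else .resolveCovariates(covariates, phen)
  Y <- traitMatrix(phen)
  k <- ncol(Y)
  label <- if (length(names(kernel@region))) names(kernel@region)[1] else "region"
  Z <- kernel@Z

  uniFit <- function(y) {
    y <- cbind(y)
    y[!is.finite(y)] <- NA
    rownames(y) <- rownames(Y)
    prep <- .prepareVC(y, X, ped, cache = cache)
    null <- .fitEngine(prep, "none")
    alt <- .fitEngine(prep, "none", Z = Z, kernelShared = TRUE,
                      init = c(null$theta, log(0.25)))
    list(prep = prep, null = null, alt = alt)
  }
  mvState <- NULL
  mvFit <- function(shared) {
    if (is.null(mvState)) {
      prep <- .prepareVC(Y, X, ped, cache = cache)
      null <- .fitEngine(prep, "none")
      mvState <<- list(prep = prep, null = null)
    }
    nK <- if (shared) 1L else k
    alt <- .fitEngine(mvState$prep, "none", Z = Z, kernelShared = shared,
                      init = c(mvState$null$theta, rep(log(0.25), nK)))
    list(prep = mvState$prep, null = mvState$null, alt = alt)
  }

  rows <- list()
  for (mdl in model) {
    f <- switch(mdl,
                single = uniFit(Y[, visit]),
                average = uniFit(rowMeans(Y, na.rm = TRUE)),
                constrained = mvFit(TRUE),
                unconstrained = mvFit(FALSE))
    stat <- max(0, 2 * (f$alt$ll - f$null$ll))
    df <- if (mdl == "unconstrained") k else 1L
    p <- if (mdl == "unconstrained") lrtPvalue(stat, df) else mixturePvalue(stat)
    kk <- f$prep$k
    u <- rep(f$alt$u, length.out = kk)
    h2g <- u^2 / (diag(f$alt$G) + diag(f$alt$E) + u^2)
    row <- data.frame(region = label, model = mdl, m = kernel@m,
                      n = f$prep$n, df = df, stat = stat, p = p,
                      h2geff = mean(h2g))
    for (t in seq_len(k))
      row[[paste0("h2geff_", t)]] <- if (kk == k) h2g[t] else NA_real_
    row$llNull <- f$null$ll
    row$llAlt <- f$alt$ll
    row$converged <- isTRUE(f$alt$converged) && isTRUE(f$null$converged)
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
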