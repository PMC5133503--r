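#' @include AllGenerics.R
NULL

#' Pedigree of related individuals
#'
#' Holds a validated, topologically ordered pedigree: every parent precedes
#' its offspring, parent references resolve, the parent graph is acyclic,
#' and named fathers/mothers have consistent sex where sex is known.
#' Construct with [Pedigree()] or [readPedigree()]; the additive kinship
#' matrix comes from [kinshipMatrix()].
#'
#' @slot famid character, pedigree (family) identifier per individual.
#' @slot id character, unique individual identifiers.
#' @slot father,mother character, parent identifiers (`NA` = founder).
#' @slot sex character, one of `"male"`, `"female"`, `"unknown"`.
#'
#' @export
setClass("Pedigree",
  representation(famid = "character", id = "character",
                 father = "character", mother = "character",
                 sex = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (n == 0L) return("pedigree contains no individuals")
  if (length(object@famid) != n || length(object@father) != n ||
      length(object@mother) != n || length(object@sex) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@id))
    return(paste("duplicated individual id(s):",
                 paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
  if (!all(object@sex %in% c("male", "female", "unknown")))
    return("sex must be 'male', 'female' or 'unknown'")
  half <- xor(is.na(object@father), is.na(object@mother))
  if (any(half))
    return(paste("half-specified parents for:",
                 paste(object@id[half], collapse = ", ")))
  for (p in c("father", "mother")) {
    ref <- slot(object, p)
    bad <- !is.na(ref) & !(ref %in% object@id)
    if (any(bad))
      return(paste0("dangling ", p, " id(s): ",
                    paste(unique(ref[bad]), collapse = ", ")))
  }
  idx <- match(object@father, object@id)
  if (any(!is.na(idx) & object@sex[idx] == "female"))
    return("individual named as father has sex female")
  idx <- match(object@mother, object@id)
  if (any(!is.na(idx) & object@sex[idx] == "male"))
    return("individual named as mother has sex male")
  pos <- seq_len(n)
  fpos <- match(object@father, object@id)
  mpos <- match(object@mother, object@id)
  if (any(stats::na.omit(fpos >= pos)) || any(stats::na.omit(mpos >= pos)))
    return("individuals are not in topological order (parent after child)")
  TRUE
})

#' Longitudinal phenotype and covariate container
#'
#' One quantitative trait measured at `k >= 1` time points per individual
#' (missing visits allowed, `NA`), plus per-individual covariates.
#' Row names of both tables are individual ids and must match.
#'
#' @slot trait numeric matrix, individuals x time points.
#' @slot traitName character scalar.
#' @slot covariates data.frame of per-individual covariates.
#'
#' @export
setClass("LongPhenotypes",
  representation(trait = "matrix", traitName = "character",
                 covariates = "data.frame"))

setValidity("LongPhenotypes", function(object) {
  if (ncol(object@trait) < 1L) return("need at least one time point")
  if (is.null(rownames(object@trait))) return("trait matrix needs id rownames")
  if (anyDuplicated(rownames(object@trait))) return("duplicated ids")
  if (nrow(object@covariates) > 0 &&
      !identical(rownames(object@covariates), rownames(object@trait)))
    return("covariate rows must match trait rows")
  if (!is.numeric(object@trait)) return("trait matrix must be numeric")
  TRUE
})

#' Biallelic SNV dosage matrix
#'
#' Additive genotype dosages (count of ALT alleles, 0/1/2, `NA` missing)
#' for pedigree members, with variant coordinates as a
#' [GenomicRanges::GRanges] and per-variant ALT allele frequencies
#' computed from non-missing calls.
#'
#' @slot dosage numeric matrix, individuals x variants.
#' @slot variants GRanges, one range per variant (names = variant ids,
#'   metadata columns `ref` and `alt`).
#' @slot af numeric, ALT allele frequency per variant.
#'
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", variants = "GRanges", af = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  if (ncol(object@dosage) != length(object@variants))
    return("dosage columns must match variants")
  if (length(object@af) != length(object@variants))
    return("af length must match variants")
  d <- object@dosage
  if (!all(d[!is.na(d)] %in% 0:2)) return("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(d))) return("dosage matrix needs id rownames")
  TRUE
})

#' Region-local empirical kinship (gene kernel)
#'
#' Standardized genetic relationship matrix built from the biallelic
#' variants of one genomic region, `K = Z Z'` with
#' `Z[, j] = (g_j - 2 p_j) / sqrt(2 m p_j (1 - p_j))`.
#'
#' @slot K symmetric numeric matrix, individuals x individuals.
#' @slot Z numeric matrix of scaled loadings with `K = tcrossprod(Z)`.
#' @slot region GRanges of length 1, the region the kernel was built from.
#' @slot m integer, number of polymorphic variants used.
#'
#' @export
setClass("GeneKernel",
  representation(K = "matrix", Z = "matrix", region = "GRanges",
                 m = "integer"))

setValidity("GeneKernel", function(object) {
  if (object@m < 1L) return("kernel must use at least one variant")
  if (nrow(object@K) != ncol(object@K)) return("K must be square")
  if (max(abs(object@K - t(object@K))) > 1e-8) return("K must be symmetric")
  ev <- min(eigen(object@K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) return(sprintf("K not positive semidefinite (min eigenvalue %.3g)", ev))
  TRUE
})

#' Variance-component model parameters
#'
#' Mean-model coefficients and covariance components of the multivariate
#' (k time points) pedigree model. The implied trait covariance is
#' `Omega = 2 Phi (x) G + I (x) E (+ K (x) u u')`.
#'
#' @slot mu numeric(k), per-time-point intercepts.
#' @slot beta numeric matrix (covariates x k) of covariate coefficients
#'   (0 columns allowed).
#' @slot betaSNV numeric, SNV effect: length 0 (absent), 1 (shared across
#'   time points) or k (free per time point).
#' @slot G numeric k x k additive-genetic covariance across time points.
#' @slot E numeric k x k environmental covariance across time points.
#' @slot sigmaGeff numeric, per-trait kernel-effect standard deviations:
#'   length 0 (no kernel), 1 (shared) or k.
#'
#' @export
setClass("VCParameters",
  representation(mu = "numeric", beta = "matrix", betaSNV = "numeric",
                 G = "matrix", E = "matrix", sigmaGeff = "numeric"))

setValidity("VCParameters", function(object) {
  k <- length(object@mu)
  if (k < 1L) return("need at least one time point")
  for (nm in c("G", "E")) {
    M <- slot(object, nm)
    if (!all(dim(M) == k)) return(paste(nm, "must be k x k"))
    if (max(abs(M - t(M))) > 1e-8) return(paste(nm, "must be symmetric"))
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return(paste(nm, "must be positive semidefinite"))
    if (!all(is.finite(M))) return(paste(nm, "must be finite"))
  }
  if (!length(object@betaSNV) %in% c(0L, 1L, k))
    return("betaSNV must have length 0, 1 or k")
  if (!length(object@sigmaGeff) %in% c(0L, 1L, k))
    return("sigmaGeff must have length 0, 1 or k")
  if (length(object@sigmaGeff) && any(object@sigmaGeff < 0))
    return("sigmaGeff must be non-negative")
  if (ncol(object@beta) != 0 && ncol(object@beta) != k)
    return("beta must have k columns (or none)")
  TRUE
})

#' Maximum-likelihood fit of a variance-component model
#'
#' @slot params [VCParameters-class] at the optimum.
#' @slot logLik numeric, maximized log-likelihood.
#' @slot converged logical.
#' @slot boundary logical, TRUE when a variance hit the parameter-space
#'   boundary (sigma ~ 0 or |rho| ~ 1).
#' @slot iterations integer.
#' @slot gradNorm numeric, max-norm of the numerical gradient over the
#'   free covariance parameters at the optimum.
#' @slot n,k integer, individuals and time points used.
#'
#' @export
setClass("VCFit",
  representation(params = "VCParameters", logLik = "numeric",
                 converged = "logical", boundary = "logical",
                 iterations = "integer", gradNorm = "numeric",
                 n = "integer", k = "integer"))

## -- show methods -----------------------------------------------------------

setMethod("show", "Pedigree", function(object) {
  nfam <- length(unique(object@famid))
  cat(sprintf("Pedigree: %d individuals in %d famil%s, %d founders\n",
              length(object@id), nfam, if (nfam == 1) "y" else "ies",
              sum(is.na(object@father))))
})

setMethod("show", "LongPhenotypes", function(object) {
  cat(sprintf("LongPhenotypes: trait '%s', %d individuals x %d time points",
              object@traitName, nrow(object@trait), ncol(object@trait)))
  cat(sprintf(", %d missing cells\n", sum(is.na(object@trait))))
  if (ncol(object@covariates))
    cat("  covariates:", paste(colnames(object@covariates), collapse = ", "),
        "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d biallelic SNVs\n",
              nrow(object@dosage), ncol(object@dosage)))
})

setMethod("show", "GeneKernel", function(object) {
  r <- object@region
  cat(sprintf("GeneKernel '%s' (%s:%d-%d): %d individuals, %d variants\n",
              if (length(names(r))) names(r)[1] else "region",
              as.character(GenomicRanges::seqnames(r))[1],
              GenomicRanges::start(r)[1], GenomicRanges::end(r)[1],
              nrow(object@K), object@m))
})

setMethod("show", "VCParameters", function(object) {
  k <- length(object@mu)
  h2 <- diag(object@G) / (diag(object@G) + diag(object@E))
  cat(sprintf("VCParameters (k = %d): h2 = %s\n", k,
              paste(sprintf("%.3f", h2), collapse = ", ")))
  if (length(object@betaSNV))
    cat("  betaSNV:", paste(sprintf("%.4g", object@betaSNV), collapse = ", "),
        "\n")
  if (length(object@sigmaGeff))
    cat("  sigmaGeff:", paste(sprintf("%.4g", object@sigmaGeff),
                              collapse = ", "), "\n")
})

setMethod("show", "VCFit", function(object) {
  cat(sprintf("VCFit: logLik = %.4f, %sconverged%s (n = %d, k = %d)\n",
              object@logLik, if (object@converged) "" else "NOT ",
              if (object@boundary) ", boundary solution" else "",
              object@n, object@k))
})

## -- accessors --------------------------------------------------------------

#' @describeIn Pedigree-class individual identifiers, topological order.
#' @param x object.
#' @export
setMethod("pedIds", "Pedigree", function(x) x@id)

#' @describeIn Pedigree-class identifiers of founders (both parents missing).
#' @export
setMethod("founders", "Pedigree", function(x) x@id[is.na(x@father)])

#' @describeIn Pedigree-class the pedigree as a data.frame
#'   (famid, id, father, mother, sex).
#' @export
setMethod("pedData", "Pedigree", function(x)
  data.frame(famid = x@famid, id = x@id, father = x@father,
             mother = x@mother, sex = x@sex, stringsAsFactors = FALSE))

#' @describeIn LongPhenotypes-class the individuals x time points trait matrix.
#' @param x object.
#' @export
setMethod("traitMatrix", "LongPhenotypes", function(x) x@trait)

#' @describeIn LongPhenotypes-class the trait name.
#' @export
setMethod("traitName", "LongPhenotypes", function(x) x@traitName)

#' @describeIn LongPhenotypes-class the per-individual covariate table.
#' @export
setMethod("covariates", "LongPhenotypes", function(x) x@covariates)

#' @describeIn GenotypeMatrix-class the additive dosage matrix.
#' @param x object.
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn GenotypeMatrix-class variant coordinates as GRanges.
#' @export
setMethod("variants", "GenotypeMatrix", function(x) x@variants)

#' @describeIn GenotypeMatrix-class ALT allele frequencies.
#' @export
setMethod("alleleFreq", "GenotypeMatrix", function(x) x@af)

#' @describeIn GeneKernel-class the empirical kinship matrix K.
#' @param x object.
#' @export
setMethod("kernelMatrix", "GeneKernel", function(x) x@K)
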