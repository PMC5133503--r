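#' @include vc-api.R
NULL

#' Likelihood-ratio-test p-value
#'
#' Upper-tail chi-square probability of the LRT statistic
#' `T = 2 (logL_alt - logL_null)`. Small negative statistics (optimizer
#' slack) are clipped to zero; larger negative values signal an upstream
#' optimization failure and raise an error.
#'
#' @param stat LRT statistic(s).
#' @param df degrees of freedom (1 for the constrained and average tests,
#'   k for the unconstrained test on k time points).
#' @return p-value(s) in (0, 1].
#' @examples
#' lrtPvalue(3.841, 1)   # ~0.05
#' lrtPvalue(7.815, 3)   # ~0.05
#' @export
lrtPvalue <- function(stat, df) {
  if (any(stat < -1e-6, na.rm = TRUE))
    stop("negative LRT statistic beyond numerical slack; optimization failed upstream")
  stat <- pmax(stat, 0)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Marginal covariate screening on the time-averaged trait
#'
#' Each candidate is tested one at a time as a fixed effect in the
#' univariate polygenic model (no SNV term) for the per-individual average
#' of the trait over available time points; candidates with LRT p < alpha
#' are retained for downstream association models. Constant candidates are
#' skipped with a warning.
#'
#' @param phen a [LongPhenotypes-class].
#' @param ped a [Pedigree-class].
#' @param candidates numeric matrix of candidate columns (id rownames);
#'   default [covariateCandidates()] (age, sex, age x sex, age^2,
#'   age^2 x sex, smoking).
#' @param alpha retention threshold (default 0.05).
#' @param cache internal: precomputed relatedness structure for repeated
#'   calls on the same individuals.
#' @return data.frame with columns `candidate`, `p`, `selected`; the
#'   matrix of retained columns is in `attr(, "matrix")`.
#' @export
screenCovariates <- function(phen, ped, candidates = NULL, alpha = 0.05,
                             cache = NULL) {
  if (is.null(candidates)) candidates <- covariateCandidates(phen)
  candidates <- as.matrix(candidates)
  yavg <- cbind(rowMeans(traitMatrix(phen), na.rm = TRUE))
  yavg[!is.finite(yavg)] <- NA
  rownames(yavg) <- rownames(traitMatrix(phen))
  if (is.null(cache))
    cache <- .pedStruct(ped, rownames(yavg)[!is.na(yavg[, 1])])
  prep0 <- .prepareVC(yavg, NULL, ped, cache = cache)
  null <- .fitEngine(prep0, "none")
  out <- data.frame(candidate = colnames(candidates), p = NA_real_,
                    selected = FALSE)
  for (j in seq_len(ncol(candidates))) {
    cj <- candidates[, j, drop = FALSE]
    if (stats::sd(cj) == 0) {
      warning("constant candidate covariate '", colnames(candidates)[j],
              "' skipped")
      next
    }
    prep <- .prepareVC(yavg, cj, ped, cache = cache)
    alt <- .fitEngine(prep, "none", init = null$theta)
    out$p[j] <- lrtPvalue(max(0, 2 * (alt$ll - null$ll)), 1)
  }
  out$selected <- !is.na(out$p) & out$p < alpha
  sel <- candidates[, out$candidate[out$selected], drop = FALSE]
  attr(out, "matrix") <- sel
  out
}

#' Family-based measured-genotype association tests
#'
#' Runs, per variant, any of the three strategies compared in this
#' package: `"constrained"` (multivariate model, one SNV beta shared by
#' all time points; 1-df LRT), `"unconstrained"` (per-time-point betas;
#' k-df LRT) and `"average"` (univariate model on the per-individual mean
#' of available time points; 1-df LRT). Relatedness enters through the
#' pedigree kinship matrix; missing dosages are mean-imputed at test time;
#' monomorphic variants return p = 1 with a flag rather than an error.
#'
#' @param genos a [GenotypeMatrix-class].
#' @param phen a [LongPhenotypes-class] (k >= 2 time points for the
#'   multivariate tests).
#' @param ped a [Pedigree-class].
#' @param covariates `"auto"` (marginal screening via
#'   [screenCovariates()]), a character vector of covariate names, a
#'   matrix, or `NULL`.
#' @param tests subset of `c("constrained", "unconstrained", "average")`.
#' @param variantIds optional variant subset (column names of the dosage
#'   matrix).
#' @param maf minor-allele-frequency floor; variants below it are skipped
#'   (default 0, no floor).
#' @param cache internal: precomputed relatedness structure for repeated
#'   calls on the same individuals.
#' @return data.frame with one row per variant x test: `variant`, `test`,
#'   `n`, `df`, `stat`, `p`, `beta` (shared/average effect),
#'   `beta_1..beta_k` (unconstrained), `llNull`, `llAlt`, `converged`,
#'   `flag`.
#' @export
assocTest <- function(genos, phen, ped, covariates = "auto",
                      tests = c("constrained", "unconstrained", "average"),
                      variantIds = NULL, maf = 0, cache = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  X <- if (identical(covariates, "auto"))
    attr(screenCovariates(phen, ped, cache = cache), "matrix")
  else .resolveCovariates(covariates, phen)
  Y <- traitMatrix(phen)
  k <- ncol(Y)
  if (k < 2L && any(tests != "average"))
    stop("multivariate tests need at least 2 time points")
  D <- dosages(genos)
  if (is.null(variantIds)) variantIds <- colnames(D)
  af <- alleleFreq(genos)
  names(af) <- colnames(D)

  needMV <- any(tests %in% c("constrained", "unconstrained"))
  needAV <- "average" %in% tests
  if (needMV) {
    prepMV <- .prepareVC(Y, X, ped, cache = cache)
    nullMV <- .fitEngine(prepMV, "none")
  }
  if (needAV) {
    yavg <- cbind(rowMeans(Y, na.rm = TRUE))
    yavg[!is.finite(yavg)] <- NA
    rownames(yavg) <- rownames(Y)
    prepAV <- .prepareVC(yavg, X, ped, cache = cache)
    nullAV <- .fitEngine(prepAV, "none")
  }

  rows <- list()
  for (v in variantIds) {
    if (maf > 0 && min(af[v], 1 - af[v]) < maf) next
    gv <- D[, v]
    mono <- stats::sd(gv, na.rm = TRUE) %in% c(0, NA) || all(is.na(gv))
    fits <- list()
    if (!mono && needMV) {
      g <- .imputeDosage(gv[prepMV$ids], af[v])
      if (stats::sd(g) == 0) mono <- TRUE else {
        names(g) <- prepMV$ids
        if ("constrained" %in% tests || "unconstrained" %in% tests)
          fits$constrained <- .fitEngine(prepMV, "shared", g = g,
                                         init = c(nullMV$theta))
        if ("unconstrained" %in% tests)
          fits$unconstrained <- .fitEngine(prepMV, "free", g = g,
                                           init = fits$constrained$theta)
      }
    }
    if (!mono && needAV) {
      g <- .imputeDosage(gv[prepAV$ids], af[v])
      if (stats::sd(g) == 0) mono <- TRUE else {
        names(g) <- prepAV$ids
        fits$average <- .fitEngine(prepAV, "shared", g = g,
                                   init = c(nullAV$theta))
      }
    }
    for (tst in tests) {
      if (mono) {
        rows[[length(rows) + 1L]] <- .resultRow(v, tst, k, n = nrow(D),
                                                flag = "monomorphic")
        next
      }
      alt <- fits[[tst]]
      nul <- if (tst == "average") nullAV else nullMV
      prep <- if (tst == "average") prepAV else prepMV
      df <- if (tst == "unconstrained") k else 1L
      stat <- max(0, 2 * (alt$ll - nul$ll))
      p0 <- ncol(prep$X1)
      kk <- prep$k
      bg <- alt$beta[kk * p0 + seq_len(if (tst == "unconstrained") kk else 1L)]
      rows[[length(rows) + 1L]] <- .resultRow(
        v, tst, k, n = prep$n, df = df, stat = stat,
        p = lrtPvalue(stat, df),
        beta = if (tst == "unconstrained") NA_real_ else bg,
        betas = if (tst == "unconstrained") bg else rep(NA_real_, k),
        llNull = nul$ll, llAlt = alt$ll,
        converged = isTRUE(alt$converged) && isTRUE(nul$converged))
    }
  }
  do.call(rbind, rows)
}

.resultRow <- function(variant, test, k, n, df = NA_integer_,
                       stat = NA_real_, p = 1, beta = NA_real_,
                       betas = rep(NA_real_, k), llNull = NA_real_,
                       llAlt = NA_real_, converged = NA, flag = "") {
  row <- data.frame(variant = variant, test = test, n = n, df = df,
                    stat = stat, p = p, beta = beta)
  for (t in seq_len(k)) row[[paste0("beta_", t)]] <- betas[t]
  row$llNull <- llNull
  row$llAlt <- llAlt
  row$converged <- converged
  row$flag <- flag
  row
}

#' Tally replicates meeting p-value thresholds
#'
#' The machine-readable power/type-I summary: for every (variant, test,
#' threshold) combination, the number of replicates with p strictly below
#' the threshold. Missing (replicate, variant, test) cells are counted as
#' non-significant with a warning.
#'
#' @param pvals data.frame with columns `replicate`, `variant`, `test`,
#'   `p` (e.g. rbind-ed [assocTest()] output with a `replicate` column).
#' @param thresholds p-value thresholds (default the reporting thresholds
#'   1e-3, 5e-5, 5e-9).
#' @return data.frame `variant`, `test`, `threshold`, `count`,
#'   `replicates`.
#' @export
tallyReplicates <- function(pvals, thresholds = c(1e-3, 5e-5, 5e-9)) {
  need <- c("replicate", "variant", "test", "p")
  if (!all(need %in% colnames(pvals)))
    stop("pvals needs columns ", paste(need, collapse = ", "))
  nrep <- length(unique(pvals$replicate))
  grid <- unique(pvals[, c("variant", "test")])
  cells <- table(paste(pvals$variant, pvals$test))
  if (nrep > 0 && any(cells < nrep))
    warning("missing replicate cells counted as non-significant")
  out <- list()
  for (i in seq_len(nrow(grid))) {
    sub <- pvals[pvals$variant == grid$variant[i] & pvals$test == grid$test[i], ]
    for (th in thresholds)
      out[[length(out) + 1L]] <- data.frame(
        variant = grid$variant[i], test = grid$test[i], threshold = th,
        count = sum(sub$p < th, na.rm = TRUE), replicates = nrep)
  }
  if (!length(out))
    return(data.frame(variant = character(0), test = character(0),
                      threshold = numeric(0), count = integer(0),
                      replicates = integer(0)))
  do.call(rbind, out)
}

#' Write association or tally results as TSV
#'
#' Fixed column order, full double precision; [readResults()] is its
#' inverse.
#'
#' @param results data.frame from [assocTest()], [geneCentricTest()] or
#'   [tallyReplicates()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  lead <- intersect(c("variant", "region", "test", "model", "threshold",
                      "count", "replicates", "n", "df", "stat", "p", "beta"),
                    colnames(results))
  results <- results[, c(lead, setdiff(colnames(results), lead)), drop = FALSE]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(x) format(x, digits = 17))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results TSV
#'
#' @param path file written by [writeResults()].
#' @return data.frame.
#' @export
readResults <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
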