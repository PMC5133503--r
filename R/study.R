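#' @include sim.R assoc.R kernel.R
NULL

#' Run a replicated power / type-I-error study
#'
#' Simulates `nReplicates` studies under one configuration (pedigree set
#' fixed across replicates; genotypes and phenotypes redrawn), runs the
#' selected association tests on every variant in every replicate, and
#' tallies significant results per threshold — the machine-readable
#' analog of a replicate-count power table. Null variants additionally
#' yield empirical type-I rates. Per-replicate seeds are derived from the
#' master seed by counter-based splitting, so any replicate can be rerun
#' in isolation.
#'
#' @param config a [simConfig()] object.
#' @param tests subset of `c("constrained", "unconstrained", "average")`.
#' @param gcModels optional gene-centric models
#'   (`"single"`, `"average"`, `"constrained"`, `"unconstrained"`) run on
#'   the configured region each replicate (requires `config$region`).
#' @param thresholds tally thresholds (default 1e-3, 5e-5, 5e-9).
#' @param nReplicates number of replicates.
#' @param seed master seed.
#' @param covariates `"auto"` (per-replicate marginal screening),
#'   character names from the simulated covariates (age, sex, smoke), or
#'   `NULL`.
#' @param alphaGrid nominal levels for the null-variant type-I summary.
#' @param regenotype redraw genotypes each replicate (default TRUE);
#'   FALSE reuses the first replicate's genotypes, mimicking a fixed
#'   observed genotype set.
#' @param verbose print progress every 50 replicates.
#' @return List: `pvals` (long data.frame: replicate, variant, test, p,
#'   stat, df), `tally` (from [tallyReplicates()], causal and region
#'   variants), `typeI` (per test x alpha empirical rate over null
#'   variants), `failures` (count of replicate-level errors), `ped`.
#' @export
runStudy <- function(config, tests = c("constrained", "unconstrained",
                                       "average"),
                     gcModels = NULL,
                     thresholds = c(1e-3, 5e-5, 5e-9),
                     nReplicates = 200, seed = 1,
                     covariates = "auto",
                     alphaGrid = c(0.05, 0.01),
                     regenotype = TRUE, verbose = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (nReplicates < 1)
    return(list(pvals = data.frame(), tally = tallyReplicates(
      data.frame(replicate = integer(0), variant = character(0),
                 test = character(0), p = numeric(0)), thresholds),
      typeI = data.frame(), failures = 0L, ped = NULL))
  set.seed(seed)
  ped <- simPedigrees(config$nPedigrees, config$totalSize)
  phi <- kinshipMatrix(ped)
  struct <- .pedStruct(ped, pedIds(ped), phi = phi)
  fixedGenos <- NULL
  res <- vector("list", nReplicates)
  failures <- 0L
  for (r in seq_len(nReplicates)) {
    sr <- (seed + 7919 * r) %% 2147483647L
    out <- tryCatch({
      rep <- simReplicate(config, seed = sr, ped = ped, phi = phi)
      if (!regenotype) {
        if (is.null(fixedGenos)) fixedGenos <- rep$genos
        else {
          sim <- simPhenotypes(ped, fixedGenos, config, phi = phi)
          rep$genos <- fixedGenos
          rep$phen <- sim$phen
        }
      }
      snvIds <- grep("^(causal|null)_", colnames(dosages(rep$genos)),
                     value = TRUE)
      a <- assocTest(rep$genos, rep$phen, ped, covariates = covariates,
                     tests = tests, variantIds = snvIds, cache = struct)
      rows <- data.frame(replicate = r, variant = a$variant, test = a$test,
                         p = a$p, stat = a$stat, df = a$df)
      if (!is.null(gcModels) && !is.null(config$region)) {
        regionIdx <- grep("^region_", colnames(dosages(rep$genos)))
        rgGr <- range(variants(rep$genos)[regionIdx], ignore.strand = TRUE)
        names(rgGr) <- "region"
        gk <- buildLocalKinship(rep$genos, rgGr)
        gc <- geneCentricTest(gk, rep$phen, ped, covariates = covariates,
                              model = gcModels, cache = struct)
        rows <- rbind(rows, data.frame(replicate = r, variant = "region",
                                       test = paste0("gc_", gc$model),
                                       p = gc$p, stat = gc$stat, df = gc$df))
      }
      rows
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(out)) failures <- failures + 1L else res[[r]] <- out
    if (verbose && r %% 50 == 0) message("replicate ", r, "/", nReplicates)
  }
  pvals <- do.call(rbind, res)
  nullRegion <- !is.null(config$region) && config$region$varFrac == 0
  isNull <- grepl("^null_", pvals$variant) |
    (nullRegion & grepl("^gc_", pvals$test))
  tally <- tallyReplicates(pvals[!isNull, , drop = FALSE], thresholds)
  typeI <- do.call(rbind, lapply(unique(pvals$test), function(tst) {
    sub <- pvals[isNull & pvals$test == tst, ]
    if (!nrow(sub)) return(NULL)
    do.call(rbind, lapply(alphaGrid, function(a)
      data.frame(test = tst, alpha = a, rate = mean(sub$p < a),
                 hits = sum(sub$p < a), ntests = nrow(sub))))
  }))
  list(pvals = pvals, tally = tally, typeI = typeI,
       failures = failures, ped = ped)
}
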