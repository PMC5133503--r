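#' @include pedigree.R genotypes.R phenotypes.R
NULL

#' Configuration for the synthetic family-study generator
#'
#' Defaults emulate a large family-based blood-pressure study design:
#' 20 extended pedigrees totalling
#' 849 individuals, three visits of an SBP-like quantitative trait with
#' time-stable variant effects, a polygenic background with genetic
#' cross-visit correlation 1, and age/sex/smoking covariates. The nine
#' default causal variance fractions are
#' 0.0278, 0.0206, 0.0149, 0.0143, 0.011, 0.0081, 0.004, 0.0027, 0.0017
#' (read as proportions of trait variance).
#'
#' @param nPedigrees,totalSize pedigree count and total individuals.
#' @param k number of time points.
#' @param causal data.frame with columns `maf` and `varFrac`, one row per
#'   causal variant; the per-allele effect is
#'   `beta = sqrt(varFrac * sigma2Total / (2 maf (1 - maf)))`.
#' @param nullVariants number of truly null SNVs; `nullMafRange` their
#'   MAF range.
#' @param h2 polygenic heritability per time point.
#' @param rhoG,rhoE genetic and environmental cross-visit correlations.
#' @param sigma2Total total (genetic + regional + environmental) trait
#'   variance; the environmental share is
#'   `1 - h2 - sum(varFrac) - regionVarFrac`.
#' @param mu per-visit intercepts (recycled to length k).
#' @param ageEffect,sexEffect,smokeEffect covariate effects (trait units;
#'   age per year, centered at `meanAge`).
#' @param meanAge,sdAge,visitSpacing,smokePrev covariate generator
#'   settings (baseline age distribution, years between visits, smoking
#'   prevalence).
#' @param region `NULL`, or a list describing one genomic region for the
#'   gene-centric kernel: `m` variants, `mafRange`, total `varFrac`
#'   explained by `nCausal` of them (0 for a null region).
#' @return A `SimConfig` list.
#' @export
simConfig <- function(nPedigrees = 20, totalSize = 849, k = 3,
                      causal = data.frame(
                        maf = 0.2,
                        varFrac = c(0.0278, 0.0206, 0.0149, 0.0143, 0.011,
                                    0.0081, 0.004, 0.0027, 0.0017)),
                      nullVariants = 20, nullMafRange = c(0.05, 0.5),
                      h2 = 0.4, rhoG = 1.0, rhoE = 0.4, sigma2Total = 1,
                      mu = NULL, ageEffect = 0.01, sexEffect = 0.3,
                      smokeEffect = 0.25, meanAge = 45, sdAge = 12,
                      visitSpacing = 5, smokePrev = 0.2, region = NULL) {
  if (is.null(mu)) mu <- seq(0, by = 0.1, length.out = k)
  mu <- rep(mu, length.out = k)
  regionV <- if (is.null(region)) 0 else region$varFrac
  if (!is.null(region)) {
    region <- utils::modifyList(list(m = 40L, mafRange = c(0.05, 0.5),
                                     varFrac = 0, nCausal = 4L), region)
    regionV <- region$varFrac
  }
  budget <- sum(causal$varFrac) + regionV + h2
  if (budget >= 1)
    stop(sprintf("infeasible variance budget: causal + region + h2 = %.3f >= 1",
                 budget))
  if (nrow(causal) && (any(causal$maf <= 0) || any(causal$maf > 0.5)))
    stop("causal maf values must lie in (0, 0.5]")
  if (k < 1) stop("k must be >= 1")
  structure(list(nPedigrees = nPedigrees, totalSize = totalSize, k = k,
                 causal = causal, nullVariants = nullVariants,
                 nullMafRange = nullMafRange, h2 = h2, rhoG = rhoG,
                 rhoE = rhoE, sigma2Total = sigma2Total, mu = mu,
                 ageEffect = ageEffect, sexEffect = sexEffect,
                 smokeEffect = smokeEffect, meanAge = meanAge,
                 sdAge = sdAge, visitSpacing = visitSpacing,
                 smokePrev = smokePrev, region = region),
            class = "SimConfig")
}

#' Generate a set of extended pedigrees
#'
#' Builds `nPedigrees` pedigrees of 3-4 generations whose sizes sum to
#' `totalSize`: each starts from a founder couple and grows by adding
#' children or marrying in founder spouses until its target size is
#' reached. Deterministic given the seed.
#'
#' @param nPedigrees number of pedigrees.
#' @param totalSize total number of individuals across pedigrees.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return A [Pedigree-class] containing all families.
#' @export
simPedigrees <- function(nPedigrees = 20, totalSize = 849, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (totalSize < 3 * nPedigrees)
    stop("totalSize too small: need at least a trio per pedigree")
  sizes <- rep(totalSize %/% nPedigrees, nPedigrees)
  extra <- totalSize %% nPedigrees
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (nPedigrees > 1) {
    jit <- round(stats::rnorm(nPedigrees, 0, sizes[1] / 7))
    sizes <- pmax(sizes + jit, 5L)
    while (sum(sizes) != totalSize) {
      i <- if (sum(sizes) > totalSize) which.max(sizes) else which.min(sizes)
      sizes[i] <- sizes[i] + sign(totalSize - sum(sizes))
    }
  }
  peds <- lapply(seq_len(nPedigrees), function(f)
    .growPedigree(sprintf("fam%02d", f), sizes[f]))
  df <- do.call(rbind, peds)
  Pedigree(df$famid, df$id, df$father, df$mother, df$sex)
}

## grow one pedigree to exactly `size` members
.growPedigree <- function(famid, size, maxGen = 4L) {
  id <- character(size)
  father <- mother <- rep(NA_character_, size)
  sex <- character(size)
  gen <- integer(size)
  nid <- 0L
  newInd <- function(s, g, f = NA_character_, m = NA_character_) {
    nid <<- nid + 1L
    id[nid] <<- sprintf("%s_%03d", famid, nid)
    sex[nid] <<- s
    gen[nid] <<- g
    father[nid] <<- f
    mother[nid] <<- m
    id[nid]
  }
  f0 <- newInd("male", 1L)
  m0 <- newInd("female", 1L)
  couples <- list(list(f = f0, m = m0, g = 1L))
  singles <- character(0)   # unmarried non-founders eligible to marry
  singleGen <- integer(0)
  while (nid < size) {
    canMarry <- length(singles) > 0
    marry <- canMarry && stats::runif(1) < 0.35
    if (marry) {
      i <- sample.int(length(singles), 1L)
      who <- singles[i]
      g <- singleGen[i]
      singles <- singles[-i]
      singleGen <- singleGen[-i]
      wsex <- sex[match(who, id)]
      ssex <- if (wsex == "female") "male" else "female"
      sp <- newInd(ssex, g)
      couples[[length(couples) + 1L]] <-
        if (ssex == "male") list(f = sp, m = who, g = g)
        else list(f = who, m = sp, g = g)
    } else {
      fertile <- which(vapply(couples, function(cp) cp$g < maxGen, logical(1)))
      if (!length(fertile)) fertile <- seq_along(couples)
      cp <- couples[[fertile[sample.int(length(fertile), 1L)]]]
      csex <- if (stats::runif(1) < 0.5) "male" else "female"
      ch <- newInd(csex, cp$g + 1L, f = cp$f, m = cp$m)
      if (cp$g + 1L < maxGen) {
        singles <- c(singles, ch)
        singleGen <- c(singleGen, cp$g + 1L)
      }
    }
  }
  data.frame(famid = famid, id = id, father = father, mother = mother,
             sex = sex, stringsAsFactors = FALSE)
}

#' Gene-drop a biallelic variant through a pedigree
#'
#' Founders receive alleles as independent Bernoulli(maf) draws; offspring
#' inherit one randomly chosen allele from each parent. The dosage is the
#' per-individual allele sum.
#'
#' @param ped a [Pedigree-class].
#' @param maf ALT allele frequency in founders, in (0, 0.5]; a vector of
#'   length `n` gives each drop its own frequency.
#' @param n number of independent drops (columns).
#' @param seed optional seed.
#' @return Integer matrix, individuals x drops, with id rownames.
#' @export
geneDrop <- function(ped, maf, n = length(maf), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(maf <= 0) || any(maf > 0.5)) stop("maf must be in (0, 0.5]")
  if (!length(maf) %in% c(1L, n)) stop("maf must have length 1 or n")
  ids <- ped@id
  ni <- length(ids)
  fi <- match(ped@father, ids)
  mi <- match(ped@mother, ids)
  pat <- matrix(0L, ni, n)
  mat <- matrix(0L, ni, n)
  for (i in seq_len(ni)) {
    if (is.na(fi[i])) {
      pat[i, ] <- stats::rbinom(n, 1L, maf)
      mat[i, ] <- stats::rbinom(n, 1L, maf)
    } else {
      pick <- stats::runif(n) < 0.5
      pat[i, ] <- ifelse(pick, pat[fi[i], ], mat[fi[i], ])
      pick <- stats::runif(n) < 0.5
      mat[i, ] <- ifelse(pick, pat[mi[i], ], mat[mi[i], ])
    }
  }
  d <- pat + mat
  rownames(d) <- ids
  d
}

## symmetric matrix square root
.sqrtm <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

## correlation matrix with common off-diagonal rho
.equicor <- function(k, rho) matrix(rho, k, k) + (1 - rho) * diag(k)

#' Simulate longitudinal phenotypes on a pedigree
#'
#' Generates `y_it = mu_t + covariate effects + sum_c beta_c g_ic + a_it
#' + e_it` with polygenic effects `a` drawn from `MVN(0, 2 Phi (x) G)`
#' and residuals from `MVN(0, I (x) E)`; variant effects are constant
#' across time points (`beta_c` from the configured variance fraction).
#'
#' @param ped a [Pedigree-class].
#' @param genos a [GenotypeMatrix-class]; columns whose names appear in
#'   `names(beta)` act as causal variants.
#' @param config a [simConfig()] object.
#' @param beta named per-allele effects; default computed from
#'   `config$causal` for columns `causal_1..`, plus region causal
#'   variants when configured.
#' @param seed optional seed.
#' @param phi optional precomputed kinship matrix for `ped` (saves
#'   recomputation across replicates).
#' @return List with `phen` (a [LongPhenotypes-class]) and `truth`
#'   (effects and variance components used).
#' @export
simPhenotypes <- function(ped, genos, config, beta = NULL, seed = NULL,
                          phi = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- ped@id
  n <- length(ids)
  k <- config$k
  if (is.null(beta)) beta <- .truthBetas(config)
  s2 <- config$sigma2Total
  regionV <- if (is.null(config$region)) 0 else config$region$varFrac
  s2g <- config$h2 * s2
  s2e <- (1 - config$h2 - sum(config$causal$varFrac) - regionV) * s2
  G <- s2g * .equicor(k, config$rhoG)
  E <- s2e * .equicor(k, config$rhoE)
  age <- pmin(pmax(round(stats::rnorm(n, config$meanAge, config$sdAge)), 18), 85)
  sexI <- as.numeric(ped@sex == "female")
  smoke <- stats::rbinom(n, 1L, config$smokePrev)
  fixed <- matrix(config$mu, n, k, byrow = TRUE) +
    config$ageEffect * (age - config$meanAge) +
    config$sexEffect * sexI + config$smokeEffect * smoke
  D <- dosages(genos)[ids, , drop = FALSE]
  use <- intersect(names(beta), colnames(D))
  if (length(use))
    fixed <- fixed + as.vector(D[, use, drop = FALSE] %*% beta[use])
  sqG <- .sqrtm(G)
  sqE <- .sqrtm(E)
  a <- matrix(0, n, k)
  if (is.null(phi)) phi <- kinshipMatrix(ped)
  for (fidx in split(seq_len(n), factor(ped@famid, unique(ped@famid)))) {
    LA <- t(chol(2 * phi[fidx, fidx, drop = FALSE]))
    a[fidx, ] <- LA %*% matrix(stats::rnorm(length(fidx) * k),
                               length(fidx)) %*% sqG
  }
  e <- matrix(stats::rnorm(n * k), n) %*% sqE
  Y <- fixed + a + e
  rownames(Y) <- ids
  cov <- data.frame(age = age, sex = sexI, smoke = smoke, row.names = ids)
  phen <- LongPhenotypes(Y, traitName = "sbp", covariates = cov,
                         pedigree = ped)
  list(phen = phen,
       truth = list(beta = beta, G = G, E = E, h2 = config$h2,
                    rhoG = config$rhoG, rhoE = config$rhoE,
                    sigma2Total = s2, varFrac = config$causal$varFrac))
}

## per-allele effects implied by the configured variance fractions
.truthBetas <- function(config) {
  beta <- numeric(0)
  if (nrow(config$causal)) {
    b <- sqrt(config$causal$varFrac * config$sigma2Total /
                (2 * config$causal$maf * (1 - config$causal$maf)))
    names(b) <- paste0("causal_", seq_along(b))
    beta <- b
  }
  rg <- config$region
  if (!is.null(rg) && rg$varFrac > 0 && rg$nCausal > 0) {
    mafs <- attr(rg, "mafs")  # set by simReplicate once drawn
    per <- rg$varFrac / rg$nCausal
    if (!is.null(mafs)) {
      b <- sqrt(per * config$sigma2Total / (2 * mafs * (1 - mafs)))
      names(b) <- paste0("region_", seq_along(mafs))
      beta <- c(beta, b[seq_len(rg$nCausal)])
    }
  }
  beta
}

#' Simulate one complete study replicate
#'
#' Gene-drops the configured causal, null and (optionally) region
#' variants through the pedigree and simulates the longitudinal trait.
#' The per-replicate truth record suffices to recompute the expected
#' variance decomposition.
#'
#' @param config a [simConfig()] object.
#' @param seed integer seed for this replicate.
#' @param ped optional [Pedigree-class] to reuse (the study design keeps
#'   the pedigree fixed across replicates); generated when `NULL`.
#' @param phi optional precomputed kinship matrix for `ped`.
#' @return List with `ped`, `genos`, `phen`, `truth`, `seed`.
#' @export
simReplicate <- function(config, seed = 1L, ped = NULL, phi = NULL) {
  set.seed(seed)
  if (is.null(ped))
    ped <- simPedigrees(config$nPedigrees, config$totalSize)
  ncau <- nrow(config$causal)
  inf <- data.frame(name = character(0), chrom = character(0),
                    pos = integer(0), maf = numeric(0))
  if (ncau)
    inf <- rbind(inf, data.frame(
      name = paste0("causal_", seq_len(ncau)), chrom = "3",
      pos = 48000000L + seq_len(ncau) * 1000L, maf = config$causal$maf))
  if (config$nullVariants > 0)
    inf <- rbind(inf, data.frame(
      name = paste0("null_", seq_len(config$nullVariants)), chrom = "9",
      pos = 12000000L + seq_len(config$nullVariants) * 1000L,
      maf = stats::runif(config$nullVariants, config$nullMafRange[1],
                         config$nullMafRange[2])))
  rg <- config$region
  if (!is.null(rg)) {
    mafs <- stats::runif(rg$m, rg$mafRange[1], rg$mafRange[2])
    attr(rg, "mafs") <- mafs
    config$region <- rg
    inf <- rbind(inf, data.frame(
      name = paste0("region_", seq_len(rg$m)), chrom = "3",
      pos = 47887577L + seq_len(rg$m) * 250L, maf = mafs))
  }
  D <- geneDrop(ped, inf$maf, n = nrow(inf))
  colnames(D) <- inf$name
  storage.mode(D) <- "double"
  gr <- GenomicRanges::GRanges(inf$chrom, IRanges::IRanges(inf$pos, width = 1L),
                               ref = "A", alt = "G")
  names(gr) <- inf$name
  genos <- GenotypeMatrix(D, gr, pedigree = ped)
  sim <- simPhenotypes(ped, genos, config, phi = phi)
  list(ped = ped, genos = genos, phen = sim$phen,
       truth = c(sim$truth, list(seed = seed)), seed = seed)
}
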