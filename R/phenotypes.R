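#' @include AllClasses.R
NULL

#' Construct a LongPhenotypes object
#'
#' @param trait numeric matrix (individuals x time points) with id
#'   rownames, or a vector for a single time point.
#' @param traitName name of the trait.
#' @param covariates data.frame of per-individual covariates, rownames
#'   matching `trait` (reordered if needed).
#' @param pedigree optional [Pedigree-class]; when given, every phenotyped
#'   id must be a pedigree member (hard error otherwise — silently adding
#'   unrelated founders would corrupt the kinship model).
#' @return A [LongPhenotypes-class].
#' @export
LongPhenotypes <- function(trait, traitName = "trait",
                           covariates = NULL, pedigree = NULL) {
  if (is.null(dim(trait))) trait <- cbind(trait)
  trait <- as.matrix(trait)
  storage.mode(trait) <- "double"
  if (is.null(rownames(trait))) stop("trait matrix needs id rownames")
  colnames(trait) <- paste0(traitName, "_", seq_len(ncol(trait)))
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = rownames(trait))
  } else {
    if (is.null(rownames(covariates)) ||
        !setequal(rownames(covariates), rownames(trait)))
      stop("covariate rownames must match trait ids")
    covariates <- covariates[rownames(trait), , drop = FALSE]
  }
  if (!is.null(pedigree)) {
    extra <- setdiff(rownames(trait), pedIds(pedigree))
    if (length(extra))
      stop("phenotyped individual(s) not in the pedigree: ",
           paste(utils::head(extra, 10), collapse = ", "))
  }
  methods::new("LongPhenotypes", trait = trait, traitName = traitName,
               covariates = covariates)
}

#' Read a longitudinal phenotype table
#'
#' Wide format: one row per individual with columns `<trait>_1` ..
#' `<trait>_k` plus an `id` column and any covariate columns. Long format:
#' columns `id`, `visit`, `value` (plus covariates constant within id).
#' Missing visits stay `NA`. Sex/smoking-style binary covariates should
#' already be coded 0/1.
#'
#' @param path delimited text file (TSV/CSV autodetected from header).
#' @param trait trait name (prefix of the wide columns).
#' @param timePoints number of time points k; checked against the columns
#'   in wide format, used to dimension the matrix in long format.
#' @param format `"wide"` or `"long"`.
#' @param pedigree optional [Pedigree-class] for id checking.
#' @return A [LongPhenotypes-class].
#' @export
readPhenotypes <- function(path, trait, timePoints, format = c("wide", "long"),
                           pedigree = NULL) {
  format <- match.arg(format)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl(",", hdr) && !grepl("\t", hdr)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% colnames(df)) stop("phenotype file needs an 'id' column")
  df$id <- as.character(df$id)
  if (format == "wide") {
    want <- paste0(trait, "_", seq_len(timePoints))
    if (!all(want %in% colnames(df)))
      stop("expected columns ", paste(setdiff(want, colnames(df)),
                                      collapse = ", "),
           " for trait '", trait, "' with k = ", timePoints)
    if (anyDuplicated(df$id)) stop("duplicated id(s) in wide table")
    Y <- as.matrix(df[, want])
    rownames(Y) <- df$id
    cov <- df[, setdiff(colnames(df), c("id", want)), drop = FALSE]
    rownames(cov) <- df$id
  } else {
    need <- c("id", "visit", "value")
    if (!all(need %in% colnames(df)))
      stop("long format needs columns id, visit, value")
    if (anyDuplicated(df[, c("id", "visit")]))
      stop("duplicate (id, visit) record(s)")
    if (any(df$visit < 1 | df$visit > timePoints))
      stop("visit outside 1..", timePoints)
    ids <- unique(df$id)
    Y <- matrix(NA_real_, length(ids), timePoints,
                dimnames = list(ids, NULL))
    Y[cbind(match(df$id, ids), df$visit)] <- df$value
    covcols <- setdiff(colnames(df), need)
    cov <- df[!duplicated(df$id), covcols, drop = FALSE]
    rownames(cov) <- df$id[!duplicated(df$id)]
    cov <- cov[ids, , drop = FALSE]
  }
  LongPhenotypes(Y, traitName = trait, covariates = cov, pedigree = pedigree)
}

#' Write phenotypes in wide format
#'
#' Inverse of `readPhenotypes(..., format = "wide")`.
#'
#' @param phen a [LongPhenotypes-class].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(phen, path) {
  df <- data.frame(id = rownames(phen@trait), phen@trait,
                   phen@covariates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default covariate candidate set
#'
#' Builds the candidate design used for screening: baseline age (centered),
#' sex (0 = male, 1 = female), age x sex, age squared, age squared x sex,
#' and smoking — provided the required columns (`age`, `sex`, `smoke`)
#' exist in the covariate table.
#'
#' @param phen a [LongPhenotypes-class] whose covariates contain `age`,
#'   `sex` and optionally `smoke`.
#' @return Numeric matrix of candidate covariate columns.
#' @export
covariateCandidates <- function(phen) {
  cv <- covariates(phen)
  out <- list()
  if ("age" %in% colnames(cv)) {
    age <- cv$age - mean(cv$age, na.rm = TRUE)
    out$age <- age
    out$age2 <- age^2
    if ("sex" %in% colnames(cv)) {
      sx <- as.numeric(cv$sex)
      out$sex <- sx
      out$age.sex <- age * sx
      out$age2.sex <- age^2 * sx
    }
  } else if ("sex" %in% colnames(cv)) {
    out$sex <- as.numeric(cv$sex)
  }
  if ("smoke" %in% colnames(cv)) out$smoke <- as.numeric(cv$smoke)
  if (!length(out)) stop("no candidate covariates available")
  m <- do.call(cbind, out)
  rownames(m) <- rownames(cv)
  m[, c("age", "sex", "age.sex", "age2", "age2.sex", "smoke")[
    c("age", "sex", "age.sex", "age2", "age2.sex", "smoke") %in% colnames(m)],
    drop = FALSE]
}
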