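#' @include AllClasses.R
NULL

## Kahn topological sort over the parent graph; errors name a cycle.
.topoOrder <- function(id, father, mother) {
  n <- length(id)
  fi <- match(father, id)
  mi <- match(mother, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (c in kids[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving: ",
         paste(id[cyc], collapse = ", "))
  }
  out
}

#' Construct and validate a pedigree
#'
#' Validates parent references, sex consistency and acyclicity, synthesizes
#' an anonymous founder for a half-specified parent (with a warning), and
#' reorders individuals so that parents always precede offspring.
#'
#' @param famid,id,father,mother,sex character vectors, one entry per
#'   individual. Missing parents are `NA` (or `"0"`); `sex` accepts
#'   `"male"`/`"female"`/`"unknown"` or the PLINK codes `1`/`2`/`0`.
#' @return A validated, topologically sorted [Pedigree-class].
#' @examples
#' ped <- Pedigree(famid = rep("f1", 3), id = c("dad", "mum", "kid"),
#'                 father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
#'                 sex = c("male", "female", "female"))
#' founders(ped)
#' @export
Pedigree <- function(famid, id, father, mother, sex) {
  famid <- as.character(famid)
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  sex <- as.character(sex)
  father[father %in% c("0", "")] <- NA_character_
  mother[mother %in% c("0", "")] <- NA_character_
  map <- c("1" = "male", "2" = "female", "0" = "unknown",
           male = "male", female = "female", unknown = "unknown")
  if (!all(sex %in% names(map)))
    stop("unrecognized sex code(s): ",
         paste(unique(sex[!sex %in% names(map)]), collapse = ", "))
  sex <- unname(map[sex])
  if (length(id) == 0L) stop("no individuals")
  if (anyDuplicated(id))
    stop("duplicated individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))

  ## half-specified parents: synthesize an anonymous founder
  half <- which(xor(is.na(father), is.na(mother)))
  if (length(half)) {
    warning("synthesizing anonymous founder(s) for half-specified parents of: ",
            paste(id[half], collapse = ", "))
    for (i in half) {
      stub <- paste0("<anon", length(id) + 1L, ">")
      if (is.na(father[i])) {
        father[i] <- stub
        s <- "male"
      } else {
        mother[i] <- stub
        s <- "female"
      }
      famid <- c(famid, famid[i])
      id <- c(id, stub)
      father <- c(father, NA_character_)
      mother <- c(mother, NA_character_)
      sex <- c(sex, s)
    }
  }

  self <- (!is.na(father) & father == id) | (!is.na(mother) & mother == id)
  if (any(self))
    stop("pedigree contains a cycle involving: ",
         paste(id[self], collapse = ", "))

  bad <- !is.na(father) & !(father %in% id)
  if (any(bad))
    stop("dangling father id(s): ", paste(unique(father[bad]), collapse = ", "))
  bad <- !is.na(mother) & !(mother %in% id)
  if (any(bad))
    stop("dangling mother id(s): ", paste(unique(mother[bad]), collapse = ", "))

  fx <- match(father, id)
  if (any(!is.na(fx) & sex[fx] == "female"))
    stop("sex inconsistency: female individual named as father: ",
         paste(unique(id[fx[!is.na(fx) & sex[fx] == "female"]]), collapse = ", "))
  mx <- match(mother, id)
  if (any(!is.na(mx) & sex[mx] == "male"))
    stop("sex inconsistency: male individual named as mother: ",
         paste(unique(id[mx[!is.na(mx) & sex[mx] == "male"]]), collapse = ", "))

  ord <- .topoOrder(id, father, mother)
  methods::new("Pedigree", famid = famid[ord], id = id[ord],
               father = father[ord], mother = mother[ord], sex = sex[ord])
}

#' Additive kinship matrix of a pedigree
#'
#' Computes the matrix of kinship coefficients Phi by the recursive tabular
#' method over the topological order: for founders phi(i,i) = 1/2 and
#' phi(i,j) = 0 between founders; for a non-founder i with parents f, m,
#' phi(i,i) = 1/2 + phi(f,m)/2 and phi(i,j) = (phi(f,j) + phi(m,j))/2 for
#' any j processed before i. Inbreeding loops are supported; diagonal
#' entries exceed 1/2 exactly when an individual is inbred.
#'
#' @param x a [Pedigree-class].
#' @param ids optional character vector: order of rows/columns in the
#'   result (default: pedigree order).
#' @return Symmetric numeric matrix of kinship coefficients with id
#'   dimnames. Multiply by 2 to obtain the additive relationship matrix.
#' @examples
#' ped <- Pedigree(rep("f", 4), c("a", "b", "c", "d"),
#'                 c(NA, NA, "a", "a"), c(NA, NA, "b", "b"),
#'                 c("male", "female", "male", "female"))
#' kinshipMatrix(ped)["c", "d"]  # full sibs: 1/4
#' @export
setMethod("kinshipMatrix", "Pedigree", function(x, ids = NULL, ...) {
  id <- x@id
  n <- length(id)
  fi <- match(x@father, id)
  mi <- match(x@mother, id)
  phi <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fi[i]
      m <- mi[i]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        v <- 0.5 * (phi[f, j] + phi[m, j])
        phi[i, j] <- v
        phi[j, i] <- v
      }
      phi[i, i] <- 0.5 + 0.5 * phi[f, m]
    }
  }
  if (!is.null(ids)) {
    if (!all(ids %in% id)) stop("unknown id(s) requested")
    phi <- phi[ids, ids, drop = FALSE]
  }
  phi
})

## Drop allele labels through a pedigree: founders receive unique labels,
## offspring inherit one random allele per parent. Returns two n x ndrops
## integer matrices (paternal and maternal allele labels).
.dropLabels <- function(ped, ndrops) {
  id <- ped@id
  n <- length(id)
  fi <- match(ped@father, id)
  mi <- match(ped@mother, id)
  pat <- matrix(0L, n, ndrops)
  mat <- matrix(0L, n, ndrops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      pat[i, ] <- lab + 1L
      mat[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(ndrops) < 0.5
      pat[i, ] <- ifelse(pick, pat[fi[i], ], mat[fi[i], ])
      pick <- stats::runif(ndrops) < 0.5
      mat[i, ] <- ifelse(pick, pat[mi[i], ], mat[mi[i], ])
    }
  }
  list(pat = pat, mat = mat)
}

#' Monte-Carlo kinship estimate by gene dropping
#'
#' Independent cross-check of [kinshipMatrix()]: founder alleles receive
#' unique labels, alleles are transmitted by Mendelian sampling, and the
#' kinship coefficient of a pair is estimated as the frequency with which
#' one random allele from each is identical by descent.
#'
#' @param ped a [Pedigree-class].
#' @param ndrops integer, number of independent gene drops.
#' @return Symmetric matrix of estimated kinship coefficients.
#' @export
mcKinship <- function(ped, ndrops = 1e5) {
  drop <- .dropLabels(ped, ndrops)
  pat <- drop$pat
  mat <- drop$mat
  n <- nrow(pat)
  phi <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    phi[i, i] <- 0.5 + 0.5 * mean(pat[i, ] == mat[i, ])
    if (i < n) {
      for (j in seq((i + 1L), n)) {
        s <- (pat[i, ] == pat[j, ]) + (pat[i, ] == mat[j, ]) +
          (mat[i, ] == pat[j, ]) + (mat[i, ] == mat[j, ])
        phi[i, j] <- phi[j, i] <- mean(s) / 4
      }
    }
  }
  phi
}

#' Read a PLINK-style FAM/PED pedigree file
#'
#' Expects whitespace-delimited columns famid, id, father, mother, sex
#' (any further columns, e.g. a phenotype, are ignored). `"0"` marks a
#' missing parent; sex is coded 1 = male, 2 = female, 0 = unknown.
#'
#' @param path file path.
#' @return A validated [Pedigree-class].
#' @export
readPedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no individuals in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 5L))
    stop("malformed pedigree line ", which(nf < 5L)[1L], " in ", path,
         ": expected at least 5 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:5))
  Pedigree(famid = m[, 1], id = m[, 2], father = m[, 3], mother = m[, 4],
           sex = m[, 5])
}

#' Write a pedigree as a 6-column FAM file
#'
#' @param ped a [Pedigree-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  sexcode <- c(male = "1", female = "2", unknown = "0")
  df <- data.frame(ped@famid, ped@id,
                   ifelse(is.na(ped@father), "0", ped@father),
                   ifelse(is.na(ped@mother), "0", ped@mother),
                   sexcode[ped@sex], "-9")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a kinship matrix
#'
#' Writes either the square matrix as TSV with an id header row/column, or
#' a long-format table `(id1, id2, phi)` of the upper triangle including
#' the diagonal.
#'
#' @param phi kinship matrix with id dimnames, from [kinshipMatrix()].
#' @param path output file.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writeKinship <- function(phi, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(phi, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(phi)[idx[, 1]],
                     id2 = colnames(phi)[idx[, 2]],
                     phi = phi[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
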