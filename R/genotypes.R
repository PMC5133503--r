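#' @include AllClasses.R
NULL

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of ALT-allele counts (0/1/2, `NA`
#'   missing), individuals x variants, with id rownames.
#' @param variants [GenomicRanges::GRanges] with one range per variant
#'   (names = variant ids; metadata columns `ref`, `alt` optional).
#' @param pedigree optional [Pedigree-class]; all genotyped ids must be
#'   members.
#' @return A [GenotypeMatrix-class]; ALT allele frequencies are computed
#'   from non-missing calls.
#' @export
GenotypeMatrix <- function(dosage, variants, pedigree = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(colnames(dosage)) && !is.null(names(variants)))
    colnames(dosage) <- names(variants)
  if (!is.null(pedigree)) {
    extra <- setdiff(rownames(dosage), pedIds(pedigree))
    if (length(extra))
      stop("genotyped individual(s) not in the pedigree: ",
           paste(utils::head(extra, 10), collapse = ", "))
  }
  af <- colMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  methods::new("GenotypeMatrix", dosage = dosage, variants = variants,
               af = unname(af))
}

## GT string ("0/0", "0|1", "./.") -> ALT dosage
.gtToDosage <- function(gt) {
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  out[gt %in% c("1/1", "1|1")] <- 2
  out
}

#' Read biallelic SNVs from a VCF file
#'
#' Reads GT fields into additive ALT-allele dosages. Multi-allelic records
#' and non-SNV alleles are skipped with a warning; `./.` becomes `NA`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional [GenomicRanges::GRanges]; only variants
#'   overlapping it are kept.
#' @param pedigree optional [Pedigree-class]; the samples must all be
#'   members and at least one sample is required.
#' @return A [GenotypeMatrix-class].
#' @export
readVCF <- function(path, region = NULL, pedigree = NULL) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  alt <- VariantAnnotation::alt(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  multi <- lengths(alt) != 1L
  altc <- rep(NA_character_, length(ref))
  altc[!multi] <- as.character(unlist(alt[!multi]))
  keep <- !multi & nchar(ref) == 1L & nchar(altc) == 1L &
    altc %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " multi-allelic or non-SNV record(s) skipped")
  vcf <- vcf[keep]
  altc <- altc[keep]
  ref <- ref[keep]
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!is.null(region)) {
    hit <- suppressWarnings(
      IRanges::overlapsAny(rr, region, ignore.strand = TRUE))
    vcf <- vcf[hit]
    rr <- rr[hit]
    ref <- ref[hit]
    altc <- altc[hit]
  }
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- apply(gt, 2L, .gtToDosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L)
  dos <- t(dos)  # individuals x variants
  rownames(dos) <- colnames(gt)
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rr),
                               IRanges::ranges(rr),
                               ref = ref, alt = altc)
  names(gr) <- rownames(vcf)
  colnames(dos) <- names(gr)
  if (!is.null(pedigree)) {
    if (!any(rownames(dos) %in% pedIds(pedigree)))
      stop("no VCF sample overlaps the pedigree")
  }
  GenotypeMatrix(dos, gr, pedigree = pedigree)
}

#' Write a GenotypeMatrix as a VCF file
#'
#' @param genos a [GenotypeMatrix-class].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
writeVCF <- function(genos, path) {
  gr <- variants(genos)
  d <- dosages(genos)
  ref <- if (!is.null(gr$ref)) gr$ref else rep("A", length(gr))
  alt <- if (!is.null(gr$alt)) gr$alt else rep("G", length(gr))
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", ncol(d), nrow(d),
               dimnames = list(colnames(d), rownames(d)))
  ok <- !is.na(t(d))
  gt[ok] <- gtmap[round(t(d)[ok]) + 1L]
  rr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               IRanges::ranges(gr))
  names(rr) <- names(gr)
  hdr <- VariantAnnotation::VCFHeader(samples = rownames(d))
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    META = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  v <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_len(nrow(d)),
                                   row.names = rownames(d)),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(ref),
      ALT = Biostrings::DNAStringSetList(as.list(alt)),
      QUAL = rep(NA_real_, length(gr)),
      FILTER = rep(".", length(gr))),
    geno = S4Vectors::SimpleList(GT = gt))
  S4Vectors::metadata(v)$header <- hdr
  VariantAnnotation::writeVcf(v, path)
  ## htslib requires ##fileformat as the very first line
  ln <- readLines(path)
  fmt <- grep("^##fileformat", ln)
  if (!identical(fmt, 1L))
    writeLines(c(ln[fmt[1]], ln[-fmt]), path)
  invisible(path)
}

#' Read genomic regions from a BED file
#'
#' Thin wrapper over [rtracklayer::import()]; BED's 0-based half-open
#' coordinates are converted to the 1-based closed GRanges convention on
#' read. The BED name column becomes the region label.
#'
#' @param path BED file.
#' @return A [GenomicRanges::GRanges] with names from the BED name column.
#' @export
readRegions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

## mean-dosage imputation (2 * ALT frequency) for missing calls
.imputeDosage <- function(g, af = NULL) {
  if (!anyNA(g)) return(g)
  if (is.null(af)) af <- mean(g, na.rm = TRUE) / 2
  g[is.na(g)] <- 2 * af
  g
}
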