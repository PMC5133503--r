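#' @keywords internal
#' @useDynLib longvc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats pchisq rnorm runif rbinom sd cov cov2cor nlminb
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges overlapsAny ranges
"_PACKAGE"
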