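#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqinfo Seqinfo
#' @importFrom BiocGenerics strand strand<- width
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom Rcpp sourceCpp
#' @useDynLib duripop, .registration = TRUE
NULL

#' GenotypePanel: a diploid biallelic SNP panel
#'
#' The central container of the package: a variants x samples matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for a missing call) together
#' with the variant coordinates and alleles as a [GenomicRanges::GRanges]
#' (metadata columns `ref` and `alt`, single nucleotides). Variants are
#' sorted by (chromosome, position) with no duplicate sites; all variants
#' are biallelic SNPs. Rows follow the Bioconductor features-first
#' orientation; columns are named by sample id.
#'
#' Construct with [GenotypePanel()]; interrogate with [nSamples()],
#' [nVariants()], [sampleIds()], [loci()] and [dosages()].
#'
#' @slot dosage integer matrix, variants x samples, entries in `c(0:2, NA)`.
#' @slot loci `GRanges` of width-1 SNP positions with `ref`/`alt` columns.
#' @slot metadata list of free-form provenance (filter counts, simulation
#'   truth, chromosome lengths via `seqlengths` of `loci`).
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(
    dosage = "matrix",
    loci = "GRanges",
    metadata = "list"
  )
)

.validGenotypePanel <- function(object) {
  msg <- character()
  d <- object@dosage
  g <- object@loci
  if (!is.numeric(d) && !is.integer(d)) {
    msg <- c(msg, "dosage must be a numeric matrix")
  }
  if (ncol(d) < 1L) msg <- c(msg, "panel must contain at least one sample")
  if (nrow(d) != length(g)) {
    msg <- c(msg, "nrow(dosage) must equal length(loci)")
  }
  if (is.null(colnames(d)) || anyDuplicated(colnames(d))) {
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (length(g)) {
    mc <- mcols(g)
    if (!all(c("ref", "alt") %in% colnames(mc))) {
      msg <- c(msg, "loci must carry 'ref' and 'alt' metadata columns")
    } else {
      bases <- c("A", "C", "G", "T")
      if (!all(mc$ref %in% bases) || !all(mc$alt %in% bases)) {
        msg <- c(msg, "ref and alt must be single nucleotides (A/C/G/T)")
      }
      if (any(mc$ref == mc$alt)) {
        msg <- c(msg, "ref and alt alleles must differ")
      }
    }
    chr <- as.integer(seqnames(g))
    pos <- start(g)
    if (is.unsorted(order(chr, pos)) ||
        any(diff(chr) < 0) ||
        any(diff(pos)[diff(chr) == 0] <= 0)) {
      msg <- c(msg, "variants must be sorted by (chrom, pos) without duplicates")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("GenotypePanel", .validGenotypePanel)

#' AdmixtureFit: maximum-likelihood admixture model fit
#'
#' Result of [admixtureEM()]: ancestry fractions `Q` (samples x K, rows on
#' the simplex), cluster allele frequencies `F` (K x loci, clamped to
#' `[1e-6, 1 - 1e-6]`), the log-likelihood trace of the EM iterations
#' (non-decreasing by construction), and convergence bookkeeping.
#'
#' @slot Q numeric matrix samples x K; rows sum to 1.
#' @slot F numeric matrix K x loci of cluster alternate-allele frequencies.
#' @slot logLik numeric vector, per-iteration log-likelihood trace.
#' @slot converged logical flag.
#' @slot nIterations integer, iterations used by the best restart.
#' @aliases AdmixtureFit-class
#' @exportClass AdmixtureFit
setClass("AdmixtureFit",
  representation(
    Q = "matrix",
    F = "matrix",
    logLik = "numeric",
    converged = "logical",
    nIterations = "integer"
  )
)

setValidity("AdmixtureFit", function(object) {
  msg <- character()
  if (nrow(object@F) != ncol(object@Q)) {
    msg <- c(msg, "ncol(Q) must equal nrow(F) (both are K)")
  }
  if (any(abs(rowSums(object@Q) - 1) > 1e-8)) {
    msg <- c(msg, "rows of Q must sum to 1 (tolerance 1e-8)")
  }
  if (any(object@F < 1e-6 - 1e-12 | object@F > 1 - 1e-6 + 1e-12)) {
    msg <- c(msg, "F entries must lie in [1e-6, 1 - 1e-6]")
  }
  if (any(diff(object@logLik) < -1e-6)) {
    msg <- c(msg, "log-likelihood trace must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})
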