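#' Construct a GenotypePanel
#'
#' @param dosage numeric/integer matrix of alternate-allele dosages,
#'   variants x samples, values 0/1/2 or `NA` (missing call). Column names
#'   are the sample ids; if absent, `S1..Sn` are assigned.
#' @param chrom character vector of chromosome names, one per variant.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @param seqlengths optional named vector of chromosome lengths.
#' @param metadata free-form provenance list.
#' @param sort reorder variants by (chrom, pos) if needed (default TRUE;
#'   chromosome order is order of first appearance unless `seqlengths`
#'   names impose one).
#'
#' @return A [GenotypePanel-class] object.
#' @examples
#' p <- GenotypePanel(matrix(c(0, 1, 2, NA), 2, 2,
#'                           dimnames = list(NULL, c("a", "b"))),
#'                    chrom = c("chr1", "chr1"), pos = c(10L, 20L),
#'                    ref = c("A", "C"), alt = c("G", "T"))
#' nVariants(p)
#' @export
GenotypePanel <- function(dosage, chrom, pos, ref, alt,
                          seqlengths = NULL, metadata = list(),
                          sort = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  }
  lev <- if (!is.null(seqlengths)) names(seqlengths) else unique(chrom)
  chrom <- factor(chrom, levels = lev)
  if (sort && length(pos)) {
    o <- order(as.integer(chrom), pos)
    dosage <- dosage[o, , drop = FALSE]
    chrom <- chrom[o]
    pos <- pos[o]
    ref <- ref[o]
    alt <- alt[o]
  }
  loci <- GRanges(chrom, IRanges(pos, width = 1L), ref = as.character(ref),
                  alt = as.character(alt))
  if (!is.null(seqlengths)) {
    seqlengths(loci) <- seqlengths[seqlevels(loci)]
  }
  rownames(dosage) <- NULL
  new("GenotypePanel", dosage = dosage, loci = loci, metadata = metadata)
}

#' @rdname GenotypePanel
#' @param x,object a `GenotypePanel`.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypePanel
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname GenotypePanel
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypePanel
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname GenotypePanel
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypePanel
#' @export
setMethod("nSamples", "GenotypePanel", function(x) ncol(x@dosage))

#' @rdname GenotypePanel
#' @export
setMethod("nVariants", "GenotypePanel", function(x) nrow(x@dosage))

#' @rdname GenotypePanel
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) colnames(x@dosage))

#' @rdname GenotypePanel
#' @export
setMethod("loci", "GenotypePanel", function(x) x@loci)

#' @rdname GenotypePanel
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosage)

#' @rdname GenotypePanel
#' @export
setMethod("show", "GenotypePanel", function(object) {
  d <- object@dosage
  cat("GenotypePanel:", nrow(d), "biallelic SNPs x", ncol(d), "samples\n")
  if (length(object@loci)) {
    cat("  chromosomes:", paste(seqlevels(object@loci), collapse = ", "), "\n")
  }
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (length(object@metadata)) {
    cat("  metadata fields:", paste(names(object@metadata), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Subset a GenotypePanel
#'
#' `x[i, j]` keeps variants `i` (logical or integer over variants) and
#' samples `j` (logical, integer or character sample ids). Variant order
#' is preserved; `i` must therefore select in genomic order.
#'
#' @param x a `GenotypePanel`.
#' @param i variant index.
#' @param j sample index or ids.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  if (is.character(j)) j <- match(j, colnames(x@dosage))
  if (anyNA(j)) stop("unknown sample id in subset")
  new("GenotypePanel",
      dosage = x@dosage[i, j, drop = FALSE],
      loci = x@loci[i],
      metadata = x@metadata)
})

#' Per-variant allele bookkeeping for one set of samples
#'
#' Counts, for every variant, the number of non-missing alleles, the
#' alternate-allele count and the heterozygote count among the given
#' samples. The workhorse behind the diversity and differentiation
#' statistics.
#'
#' @param panel a `GenotypePanel`.
#' @param samples character sample ids, or NULL for all samples.
#' @return data.frame with columns `nAllele`, `nAlt`, `nHet`, `nGeno`.
#' @keywords internal
alleleCounts <- function(panel, samples = NULL) {
  d <- panel@dosage
  if (!is.null(samples)) {
    idx <- match(samples, colnames(d))
    if (anyNA(idx)) {
      stop("unknown sample id(s): ",
           paste(samples[is.na(idx)], collapse = ", "))
    }
    d <- d[, idx, drop = FALSE]
  }
  ok <- !is.na(d)
  nGeno <- rowSums(ok)
  nAlt <- rowSums(d, na.rm = TRUE)
  nHet <- rowSums(d == 1L, na.rm = TRUE)
  data.frame(nAllele = 2L * nGeno, nAlt = nAlt, nHet = nHet, nGeno = nGeno)
}

#' Resolve a population label to its sample ids
#' @keywords internal
popSamples <- function(sampleInfo, population) {
  if (!population %in% sampleInfo$population) {
    stop("unknown population label: ", population)
  }
  sampleInfo$sample_id[sampleInfo$population == population]
}

#' Validate a sample metadata table
#'
#' @param sampleInfo data.frame with columns `sample_id`, `population`,
#'   `origin`.
#' @param populations closed set of allowed population labels;
#'   `"unassigned"` is always allowed.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateSampleInfo <- function(sampleInfo,
                               populations = c("POP1", "POP2", "POP3")) {
  stopifnot(all(c("sample_id", "population", "origin") %in%
                colnames(sampleInfo)))
  if (anyDuplicated(sampleInfo$sample_id)) {
    stop("sample ids must be unique")
  }
  bad <- setdiff(unique(sampleInfo$population), c(populations, "unassigned"))
  if (length(bad)) {
    stop("population labels outside the declared set: ",
         paste(bad, collapse = ", "))
  }
  sampleInfo
}
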