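#' Filtering thresholds for a SNP panel
#'
#' Defaults mirror the standard post-calling filters for a resequencing
#' panel: drop a site when its missing-call fraction exceeds 20% or its
#' minor allele frequency falls below 0.01 (computed from non-missing
#' alleles). Thresholds are strict: a site is removed if missingness
#' `>` `maxMissingFraction` or MAF `<` `minMAF`, so a site at exactly the
#' boundary is retained.
#'
#' @param maxMissingFraction maximum tolerated missing-call fraction.
#' @param minMAF minimum minor allele frequency.
#' @param biallelicOnly keep only biallelic SNPs (always true for panels
#'   built by [readVCF()], which drops other records on input).
#' @return A `filterSpec` list.
#' @export
filterSpec <- function(maxMissingFraction = 0.20, minMAF = 0.01,
                       biallelicOnly = TRUE) {
  stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1,
            minMAF >= 0, minMAF <= 0.5)
  structure(list(maxMissingFraction = maxMissingFraction,
                 minMAF = minMAF,
                 biallelicOnly = biallelicOnly),
            class = "filterSpec")
}

#' Read a multi-sample VCF into a GenotypePanel
#'
#' Only biallelic SNP records are kept; multi-allelic records and records
#' whose REF or ALT is not a single nucleotide are dropped and counted.
#' GT fields are converted to alternate-allele dosages; `.` alleles and
#' `./.`-style calls become `NA`. Phased (`|`) and unphased (`/`)
#' separators are both accepted.
#'
#' @param path VCF file (plain or gzip).
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction.
#' @param verbose log the exclusion counts.
#' @return A [GenotypePanel-class]; exclusion counts are stored in
#'   `metadata(panel)$vcf_exclusions`.
#' @export
readVCF <- function(path, region = NULL, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (ncol(gt) < 2L) stop("VCF contains no sample columns")
  n0 <- nrow(fix)
  if (n0 == 0L) {
    return(GenotypePanel(matrix(integer(), 0, ncol(gt) - 1L,
                                dimnames = list(NULL, colnames(gt)[-1L])),
                         chrom = character(), pos = integer(),
                         ref = character(), alt = character()))
  }
  bases <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  nExcluded <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (!is.null(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(m)) stop("malformed region: ", region)
    sel <- chrom == m[2]
    if (nzchar(m[3])) sel <- sel & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    fix <- fix[sel, , drop = FALSE]
    gt <- gt[sel, , drop = FALSE]
    chrom <- chrom[sel]
    pos <- pos[sel]
  }
  samples <- colnames(gt)[-1L]
  # first sub-field of FORMAT is GT per VCF spec ordering requirement
  gtOnly <- sub(":.*$", "", gt[, -1L, drop = FALSE])
  a1 <- substr(gtOnly, 1L, 1L)
  a2 <- substr(gtOnly, 3L, 3L)
  dose <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dosage <- matrix(dose, nrow = nrow(gt), ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (verbose && nExcluded > 0L) {
    message(nExcluded, " non-SNP or multi-allelic record(s) dropped")
  }
  GenotypePanel(dosage, chrom = chrom, pos = pos,
                ref = fix[, "REF"], alt = fix[, "ALT"],
                metadata = list(vcf_exclusions = c(non_biallelic_snp = nExcluded)))
}

#' Write a GenotypePanel as a GT-only VCFv4.2 file
#'
#' One biallelic SNP per record; missing calls are written `./.`. The
#' body is deterministic, so write - read - write round-trips to
#' byte-identical body lines.
#'
#' @param panel a `GenotypePanel`.
#' @param path output path; a `.gz` suffix gzips the output.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(panel, path) {
  g <- panel@loci
  hdr <- c("##fileformat=VCFv4.2",
           "##source=duripop",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  sl <- seqlengths(g)
  if (length(sl) && !anyNA(sl)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl), sl))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sampleIds(panel)),
                      collapse = "\t"))
  d <- panel@dosage
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtcode[d[ok] + 1L]
  body <- if (nrow(d)) {
    paste(as.character(seqnames(g)), start(g), ".",
          mcols(g)$ref, mcols(g)$alt, ".", "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"),
          sep = "\t")
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Filter a panel on missingness and minor allele frequency
#'
#' Retains a variant when its missing-call fraction is at most
#' `spec$maxMissingFraction` and its MAF (over non-missing alleles) is at
#' least `spec$minMAF`. Variant order is preserved; the operation is
#' idempotent. Per-rule exclusion counts are stored in
#' `metadata(panel)$filter_exclusions`.
#'
#' @param panel a `GenotypePanel`.
#' @param spec a [filterSpec()].
#' @return the filtered `GenotypePanel`.
#' @export
filterVariants <- function(panel, spec = filterSpec()) {
  ac <- alleleCounts(panel)
  n <- nSamples(panel)
  missFrac <- 1 - ac$nGeno / n
  p <- ifelse(ac$nAllele > 0, ac$nAlt / ac$nAllele, 0)
  maf <- pmin(p, 1 - p)
  dropMiss <- missFrac > spec$maxMissingFraction
  dropMAF <- !dropMiss & (ac$nAllele == 0 | maf < spec$minMAF)
  keep <- !dropMiss & !dropMAF
  if (!any(keep)) warning("all variants removed by filtering")
  out <- panel[keep, ]
  out@metadata$filter_exclusions <- c(missingness = sum(dropMiss),
                                      maf = sum(dropMAF))
  out
}

## ---- gene models -----------------------------------------------------

#' Construct a gene-model set
#'
#' A light container for GFF3-style gene models: gene spans, per-transcript
#' exon and CDS intervals (1-based inclusive, stored ascending regardless
#' of strand) and CDS phase. CDS intervals must nest inside exon
#' intervals.
#'
#' @param genes `GRanges` with metadata column `gene_id` and strand.
#' @param exons named `GRangesList`, one element per transcript.
#' @param cds named `GRangesList`, one element per transcript, each range
#'   carrying a `phase` metadata column.
#' @param txGene named character vector transcript id -> gene id.
#' @return A `GeneModelSet` list.
#' @export
GeneModelSet <- function(genes, exons, cds, txGene) {
  stopifnot("gene_id" %in% colnames(mcols(genes)),
            all(names(cds) %in% names(exons)),
            all(names(txGene) == names(exons)))
  for (tx in names(cds)) {
    ov <- findOverlaps(cds[[tx]], exons[[tx]], type = "within")
    if (length(unique(queryHits(ov))) != length(cds[[tx]])) {
      stop("CDS intervals of ", tx, " are not nested in its exons")
    }
  }
  structure(list(genes = genes, exons = exons, cds = cds, txGene = txGene),
            class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", length(x$genes), "genes,",
      length(x$exons), "transcripts\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Recognizes `gene`, `mRNA`/`transcript`, `exon` and `CDS` features;
#' other feature types are ignored (count reported with
#' `verbose = TRUE`). A transcript whose summed CDS length (after phase
#' adjustment) is not divisible by 3 is kept but flagged, and is skipped
#' by [annotateEffects()].
#'
#' @param path GFF3 file (plain or gzip).
#' @param verbose log ignored feature types.
#' @return A [GeneModelSet()].
#' @export
readGFF3 <- function(path, verbose = FALSE) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  known <- c("gene", "mRNA", "transcript", "exon", "CDS")
  if (verbose && any(!type %in% known)) {
    message(sum(!type %in% known), " feature(s) of unhandled type ignored")
  }
  genes <- gr[type == "gene"]
  mcols(genes) <- S4Vectors::DataFrame(gene_id = genes$ID)
  tx <- gr[type %in% c("mRNA", "transcript")]
  txIds <- tx$ID
  txGene <- vapply(tx$Parent, function(p) as.character(p)[1], character(1))
  names(txGene) <- txIds
  exonGr <- gr[type == "exon"]
  cdsGr <- gr[type == "CDS"]
  exParent <- vapply(exonGr$Parent, function(p) as.character(p)[1], character(1))
  cdsParent <- vapply(cdsGr$Parent, function(p) as.character(p)[1], character(1))
  exons <- GenomicRanges::GRangesList(lapply(txIds, function(t) {
    e <- exonGr[exParent == t]
    mcols(e) <- NULL
    sort(e, ignore.strand = TRUE)
  }))
  names(exons) <- txIds
  cds <- GenomicRanges::GRangesList(lapply(txIds, function(t) {
    cc <- cdsGr[cdsParent == t]
    ph <- if (!is.null(cc$phase)) as.integer(cc$phase) else rep(0L, length(cc))
    ph[is.na(ph)] <- 0L
    o <- order(start(cc))
    cc <- cc[o]
    mcols(cc) <- S4Vectors::DataFrame(phase = ph[o])
    cc
  }))
  names(cds) <- txIds
  GeneModelSet(genes, exons, cds, txGene)
}

#' Write a GeneModelSet as GFF3
#'
#' @param models a [GeneModelSet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(models, path) {
  lines <- "##gff-version 3"
  fmt <- function(gr, type, attr) {
    ph <- if (type == "CDS" && "phase" %in% colnames(mcols(gr))) {
      as.character(mcols(gr)$phase)
    } else rep(".", length(gr))
    sprintf("%s\tduripop\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            as.character(seqnames(gr)), type, start(gr), end(gr),
            as.character(BiocGenerics::strand(gr)), ph, attr)
  }
  for (i in seq_along(models$genes)) {
    g <- models$genes[i]
    gid <- mcols(g)$gene_id
    lines <- c(lines, fmt(g, "gene", paste0("ID=", gid)))
    for (tx in names(models$txGene)[models$txGene == gid]) {
      e <- models$exons[[tx]]
      cc <- models$cds[[tx]]
      txSpan <- range(e)
      BiocGenerics::strand(txSpan) <- BiocGenerics::strand(g)
      lines <- c(lines,
                 fmt(txSpan, "mRNA", paste0("ID=", tx, ";Parent=", gid)))
      BiocGenerics::strand(e) <- BiocGenerics::strand(g)
      BiocGenerics::strand(cc) <- BiocGenerics::strand(g)
      lines <- c(lines, fmt(e, "exon", paste0("Parent=", tx)),
                 fmt(cc, "CDS", paste0("Parent=", tx)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- FASTA and sample table ------------------------------------------

#' Read or write reference sequences
#'
#' Reference sequences are held as a named [Biostrings::DNAStringSet]
#' (chromosome name -> sequence over A/C/G/T/N).
#'
#' @param path FASTA file (plain or gzip).
#' @return `readFASTA`: a `DNAStringSet`.
#' @export
readFASTA <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname readFASTA
#' @param seqs named `DNAStringSet` (or named character vector).
#' @export
writeFASTA <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read or write the sample metadata table
#'
#' Tab-separated with header columns `sample_id`, `population`, `origin`.
#'
#' @param path TSV file (plain or gzip).
#' @param populations closed set of allowed population labels.
#' @return `readSampleTable`: validated data.frame.
#' @export
readSampleTable <- function(path, populations = c("POP1", "POP2", "POP3")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateSampleInfo(df, populations)
}

#' @rdname readSampleTable
#' @param sampleInfo data.frame as returned by [readSampleTable()].
#' @export
writeSampleTable <- function(sampleInfo, path) {
  utils::write.table(sampleInfo, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
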