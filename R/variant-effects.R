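## SNP effect classification against gene models, SnpEff-style impact
## classes. SNP-only: frameshift and other indel consequences are out of
## reach of a biallelic SNP panel.

.IMPACT_MAP <- c(stop_gained = "HIGH", stop_lost = "HIGH",
                 start_lost = "HIGH",
                 missense = "MODERATE",
                 synonymous = "LOW", stop_retained = "LOW",
                 five_prime_UTR = "MODIFIER", three_prime_UTR = "MODIFIER",
                 intron = "MODIFIER", upstream = "MODIFIER",
                 downstream = "MODIFIER", intergenic = "MODIFIER")

.SEVERITY <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

## reconstruct the coding sequence of one transcript from the reference;
## returns NULL (with a warning) when the CDS is not a valid ORF
.transcriptCDS <- function(cdsGr, strandChar, reference) {
  ch <- as.character(seqnames(cdsGr))[1]
  pieces <- vapply(seq_along(cdsGr), function(i) {
    as.character(Biostrings::subseq(reference[[ch]], start(cdsGr)[i],
                                    end(cdsGr)[i]))
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (strandChar == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  if (nchar(s) %% 3 != 0) return(NULL)
  s
}

#' Classify SNP effects against gene models
#'
#' Each variant receives its worst consequence across transcripts,
#' mapped to an impact class: `stop_gained` / `stop_lost` /
#' `start_lost` are HIGH, `missense` MODERATE, `synonymous` /
#' `stop_retained` LOW, and all non-coding consequences (UTR, intron,
#' up/downstream within `flankBp`, intergenic) MODIFIER. Coding changes
#' are evaluated by translating the reference and alternate codon with
#' the standard code, strand-aware. The reference base at each variant
#' must match the panel's REF allele (a guard against coordinate bugs).
#' Transcripts whose CDS is not a valid ORF (length not divisible by 3)
#' are skipped with a warning.
#'
#' @param panel a `GenotypePanel`.
#' @param geneModels a [GeneModelSet()].
#' @param reference named `DNAStringSet`.
#' @param flankBp up/downstream flank for the MODIFIER classes.
#' @return data.frame: `variant` (index), `chrom`, `pos`, `gene`,
#'   `consequence`, `impact`.
#' @export
annotateEffects <- function(panel, geneModels, reference, flankBp = 5000L) {
  gloci <- panel@loci
  nv <- length(gloci)
  chromVec <- as.character(seqnames(gloci))
  posVec <- start(gloci)
  refAll <- mcols(gloci)$ref
  altAll <- mcols(gloci)$alt
  ## guard: panel REF must equal the reference base
  for (ch in unique(chromVec)) {
    idx <- which(chromVec == ch)
    refChars <- strsplit(as.character(reference[[ch]]), "")[[1]]
    bad <- idx[refAll[idx] != refChars[posVec[idx]]]
    if (length(bad)) {
      stop("REF allele mismatch with reference at ", chromVec[bad[1]], ":",
           posVec[bad[1]], " (", length(bad), " site(s))")
    }
  }
  consequence <- rep("intergenic", nv)
  geneHit <- rep(NA_character_, nv)
  sev <- function(x) match(.IMPACT_MAP[x], .SEVERITY)
  better <- function(newCons, i) {
    old <- consequence[i]
    newSev <- sev(newCons); oldSev <- sev(old)
    take <- newSev < oldSev | (old == "intergenic" & newCons != "intergenic")
    take
  }
  genesGr <- geneModels$genes
  strandOf <- as.character(strand(genesGr))
  names(strandOf) <- mcols(genesGr)$gene_id
  ## flanks first (weakest), then gene regions override
  up <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::flank(genesGr, flankBp, start = TRUE)))
  dn <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::flank(genesGr, flankBp, start = FALSE)))
  for (ftype in c("downstream", "upstream")) {
    fr <- if (ftype == "upstream") up else dn
    ov <- findOverlaps(gloci, fr)
    for (h in seq_along(queryHits(ov))) {
      i <- queryHits(ov)[h]
      if (consequence[i] == "intergenic") {
        consequence[i] <- ftype
        geneHit[i] <- mcols(genesGr)$gene_id[subjectHits(ov)[h]]
      }
    }
  }
  ## per-transcript classification
  GC <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (tx in names(geneModels$exons)) {
    gid <- geneModels$txGene[[tx]]
    strandChar <- strandOf[[gid]]
    exGr <- geneModels$exons[[tx]]
    cdsGr <- geneModels$cds[[tx]]
    txStart <- min(start(exGr)); txEnd <- max(end(exGr))
    ch <- as.character(seqnames(exGr))[1]
    inTx <- which(chromVec == ch & posVec >= txStart & posVec <= txEnd)
    if (!length(inTx)) next
    cdsSeq <- .transcriptCDS(cdsGr, strandChar, reference)
    cdsValid <- !is.null(cdsSeq)
    if (!cdsValid) {
      warning("transcript ", tx, " has an invalid CDS; coding effects skipped")
    }
    cdsStarts <- start(cdsGr); cdsEnds <- end(cdsGr)
    cdsLens <- cdsEnds - cdsStarts + 1L
    cumBefore <- cumsum(c(0L, cdsLens))[seq_along(cdsLens)]
    totalCds <- sum(cdsLens)
    cdsLo <- min(cdsStarts); cdsHi <- max(cdsEnds)
    for (i in inTx) {
      p <- posVec[i]
      cdsPiece <- which(p >= cdsStarts & p <= cdsEnds)
      cons <- NULL
      if (length(cdsPiece) && cdsValid) {
        plusOff <- cumBefore[cdsPiece[1]] + (p - cdsStarts[cdsPiece[1]]) + 1L
        cpos <- if (strandChar == "+") plusOff else totalCds - plusOff + 1L
        base <- if (strandChar == "+") altAll[i] else comp[[altAll[i]]]
        codonIdx <- (cpos - 1L) %/% 3L + 1L
        within <- (cpos - 1L) %% 3L + 1L
        refCodon <- substr(cdsSeq, 3L * codonIdx - 2L, 3L * codonIdx)
        altCodon <- refCodon
        substr(altCodon, within, within) <- base
        refAA <- GC[[refCodon]]
        altAA <- GC[[altCodon]]
        cons <- if (codonIdx == 1L && refCodon == "ATG" && altCodon != "ATG") {
          "start_lost"
        } else if (refAA == "*") {
          if (altAA == "*") "stop_retained" else "stop_lost"
        } else if (altAA == "*") {
          "stop_gained"
        } else if (refAA == altAA) "synonymous" else "missense"
      } else if (length(cdsPiece)) {
        cons <- NULL  # invalid CDS: fall through to non-coding context
      }
      if (is.null(cons)) {
        inExon <- any(p >= start(exGr) & p <= end(exGr))
        cons <- if (inExon) {
          if (p < cdsLo) {
            if (strandChar == "+") "five_prime_UTR" else "three_prime_UTR"
          } else if (p > cdsHi) {
            if (strandChar == "+") "three_prime_UTR" else "five_prime_UTR"
          } else "intron"  # inside CDS span of an invalid transcript
        } else "intron"
      }
      if (better(cons, i)) {
        consequence[i] <- cons
        geneHit[i] <- gid
      }
    }
  }
  data.frame(variant = seq_len(nv), chrom = chromVec, pos = posVec,
             gene = geneHit, consequence = consequence,
             impact = unname(.IMPACT_MAP[consequence]),
             stringsAsFactors = FALSE)
}

#' Tabulate impact classes, overall and per population
#'
#' A variant counts toward a population when it is polymorphic within
#' that population (at least one copy of each allele among non-missing
#' calls).
#'
#' @param annotations data.frame from [annotateEffects()].
#' @param sampleInfo sample metadata.
#' @param panel the annotated `GenotypePanel`.
#' @return data.frame of counts: rows = impact classes, columns =
#'   `overall` plus one per population.
#' @export
effectSummary <- function(annotations, sampleInfo, panel) {
  stopifnot(nrow(annotations) == nVariants(panel))
  pops <- unique(sampleInfo$population)
  out <- data.frame(impact = .SEVERITY)
  out$overall <- vapply(.SEVERITY, function(im) {
    sum(annotations$impact == im)
  }, integer(1))
  for (pop in pops) {
    ac <- alleleCounts(panel, popSamples(sampleInfo, pop))
    poly <- ac$nAlt > 0 & ac$nAlt < ac$nAllele
    out[[pop]] <- vapply(.SEVERITY, function(im) {
      sum(annotations$impact == im & poly)
    }, integer(1))
  }
  out
}
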