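# A hand-built single-gene fixture with every coding consequence
# reachable by one SNP, on both strands.

cdsCodons <- c("ATG", "TAT", "CCT", "AAA", "GGG", "TGG", "CAT", "CAC",
               "AAG", "TAA")
cdsSeq <- paste(cdsCodons, collapse = "")

buildEffectFixture <- function() {
  set.seed(99)
  refChars <- sample(c("A", "C", "G", "T"), 1000L, replace = TRUE)
  ## plus-strand gene: exon 191-240, CDS 201-230, UTRs 191-200 / 231-240
  refChars[201:230] <- strsplit(cdsSeq, "")[[1]]
  ## minus-strand gene: exon 491-540, CDS 501-530 holds revcomp(CDS)
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cdsSeq))), "")[[1]]
  refChars[501:530] <- rc
  reference <- Biostrings::DNAStringSet(c(c1 = paste(refChars,
                                                     collapse = "")))
  genes <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(191L, 491L), c(240L, 540L)),
    strand = c("+", "-"), gene_id = c("gPlus", "gMinus"))
  exons <- GenomicRanges::GRangesList(
    gPlus.t1 = GenomicRanges::GRanges("c1", IRanges::IRanges(191L, 240L)),
    gMinus.t1 = GenomicRanges::GRanges("c1", IRanges::IRanges(491L, 540L)))
  mkCds <- function(s, e) {
    g <- GenomicRanges::GRanges("c1", IRanges::IRanges(s, e))
    S4Vectors::mcols(g)$phase <- 0L
    g
  }
  cds <- GenomicRanges::GRangesList(gPlus.t1 = mkCds(201L, 230L),
                                    gMinus.t1 = mkCds(501L, 530L))
  models <- GeneModelSet(genes, exons, cds,
                         c(gPlus.t1 = "gPlus", gMinus.t1 = "gMinus"))
  list(reference = reference, models = models, refChars = refChars)
}

effectPanel <- function(fix, pos, alt) {
  ref <- fix$refChars[pos]
  makePanel(matrix(1L, length(pos), 2), chrom = rep("c1", length(pos)),
            pos = as.integer(pos), ref = ref, alt = alt,
            seqlengths = c(c1 = 1000L))
}

test_that("coding consequences follow the codon table on the plus strand", {
  fix <- buildEffectFixture()
  ## codon 2 TAT -> TAA (pos 206 T>A): stop gained
  ## codon 3 CCT -> CCA (pos 209 T>A): synonymous
  ## codon 1 ATG -> ACG (pos 202 T>C): start lost
  ## codon 4 AAA -> GAA (pos 210 A>G): missense
  ## stop TAA -> TCA (pos 229 A>C): stop lost; TAA -> TAG: stop retained
  pos <- c(206L, 209L, 202L, 210L, 229L, 230L)
  alt <- c("A", "A", "C", "G", "C", "G")
  ann <- annotateEffects(effectPanel(fix, pos, alt), fix$models,
                         fix$reference)
  ann <- ann[order(ann$pos), ]
  expect_equal(ann$consequence,
               c("start_lost", "stop_gained", "synonymous", "missense",
                 "stop_lost", "stop_retained"))
  expect_equal(ann$impact,
               c("HIGH", "HIGH", "LOW", "MODERATE", "HIGH", "LOW"))
  expect_true(all(ann$gene == "gPlus"))
})

test_that("minus-strand variants classify like their reverse complement", {
  fix <- buildEffectFixture()
  ## CDS position 9 (codon 3 wobble) sits at genomic 530 - 8 = 522;
  ## genomic ref is complement(T) = A, genomic alt T reads as CDS A:
  ## CCT -> CCA, synonymous. Codon 2 position 6 -> genomic 525,
  ## genomic alt T reads as CDS A: TAT -> TAA, stop gained.
  ann <- annotateEffects(effectPanel(fix, c(522L, 525L), c("T", "T")),
                         fix$models, fix$reference)
  ann <- ann[order(ann$pos), ]
  expect_equal(ann$consequence, c("synonymous", "stop_gained"))
  expect_true(all(ann$gene == "gMinus"))
})

test_that("non-coding contexts map to MODIFIER with the right terms", {
  fix <- buildEffectFixture()
  pos <- c(100L, 160L, 195L, 235L, 260L, 525L)
  alt <- ifelse(fix$refChars[pos] == "A", "G", "A")
  ann <- annotateEffects(effectPanel(fix, pos, alt), fix$models,
                         fix$reference, flankBp = 50L)
  ann <- ann[order(ann$pos), ]
  ## 100: beyond both genes' 50-bp flanks -> intergenic
  ## 160: within 50 bp upstream of gPlus -> upstream
  ## 195: exon before CDS on + strand -> 5' UTR; 235 -> 3' UTR
  ## 260: within 50 bp downstream of gPlus -> downstream
  expect_equal(ann$consequence[1:5],
               c("intergenic", "upstream", "five_prime_UTR",
                 "three_prime_UTR", "downstream"))
  expect_true(all(ann$impact[1:5] == "MODIFIER"))
})

test_that("a REF/reference mismatch is refused", {
  fix <- buildEffectFixture()
  p <- makePanel(matrix(1L, 1, 2), chrom = "c1", pos = 100L,
                 ref = setdiff(c("A", "C", "G", "T"),
                               fix$refChars[100])[1],
                 alt = fix$refChars[100], seqlengths = c(c1 = 1000L))
  expect_error(annotateEffects(p, fix$models, fix$reference),
               "REF allele mismatch")
})

test_that("an invalid CDS is skipped with a warning, not an error", {
  fix <- buildEffectFixture()
  bad <- fix$models
  ## truncate the plus-strand CDS to a length not divisible by 3
  bad$cds$gPlus.t1 <- GenomicRanges::GRanges("c1",
                                             IRanges::IRanges(201L, 229L))
  S4Vectors::mcols(bad$cds$gPlus.t1)$phase <- 0L
  expect_warning(
    ann <- annotateEffects(effectPanel(fix, 206L, "A"), bad,
                           fix$reference),
    "invalid CDS")
  expect_equal(ann$impact, "MODIFIER")
})

test_that("simulated coding variants agree with whole-CDS re-translation", {
  cfg <- simConfig(seed = 23L, chromLayout = c(cA = 200000L),
                   nPerPop = c(POP1 = 4L, POP2 = 3L, POP3 = 3L),
                   nAdmixed = 0L, sweeps = list(),
                   geneSim = list(nGenes = 14L, codonRange = c(80L, 150L),
                                  exonRange = c(1L, 3L)))
  sim <- simulatePanel(cfg)
  ann <- annotateEffects(sim$panel, sim$genes, sim$reference)
  coding <- ann[ann$consequence %in% c("stop_gained", "stop_lost",
                                       "start_lost", "missense",
                                       "synonymous", "stop_retained"), ]
  expect_gt(nrow(coding), 5L)
  refAlleles <- S4Vectors::mcols(loci(sim$panel))$ref
  altAlleles <- S4Vectors::mcols(loci(sim$panel))$alt
  for (r in seq_len(nrow(coding))) {
    row <- coding[r, ]
    tx <- paste0(row$gene, ".t1")
    cdsGr <- sim$genes$cds[[tx]]
    strandChar <- as.character(BiocGenerics::strand(
      sim$genes$genes[S4Vectors::mcols(sim$genes$genes)$gene_id ==
                        row$gene]))
    ## oracle: substitute the alt base in the genome, re-extract and
    ## translate the whole CDS, and compare protein sequences
    chrSeq <- strsplit(as.character(sim$reference[[row$chrom]]), "")[[1]]
    i <- row$variant
    expect_equal(chrSeq[row$pos], refAlleles[i])
    altSeq <- chrSeq
    altSeq[row$pos] <- altAlleles[i]
    getProt <- function(chars) {
      pieces <- vapply(seq_along(cdsGr), function(j) {
        paste(chars[start(cdsGr)[j]:end(cdsGr)[j]], collapse = "")
      }, character(1))
      s <- Biostrings::DNAString(paste(pieces, collapse = ""))
      if (strandChar == "-") s <- Biostrings::reverseComplement(s)
      as.character(Biostrings::translate(s, if.fuzzy.codon = "X"))
    }
    pRef <- getProt(chrSeq)
    pAlt <- getProt(altSeq)
    want <- if (pRef == pAlt) {
      c("synonymous", "stop_retained")
    } else if (substr(pAlt, 1, 1) != "M") {
      "start_lost"
    } else if (grepl("\\*", substr(pAlt, 1, nchar(pAlt) - 1))) {
      "stop_gained"
    } else if (substr(pRef, nchar(pRef), nchar(pRef)) == "*" &&
               substr(pAlt, nchar(pAlt), nchar(pAlt)) != "*") {
      "stop_lost"
    } else "missense"
    expect_true(row$consequence %in% want,
                label = paste("variant", i, row$consequence, "vs oracle",
                              paste(want, collapse = "/")))
  }
})

test_that("effect summaries count polymorphic variants per population", {
  ## all-intergenic toy: two genes far away from every variant
  fix <- buildEffectFixture()
  d <- rbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 1L, 1L), c(2L, 2L, 2L, 2L))
  pos <- c(50L, 60L, 70L)
  p <- makePanel(d, chrom = rep("c1", 3), pos = pos,
                 ref = fix$refChars[pos],
                 alt = ifelse(fix$refChars[pos] == "A", "G", "A"),
                 seqlengths = c(c1 = 1000L))
  ann <- annotateEffects(p, fix$models, fix$reference, flankBp = 10L)
  expect_true(all(ann$impact == "MODIFIER"))
  si <- data.frame(sample_id = sampleIds(p),
                   population = c("POP1", "POP1", "POP2", "POP2"),
                   origin = "t", stringsAsFactors = FALSE)
  su <- effectSummary(ann, si, p)
  ## site 3 is monomorphic everywhere; site 1 polymorphic in both pops;
  ## site 2 polymorphic only in POP2
  expect_equal(su$overall[su$impact == "MODIFIER"], 3L)
  expect_equal(su$POP1[su$impact == "MODIFIER"], 1L)
  expect_equal(su$POP2[su$impact == "MODIFIER"], 2L)
  expect_true(all(su$POP1 <= su$overall))
})
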