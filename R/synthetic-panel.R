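## Synthetic panel generation.
##
## The generator emulates the study design the analysis assumes: three
## Balding-Nichols populations of 52/40/22 diploids (114 accessions), a
## minority of admixed individuals, distance-decaying LD (fastest decay
## in the most diverse population), planted low-diversity sweep regions,
## and random gene models with valid CDS embedded in a generated
## reference. A separate neutral coalescent simulator provides panels
## with realistic allele-frequency spectra for calibrating pi and
## Tajima's D.

#' Derive a child RNG seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages draw from `deriveSeed(seed, stream)` with a documented stream
#' index so that stages are reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param stream small integer stream index.
#' @return a 32-bit integer seed.
#' @export
deriveSeed <- function(seed, stream) {
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 +
                as.numeric(stream) * 99991) %% m)
}

#' Describe a planted selective sweep
#'
#' Inside `[start, end]` on `chrom`, the target population's allele
#' frequencies are pushed toward the nearer boundary so that expected
#' heterozygosity (hence windowed pi) is multiplied by
#' `diversityReduction`.
#'
#' @param population target population label.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval.
#' @param diversityReduction factor in (0, 1].
#' @export
sweepSpec <- function(population, chrom, start, end, diversityReduction) {
  stopifnot(diversityReduction > 0, diversityReduction <= 1, start <= end)
  list(population = population, chrom = chrom, start = start, end = end,
       diversityReduction = diversityReduction)
}

#' Simulation configuration for the synthetic panel
#'
#' Defaults reproduce the study conditions: 114 accessions split
#' 52/40/22 over POP1/POP2/POP3; per-population drift (0.07, 0.17, 0.23)
#' chosen so pairwise Weir-Cockerham Fst lands near 0.12/0.15/0.20;
#' ancestral alternate-allele frequencies uniform on (0.05, 0.95); SNP
#' density 0.0056 per bp so POP1 per-bp diversity is near 0.0019 with
#' POP2 and POP3 ordered below it; six admixed individuals with
#' Dirichlet(1.5) ancestry; distance-decaying LD, fastest in POP1 and
#' slowest in POP3, with decay distances scaled down in proportion to
#' the miniature 6-Mb genome (half-decay a few kb rather than the tens
#' of kb of a full-size genome, keeping the linked/unlinked contrast
#' realistic at this genome size); one planted sweep in POP3
#' (chr01:900,001-1,100,000, diversity reduced to 0.2x); 120 random
#' gene models.
#'
#' @param nPerPop named integer vector of diploid counts per population.
#' @param popDrift Balding-Nichols drift F per population, in (0, 1).
#' @param ancestralMAFRange uniform range for the ancestral frequency.
#' @param nAdmixed number of admixed individuals (drawn round-robin from
#'   the populations; their metadata label stays the source population).
#' @param admixAlpha symmetric Dirichlet concentration for admixed Q.
#' @param chromLayout named vector of chromosome lengths (bp).
#' @param snpDensity expected SNPs per bp.
#' @param ldRho per-population per-bp decay rate of the latent haplotype
#'   correlation `ldNugget * exp(-ldRho * distance)`; larger = faster LD
#'   decay.
#' @param ldNugget short-range ceiling of the latent correlation in
#'   (0, 1]: real panels plateau well below r2 = 1 at short distances,
#'   and perfectly duplicated SNP columns are not a feature to emulate.
#' @param missingRate probability that a genotype call is missing.
#' @param sweeps list of [sweepSpec()].
#' @param geneSim list: `nGenes`, `codonRange` (CDS codons), `exonRange`
#'   (exons per gene).
#' @param seed master seed.
#' @return a `simConfig` list.
#' @export
simConfig <- function(nPerPop = c(POP1 = 52L, POP2 = 40L, POP3 = 22L),
                      popDrift = c(POP1 = 0.07, POP2 = 0.17, POP3 = 0.23),
                      ancestralMAFRange = c(0.05, 0.95),
                      nAdmixed = 6L,
                      admixAlpha = 1.5,
                      chromLayout = c(chr01 = 1500000L, chr02 = 1500000L,
                                      chr03 = 1500000L, chr04 = 1500000L),
                      snpDensity = 0.0056,
                      ldRho = c(POP1 = 1.4e-4, POP2 = 5e-5, POP3 = 2.4e-5),
                      ldNugget = 0.75,
                      missingRate = 0.02,
                      sweeps = list(sweepSpec("POP3", "chr01",
                                              900001L, 1100000L, 0.2)),
                      geneSim = list(nGenes = 120L,
                                     codonRange = c(100L, 300L),
                                     exonRange = c(1L, 3L)),
                      seed = 1L) {
  stopifnot(all(nPerPop >= 0), all(popDrift > 0), all(popDrift < 1),
            all(chromLayout > 0), nAdmixed <= sum(nPerPop))
  if (is.null(names(nPerPop))) names(nPerPop) <- paste0("POP", seq_along(nPerPop))
  structure(list(nPerPop = nPerPop, popDrift = popDrift,
                 ancestralMAFRange = ancestralMAFRange,
                 nAdmixed = nAdmixed, admixAlpha = admixAlpha,
                 chromLayout = chromLayout, snpDensity = snpDensity,
                 ldRho = ldRho, ldNugget = ldNugget,
                 missingRate = missingRate, sweeps = sweeps,
                 geneSim = geneSim, seed = seed),
            class = "simConfig")
}

## push p toward the nearer boundary so 2p'(1-p') = r * 2p(1-p)
.sweepFreq <- function(p, r) {
  disc <- sqrt(pmax(0, 1 - 4 * r * p * (1 - p)))
  ifelse(p <= 0.5, (1 - disc) / 2, (1 + disc) / 2)
}

## latent-Gaussian haplotypes for one population on one chromosome:
## marginals are exactly Bernoulli(p_l); latent correlation between
## sites is nugget * exp(-rho * distance) (AR(1) chain plus independent
## noise), so r2 plateaus below 1 at short range as in real panels
.simHaplotypes <- function(nHap, p, pos, rho, nugget = 1) {
  L <- length(p)
  z <- matrix(0, nHap, L)
  z[, 1L] <- stats::rnorm(nHap)
  if (L > 1L) {
    phi <- exp(-rho * diff(pos))
    sig <- sqrt(1 - phi^2)
    for (l in 2:L) {
      z[, l] <- phi[l - 1L] * z[, l - 1L] + sig[l - 1L] * stats::rnorm(nHap)
    }
  }
  if (nugget < 1) {
    z <- sqrt(nugget) * z + sqrt(1 - nugget) * matrix(stats::rnorm(nHap * L),
                                                      nHap, L)
  }
  thr <- stats::qnorm(p)
  sweep_ <- matrix(thr, nHap, L, byrow = TRUE)
  (z < sweep_) + 0L
}

## random CDS: ATG + sense codons + stop
.senseCodons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.randomCDS <- function(nCodons) {
  paste0("ATG",
         paste(sample(.senseCodons, nCodons - 2L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

## place genes on a chromosome, returning interval bookkeeping
.placeGene <- function(occupied, chromLen, span, maxTry = 200L) {
  for (i in seq_len(maxTry)) {
    s <- sample.int(chromLen - span - 2000L, 1L) + 1000L
    e <- s + span - 1L
    if (!any(s <= occupied[, 2L] + 500L & e >= occupied[, 1L] - 500L)) {
      return(c(s, e))
    }
  }
  NULL
}

#' Simulate the full synthetic study panel
#'
#' Generates genotypes under the Balding-Nichols model with
#' distance-decaying LD, sample metadata, random gene models with valid
#' CDS embedded in a generated reference sequence, and a ground-truth
#' record for recovery tests. See [simConfig()] for the model and the
#' default study conditions.
#'
#' @param config a [simConfig()].
#' @return list with elements `panel` ([GenotypePanel-class]),
#'   `sampleInfo` (data.frame), `genes` ([GeneModelSet()]), `reference`
#'   (`DNAStringSet`), `truth` (list: `Q`, `popDrift`, `sweeps`,
#'   `ancestralFreq`, `popFreq`, `admixedIds`).
#' @export
simulatePanel <- function(config = simConfig()) {
  pops <- names(config$nPerPop)
  K <- length(pops)
  ## stream 1: variant positions and allele frequencies
  set.seed(deriveSeed(config$seed, 1L))
  chroms <- names(config$chromLayout)
  posList <- lapply(chroms, function(ch) {
    L <- config$chromLayout[[ch]]
    n <- stats::rpois(1L, L * config$snpDensity)
    sort(sample.int(L, min(n, L)))
  })
  names(posList) <- chroms
  chromVec <- rep(chroms, lengths(posList))
  posVec <- unlist(posList, use.names = FALSE)
  nTot <- length(posVec)
  pAnc <- stats::runif(nTot, config$ancestralMAFRange[1],
                       config$ancestralMAFRange[2])
  pPop <- matrix(0, K, nTot, dimnames = list(pops, NULL))
  for (k in seq_len(K)) {
    Fk <- config$popDrift[[k]]
    pPop[k, ] <- stats::rbeta(nTot, pAnc * (1 - Fk) / Fk,
                              (1 - pAnc) * (1 - Fk) / Fk)
  }
  for (sw in config$sweeps) {
    idx <- which(chromVec == sw$chrom & posVec >= sw$start & posVec <= sw$end)
    k <- match(sw$population, pops)
    pPop[k, idx] <- .sweepFreq(pPop[k, idx], sw$diversityReduction)
  }

  ## sample bookkeeping: ids, populations, admixed Q
  N <- sum(config$nPerPop)
  ids <- sprintf("DZ%03d", seq_len(N))
  popLab <- rep(pops, config$nPerPop)
  Q <- matrix(0, N, K, dimnames = list(ids, pops))
  Q[cbind(seq_len(N), match(popLab, pops))] <- 1
  admixedIds <- character(0)
  if (config$nAdmixed > 0L) {
    ## last individuals of each population, round-robin
    perPopIdx <- split(seq_len(N), popLab)[pops]
    take <- integer(0)
    j <- 0L
    while (length(take) < config$nAdmixed) {
      k <- (j %% K) + 1L
      cand <- rev(perPopIdx[[k]])
      pick <- cand[sum(take %in% perPopIdx[[k]]) + 1L]
      take <- c(take, pick)
      j <- j + 1L
    }
    for (i in take) {
      q <- stats::rgamma(K, config$admixAlpha)
      q <- q / sum(q)
      k0 <- match(popLab[i], pops)
      mx <- which.max(q)
      if (mx != k0) q[c(k0, mx)] <- q[c(mx, k0)]  # argmax stays the source pop
      Q[i, ] <- q
    }
    admixedIds <- ids[take]
  }

  ## stream 2: haplotypes
  set.seed(deriveSeed(config$seed, 2L))
  dosage <- matrix(0L, nTot, N, dimnames = list(NULL, ids))
  unadm <- setdiff(ids, admixedIds)
  for (k in seq_len(K)) {
    members <- which(popLab == pops[k] & ids %in% unadm)
    if (!length(members)) next
    nHap <- 2L * length(members)
    for (ch in chroms) {
      idx <- which(chromVec == ch)
      if (!length(idx)) next
      hap <- .simHaplotypes(nHap, pPop[k, idx], posVec[idx],
                            config$ldRho[[k]], config$ldNugget)
      dosage[idx, members] <- t(hap[seq(1L, nHap, 2L), , drop = FALSE] +
                                  hap[seq(2L, nHap, 2L), , drop = FALSE])
    }
  }
  for (id in admixedIds) {
    i <- match(id, ids)
    cum <- cumsum(Q[i, ])
    for (a in 1:2) {
      anc <- findInterval(stats::runif(nTot), cum) + 1L
      allele <- stats::runif(nTot) < pPop[cbind(anc, seq_len(nTot))]
      dosage[, i] <- dosage[, i] + as.integer(allele)
    }
  }

  ## stream 3: reference sequence and gene models
  set.seed(deriveSeed(config$seed, 3L))
  refGenes <- .simulateReferenceAndGenes(config, chromVec, posVec)
  reference <- refGenes$reference
  genes <- refGenes$genes

  ## variant alleles from the finished reference
  refBase <- character(nTot)
  for (ch in chroms) {
    idx <- which(chromVec == ch)
    refBase[idx] <- strsplit(as.character(
      Biostrings::subseq(reference[[ch]], 1L, config$chromLayout[[ch]])),
      "")[[1]][posVec[idx]]
  }
  bases <- c("A", "C", "G", "T")
  altBase <- vapply(refBase, function(b) sample(setdiff(bases, b), 1L),
                    character(1), USE.NAMES = FALSE)

  ## stream 4: missingness
  set.seed(deriveSeed(config$seed, 4L))
  if (config$missingRate > 0) {
    dosage[stats::runif(length(dosage)) < config$missingRate] <- NA_integer_
  }

  panel <- GenotypePanel(dosage, chrom = chromVec, pos = posVec,
                         ref = refBase, alt = altBase,
                         seqlengths = config$chromLayout,
                         metadata = list(simulated = TRUE,
                                         seed = config$seed),
                         sort = FALSE)
  origins <- c("Hainan-Sanya", "Hainan-Baoting", "Hainan-Ledong",
               "Hainan-Wanning", "Yunnan-Xishuangbanna")
  sampleInfo <- data.frame(
    sample_id = ids,
    population = popLab,
    origin = origins[1L + (seq_len(N) %% length(origins))],
    stringsAsFactors = FALSE)
  truth <- list(Q = Q, popDrift = config$popDrift, sweeps = config$sweeps,
                ancestralFreq = pAnc, popFreq = pPop,
                admixedIds = admixedIds)
  list(panel = panel, sampleInfo = sampleInfo, genes = genes,
       reference = reference, truth = truth)
}

.simulateReferenceAndGenes <- function(config, chromVec, posVec) {
  chroms <- names(config$chromLayout)
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(chroms, function(ch) {
    sample(bases, config$chromLayout[[ch]], replace = TRUE)
  })
  names(seqs) <- chroms
  nGenes <- config$geneSim$nGenes
  geneChrom <- sample(chroms, nGenes, replace = TRUE,
                      prob = config$chromLayout / sum(config$chromLayout))
  geneRows <- list()
  exonsL <- list()
  cdsL <- list()
  txGene <- character(0)
  occupied <- lapply(chroms, function(ch) matrix(numeric(), 0L, 2L))
  names(occupied) <- chroms
  for (g in seq_len(nGenes)) {
    ch <- geneChrom[g]
    nCodons <- sample(config$geneSim$codonRange[1]:config$geneSim$codonRange[2], 1L)
    nEx <- sample(config$geneSim$exonRange[1]:config$geneSim$exonRange[2], 1L)
    cdsSeq <- .randomCDS(nCodons)
    cdsLen <- nchar(cdsSeq)
    ## split CDS into nEx chunks, each >= 20 bp
    if (nEx > 1L) {
      cuts <- sort(sample(seq(20L, cdsLen - 20L), nEx - 1L))
      while (any(diff(c(0L, cuts, cdsLen)) < 20L)) {
        cuts <- sort(sample(seq(20L, cdsLen - 20L), nEx - 1L))
      }
      chunkLen <- diff(c(0L, cuts, cdsLen))
    } else {
      chunkLen <- cdsLen
    }
    utr5 <- sample(50:150, 1L)
    utr3 <- sample(50:200, 1L)
    intronLen <- if (nEx > 1L) sample(200:800, nEx - 1L, replace = TRUE) else integer(0)
    strand <- sample(c("+", "-"), 1L)
    span <- utr5 + utr3 + cdsLen + sum(intronLen)
    pl <- .placeGene(occupied[[ch]], config$chromLayout[[ch]], span)
    if (is.null(pl)) {
      stop("could not place gene on ", ch, " after bounded retries")
    }
    occupied[[ch]] <- rbind(occupied[[ch]], pl)
    gStart <- pl[1L]
    ## genomic layout (ascending): [utrLeft][cds1]..introns..[cdsN][utrRight]
    utrLeft <- if (strand == "+") utr5 else utr3
    utrRight <- if (strand == "+") utr3 else utr5
    chunkGenomic <- if (strand == "+") chunkLen else rev(chunkLen)
    exStart <- integer(nEx); exEnd <- integer(nEx)
    cdStart <- integer(nEx); cdEnd <- integer(nEx)
    cur <- gStart
    for (j in seq_len(nEx)) {
      exStart[j] <- cur
      cdStart[j] <- cur + if (j == 1L) utrLeft else 0L
      cdEnd[j] <- cdStart[j] + chunkGenomic[j] - 1L
      exEnd[j] <- cdEnd[j] + if (j == nEx) utrRight else 0L
      cur <- exEnd[j] + 1L + if (j < nEx) intronLen[j] else 0L
    }
    ## write CDS content into the chromosome (ascending genomic order)
    genomicCds <- if (strand == "+") cdsSeq else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cdsSeq)))
    }
    cdsChars <- strsplit(genomicCds, "")[[1]]
    off <- 0L
    for (j in seq_len(nEx)) {
      w <- cdEnd[j] - cdStart[j] + 1L
      seqs[[ch]][cdStart[j]:cdEnd[j]] <- cdsChars[(off + 1L):(off + w)]
      off <- off + w
    }
    gid <- sprintf("gene%03d", g)
    tid <- sprintf("gene%03d.t1", g)
    ## GFF3 phase along the strand
    lenStrand <- if (strand == "+") chunkGenomic else rev(chunkGenomic)
    phStrand <- c(0L, (3L - cumsum(lenStrand)[-nEx] %% 3L) %% 3L)
    phase <- if (strand == "+") phStrand else rev(phStrand)
    geneRows[[g]] <- data.frame(chrom = ch, start = gStart,
                                end = exEnd[nEx], strand = strand,
                                gene_id = gid, stringsAsFactors = FALSE)
    exonsL[[tid]] <- GRanges(ch, IRanges(exStart, exEnd))
    cdsGr <- GRanges(ch, IRanges(cdStart, cdEnd))
    mcols(cdsGr)$phase <- phase
    cdsL[[tid]] <- cdsGr
    txGene[tid] <- gid
  }
  gdf <- do.call(rbind, geneRows)
  genesGr <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                     strand = gdf$strand, gene_id = gdf$gene_id)
  seqlengths(genesGr) <- config$chromLayout[seqlevels(genesGr)]
  genes <- GeneModelSet(genesGr,
                        GenomicRanges::GRangesList(exonsL),
                        GenomicRanges::GRangesList(cdsL),
                        txGene)
  reference <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                               collapse = ""))
  list(reference = reference, genes = genes)
}

#' Simulate independent Balding-Nichols SNPs (no LD, no genes)
#'
#' A light-weight generator for estimator-calibration work: `nSnps`
#' unlinked biallelic SNPs for diploid populations of the given sizes,
#' with per-population drift.
#'
#' @param nPerPop named vector of diploid counts per population.
#' @param popDrift per-population drift F in (0, 1).
#' @param nSnps number of independent SNPs.
#' @param ancestralMAFRange uniform range of the ancestral frequency.
#' @param seed integer seed.
#' @param spacing bp between consecutive SNPs (positions only matter for
#'   windowing).
#' @return list `panel`, `sampleInfo`.
#' @export
simulateBNPanel <- function(nPerPop, popDrift, nSnps,
                            ancestralMAFRange = c(0.05, 0.95),
                            seed = 1L, spacing = 1000L) {
  if (is.null(names(nPerPop))) names(nPerPop) <- paste0("POP", seq_along(nPerPop))
  pops <- names(nPerPop)
  set.seed(seed)
  pAnc <- stats::runif(nSnps, ancestralMAFRange[1], ancestralMAFRange[2])
  N <- sum(nPerPop)
  popLab <- rep(pops, nPerPop)
  ids <- sprintf("BN%03d", seq_len(N))
  dosage <- matrix(0L, nSnps, N, dimnames = list(NULL, ids))
  for (k in seq_along(pops)) {
    Fk <- popDrift[[k]]
    pk <- if (Fk < 1e-9) pAnc else {
      stats::rbeta(nSnps, pAnc * (1 - Fk) / Fk, (1 - pAnc) * (1 - Fk) / Fk)
    }
    members <- which(popLab == pops[k])
    dosage[, members] <- stats::rbinom(nSnps * length(members), 2L,
                                       rep(pk, length(members)))
  }
  pos <- seq_len(nSnps) * spacing
  panel <- GenotypePanel(dosage, chrom = rep("chr01", nSnps), pos = pos,
                         ref = rep("A", nSnps), alt = rep("T", nSnps),
                         seqlengths = c(chr01 = (nSnps + 1L) * spacing),
                         sort = FALSE)
  sampleInfo <- data.frame(sample_id = ids, population = popLab,
                           origin = "simulated", stringsAsFactors = FALSE)
  list(panel = panel, sampleInfo = sampleInfo)
}

#' Neutral coalescent simulation of one locus (Hudson model)
#'
#' Standard neutral coalescent without recombination: exponential
#' coalescence times with rate `choose(k, 2)`, mutations Poisson with
#' rate `theta * length / 2` per unit of scaled branch length, placed
#' under the infinite-sites model at distinct integer positions.
#'
#' @param nHaplotypes sample size (>= 2).
#' @param thetaPerSite scaled mutation rate 4*Ne*mu per site.
#' @param lengthBp locus length.
#' @param seed optional integer seed.
#' @return 0/1 haplotype matrix (`nHaplotypes` x S) with attribute
#'   `positions` (sorted 1-based integer positions).
#' @export
simulateCoalescentLocus <- function(nHaplotypes, thetaPerSite, lengthBp,
                                    seed = NULL) {
  stopifnot(nHaplotypes >= 2, thetaPerSite > 0, lengthBp >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nHaplotypes
  ## active lineages: list of leaf index vectors + birth times
  desc <- as.list(seq_len(n))
  birth <- rep(0, n)
  t <- 0
  brDesc <- list()
  brLen <- numeric(0)
  k <- n
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    brDesc <- c(brDesc, desc[c(i, j)])
    brLen <- c(brLen, t - birth[i], t - birth[j])
    desc[[i]] <- c(desc[[i]], desc[[j]])
    birth[i] <- t
    desc[[j]] <- NULL
    birth <- birth[-j]
    k <- k - 1L
  }
  S <- stats::rpois(1L, thetaPerSite * lengthBp / 2 * sum(brLen))
  S <- min(S, lengthBp)  # infinite-sites on a finite integer grid
  hap <- matrix(0L, n, S)
  if (S > 0L) {
    br <- sample.int(length(brLen), S, replace = TRUE, prob = brLen)
    pos <- sort(sample.int(lengthBp, S))
    for (s in seq_len(S)) hap[brDesc[[br[s]]], s] <- 1L
  } else {
    pos <- integer(0)
  }
  attr(hap, "positions") <- pos
  hap
}

#' Panel of independent neutral coalescent loci, paired into diploids
#'
#' Each locus is simulated with [simulateCoalescentLocus()] and placed on
#' its own chromosome of length `lengthBp`; haplotypes are paired
#' sequentially into `nHaplotypes / 2` diploids shared across loci.
#'
#' @param nLoci number of independent loci.
#' @param nHaplotypes haplotypes per locus (even).
#' @param thetaPerSite scaled mutation rate per site.
#' @param lengthBp locus length in bp.
#' @param seed integer seed.
#' @return list `panel` ([GenotypePanel-class]), `sampleInfo`.
#' @export
simulateCoalescentPanel <- function(nLoci, nHaplotypes, thetaPerSite,
                                    lengthBp, seed = 1L) {
  stopifnot(nHaplotypes %% 2 == 0)
  set.seed(seed)
  nInd <- nHaplotypes %/% 2L
  ids <- sprintf("CO%03d", seq_len(nInd))
  chroms <- sprintf("locus%03d", seq_len(nLoci))
  doseL <- vector("list", nLoci)
  posL <- vector("list", nLoci)
  for (l in seq_len(nLoci)) {
    hap <- simulateCoalescentLocus(nHaplotypes, thetaPerSite, lengthBp)
    posL[[l]] <- attr(hap, "positions")
    doseL[[l]] <- t(hap[seq(1L, nHaplotypes, 2L), , drop = FALSE] +
                      hap[seq(2L, nHaplotypes, 2L), , drop = FALSE])
  }
  dosage <- do.call(rbind, doseL)
  colnames(dosage) <- ids
  chromVec <- rep(chroms, vapply(posL, length, integer(1)))
  posVec <- unlist(posL, use.names = FALSE)
  sl <- stats::setNames(rep(lengthBp, nLoci), chroms)
  n <- length(posVec)
  panel <- GenotypePanel(dosage, chrom = chromVec, pos = posVec,
                         ref = rep("A", n), alt = rep("T", n),
                         seqlengths = sl, sort = FALSE)
  sampleInfo <- data.frame(sample_id = ids, population = "POP1",
                           origin = "coalescent", stringsAsFactors = FALSE)
  list(panel = panel, sampleInfo = sampleInfo)
}

#' Calibrate per-population drift to target pairwise Fst
#'
#' Finds Balding-Nichols drift values `F_k` such that pilot-simulated
#' pairwise Weir-Cockerham Fst matches a target matrix. Initialized from
#' the linear approximation `E[Fst_ij] ~ (F_i + F_j) / 2` and refined by
#' multiplicative updates against pilot simulations under a fixed seed.
#'
#' @param targetFst symmetric k x k matrix of target pairwise Fst with
#'   zero diagonal.
#' @param nPerPop pilot diploid counts per population (default 40 each).
#' @param nSnps pilot SNP count.
#' @param nRounds refinement rounds.
#' @param seed pilot-simulation seed.
#' @return named numeric vector of drift values.
#' @export
calibrateDrift <- function(targetFst, nPerPop = NULL, nSnps = 20000L,
                           nRounds = 4L, seed = 99L) {
  targetFst <- as.matrix(targetFst)
  k <- nrow(targetFst)
  stopifnot(ncol(targetFst) == k, max(abs(targetFst - t(targetFst))) < 1e-12,
            all(diag(targetFst) == 0))
  pops <- rownames(targetFst)
  if (is.null(pops)) pops <- paste0("POP", seq_len(k))
  if (is.null(nPerPop)) nPerPop <- stats::setNames(rep(40L, k), pops)
  pairs <- utils::combn(k, 2L)
  tvec <- targetFst[t(pairs)]
  if (all(tvec == 0)) {
    return(stats::setNames(rep(1e-6, k), pops))  # drift-free limit
  }
  A <- matrix(0, ncol(pairs), k)
  for (j in seq_len(ncol(pairs))) A[j, pairs[, j]] <- 0.5
  F0 <- as.vector(stats::coef(stats::lm.fit(A, tvec)))
  ## with two populations the pairwise system is underdetermined;
  ## fall back to the symmetric solution F_i = F_j = target
  if (anyNA(F0)) F0 <- rep(mean(tvec), k)
  if (any(F0 <= 0)) {
    warning("target Fst matrix is not jointly attainable; clamping drift")
    F0 <- pmax(F0, 1e-4)
  }
  Fk <- F0
  for (r in seq_len(nRounds)) {
    sim <- simulateBNPanel(nPerPop, stats::setNames(Fk, pops), nSnps,
                           seed = deriveSeed(seed, r))
    obs <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      obs[j] <- wcFstGenomeWide(sim$panel, sim$sampleInfo,
                                pops[pairs[1L, j]], pops[pairs[2L, j]])
    }
    for (i in seq_len(k)) {
      inv <- which(pairs[1L, ] == i | pairs[2L, ] == i)
      ratio <- mean(tvec[inv]) / mean(obs[inv])
      Fk[i] <- min(0.99, max(1e-6, Fk[i] * ratio))
    }
  }
  stats::setNames(Fk, pops)
}
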