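# Shared fixture builders. All fixtures are constructed in code; tiny
# panels use explicit dosage matrices so expected values can be computed
# by hand or by the brute-force oracles below.

makePanel <- function(dosage, chrom = NULL, pos = NULL, ref = NULL,
                      alt = NULL, seqlengths = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  }
  GenotypePanel(dosage, chrom = chrom, pos = pos, ref = ref, alt = alt,
                seqlengths = seqlengths)
}

sampleInfoFor <- function(panel, population = "POP1") {
  data.frame(sample_id = sampleIds(panel),
             population = rep(population, length.out = nSamples(panel)),
             origin = "test", stringsAsFactors = FALSE)
}

# brute-force mean pairwise difference over all allele pairs at one site
bruteSitePi <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(g) {
    c(rep(1L, g), rep(0L, 2L - g))
  }))
  n <- length(alleles)
  if (n < 2) return(NaN)
  tot <- 0L
  for (i in seq_len(n - 1L)) {
    tot <- tot + sum(alleles[i] != alleles[(i + 1L):n])
  }
  tot / choose(n, 2)
}

# independent evaluation of the Tajima's D normalizing constants
bruteTajimaD <- function(piSum, S, n) {
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (piSum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# a small three-population Balding-Nichols panel for structure tests
smallStructuredPanel <- function(nSnps = 1200L, seed = 42L,
                                 drift = c(POP1 = 0.07, POP2 = 0.17,
                                           POP3 = 0.23)) {
  simulateBNPanel(c(POP1 = 16L, POP2 = 12L, POP3 = 10L), drift, nSnps,
                  seed = seed)
}
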