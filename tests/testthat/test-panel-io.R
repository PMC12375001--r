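test_that("VCF genotypes map to dosages; non-biallelic records are dropped", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", "sC", sep = "\t"),
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t150\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",   # multi-allelic
    "1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",    # indel
    "1\t300\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t0|1\t1|1"      # missing + phased
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  p <- readVCF(f)
  expect_equal(nVariants(p), 2L)
  expect_equal(p@metadata$vcf_exclusions[["non_biallelic_snp"]], 2L)
  expect_equal(unname(dosages(p)[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(dosages(p)[2, ]), c(NA_integer_, 1L, 2L))
  expect_equal(sampleIds(p), c("sA", "sB", "sC"))
  p2 <- readVCF(f, region = "1:100-150")
  expect_equal(nVariants(p2), 1L)
})

test_that("VCF write -> read round-trips and re-writing is byte-stable", {
  cfg <- simConfig(seed = 11L, chromLayout = c(cA = 60000L, cB = 40000L),
                   nPerPop = c(POP1 = 4L, POP2 = 3L, POP3 = 2L),
                   nAdmixed = 0L, sweeps = list(),
                   geneSim = list(nGenes = 2L, codonRange = c(60L, 90L),
                                  exonRange = c(1L, 2L)))
  sim <- simulatePanel(cfg)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeVCF(sim$panel, f1)
  back <- readVCF(f1)
  expect_identical(dosages(back), dosages(sim$panel))
  expect_equal(start(loci(back)), start(loci(sim$panel)))
  expect_identical(S4Vectors::mcols(loci(back))$ref,
                   S4Vectors::mcols(loci(sim$panel))$ref)
  writeVCF(back, f2)
  body <- function(x) grep("^#", readLines(x), invert = TRUE, value = TRUE)
  expect_identical(body(f1), body(f2))
  ## header-only VCF for an empty panel
  empty <- filterVariants(makePanel(matrix(0L, 1, 3)),
                          filterSpec(minMAF = 0.4)) |> suppressWarnings()
  f3 <- withr::local_tempfile(fileext = ".vcf")
  writeVCF(empty, f3)
  expect_length(body(f3), 0L)
  expect_silent(readVCF(f3))
})

test_that("missingness and MAF filters use strict > / < thresholds", {
  ## 10 samples; site 1 has 3 missing (0.3 > 0.2 -> removed), site 2 has
  ## 2 missing (0.2, kept)
  d <- matrix(1L, nrow = 2, ncol = 10)
  d[1, 1:3] <- NA_integer_
  d[2, 1:2] <- NA_integer_
  p <- makePanel(d)
  kept <- filterVariants(p, filterSpec(minMAF = 0))
  expect_equal(nVariants(kept), 1L)
  expect_equal(kept@metadata$filter_exclusions[["missingness"]], 1L)

  ## 100 samples = 200 alleles: alt count 1 -> MAF 0.005 removed;
  ## alt count 2 -> exactly 0.01 retained; monomorphic removed
  d <- matrix(0L, nrow = 3, ncol = 100)
  d[1, 1] <- 1L
  d[2, 1] <- 2L
  p <- makePanel(d)
  kept <- filterVariants(p)
  expect_equal(nVariants(kept), 1L)
  expect_equal(unname(dosages(kept)[1, 1]), 2L)
  expect_equal(kept@metadata$filter_exclusions[["maf"]], 2L)
})

test_that("filtering is idempotent and retained sites verify by recount", {
  sim <- simulateBNPanel(c(POP1 = 20L), c(POP1 = 0.1), 400L, seed = 9L)
  d <- dosages(sim$panel)
  set.seed(1)
  d[sample(length(d), 300)] <- NA_integer_
  p <- makePanel(d)
  spec <- filterSpec(maxMissingFraction = 0.1, minMAF = 0.05)
  once <- filterVariants(p, spec)
  twice <- filterVariants(once, spec)
  expect_identical(dosages(once), dosages(twice))
  ## brute-force recount on every retained site
  for (i in seq_len(nVariants(once))) {
    g <- dosages(once)[i, ]
    expect_lte(mean(is.na(g)), 0.1)
    al <- 2 * sum(!is.na(g))
    alt <- sum(g, na.rm = TRUE)
    expect_gte(min(alt, al - alt) / al, 0.05)
  }
  expect_warning(filterVariants(makePanel(matrix(0L, 2, 4))),
                 "all variants removed")
})

test_that("gene models, reference and sample table round-trip", {
  cfg <- simConfig(seed = 13L, chromLayout = c(cA = 120000L),
                   nPerPop = c(POP1 = 3L, POP2 = 2L, POP3 = 2L),
                   nAdmixed = 0L, sweeps = list(),
                   geneSim = list(nGenes = 6L, codonRange = c(60L, 120L),
                                  exonRange = c(1L, 3L)))
  sim <- simulatePanel(cfg)
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(sim$genes, gf)
  back <- readGFF3(gf)
  expect_equal(length(back$genes), length(sim$genes$genes))
  expect_identical(S4Vectors::mcols(back$genes)$gene_id,
                   S4Vectors::mcols(sim$genes$genes)$gene_id)
  for (tx in names(sim$genes$cds)) {
    expect_equal(start(back$cds[[tx]]), start(sim$genes$cds[[tx]]))
    expect_equal(end(back$cds[[tx]]), end(sim$genes$cds[[tx]]))
    expect_equal(S4Vectors::mcols(back$cds[[tx]])$phase,
                 S4Vectors::mcols(sim$genes$cds[[tx]])$phase)
    ## minus-strand exons are stored ascending regardless of strand
    expect_false(is.unsorted(start(back$exons[[tx]])))
  }
  ff <- withr::local_tempfile(fileext = ".fa")
  writeFASTA(sim$reference, ff)
  expect_identical(as.character(readFASTA(ff)),
                   as.character(sim$reference))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeSampleTable(sim$sampleInfo, tf)
  expect_identical(readSampleTable(tf), sim$sampleInfo)
  bad <- sim$sampleInfo
  bad$population[1] <- "POPX"
  writeSampleTable(bad, tf)
  expect_error(readSampleTable(tf), "outside the declared set")
})

test_that("GenotypePanel validity catches malformed input", {
  expect_error(GenotypePanel(matrix(3L, 1, 2), chrom = "c", pos = 1L,
                             ref = "A", alt = "T"), "0, 1, 2")
  expect_error(GenotypePanel(matrix(0L, 1, 2), chrom = "c", pos = 1L,
                             ref = "A", alt = "A"), "must differ")
  expect_error(GenotypePanel(matrix(0L, 2, 2,
                                    dimnames = list(NULL, c("a", "a"))),
                             chrom = c("c", "c"), pos = c(1L, 2L),
                             ref = c("A", "C"), alt = c("T", "G")),
               "unique")
})
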