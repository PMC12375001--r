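nullTracks <- function(n, seed) {
  set.seed(seed)
  w <- data.frame(chrom = "c", start = seq(0L, by = 1000L, length.out = n),
                  end = seq(1000L, by = 1000L, length.out = n))
  list(fst = duripop:::.newTrack(w, 10L, runif(n), "fst", "A-B"),
       rod = duripop:::.newTrack(w, 10L, runif(n), "rod", "A-B"))
}

test_that("joint outliers hit the product-of-quantiles rate under the null", {
  tr <- nullTracks(10000L, seed = 1L)
  jo <- jointOutliers(tr$fst, tr$rod, 0.95)
  ## independent uniforms: expected fraction 0.25%, i.e. about 25 windows
  expect_gte(nrow(jo$candidates), 10L)
  expect_lte(nrow(jo$candidates), 45L)
  expect_true(all(jo$candidates$fst >= jo$cutoffFst &
                    jo$candidates$rod >= jo$cutoffRod))
})

test_that("degenerate all-equal tracks follow the >= cutoff rule", {
  w <- data.frame(chrom = "c", start = 0:24 * 1000L, end = 1:25 * 1000L)
  same <- duripop:::.newTrack(w, 5L, rep(0.3, 25), "fst", "A-B")
  jo <- jointOutliers(same, same, 0.95)
  expect_equal(nrow(jo$candidates), 25L)
})

test_that("raising the quantile never adds candidates", {
  tr <- nullTracks(2000L, seed = 3L)
  sizes <- vapply(c(0.80, 0.90, 0.95, 0.99), function(q) {
    nrow(jointOutliers(tr$fst, tr$rod, q)$candidates)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  ## candidate sets are nested
  a <- jointOutliers(tr$fst, tr$rod, 0.90)$candidates
  b <- jointOutliers(tr$fst, tr$rod, 0.95)$candidates
  expect_true(all(paste(b$chrom, b$start) %in% paste(a$chrom, a$start)))
})

test_that("gene overlap respects half-open window boundaries", {
  genes <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(100L, 2001L, 5000L), c(500L, 2300L, 5400L)),
    strand = "+", gene_id = c("gIn", "gAbut", "gOut"))
  models <- GeneModelSet(genes, GenomicRanges::GRangesList(),
                         GenomicRanges::GRangesList(), character(0))
  win <- data.frame(chrom = "c", start = 0L, end = 2000L)
  ## gIn inside; gAbut starts at 2001 = one past the half-open end
  expect_equal(windowsToGenes(win, models), "gIn")
  win2 <- data.frame(chrom = "c", start = 0L, end = 2001L)
  expect_equal(windowsToGenes(win2, models), c("gAbut", "gIn"))
  ## randomized windows match a brute-force interval check
  set.seed(8)
  starts <- sample.int(6000L, 30L)
  rnd <- data.frame(chrom = "c", start = starts, end = starts + 400L)
  got <- windowsToGenes(rnd, models)
  brute <- sort(unique(unlist(lapply(seq_len(nrow(rnd)), function(i) {
    hit <- GenomicRanges::start(genes) <= rnd$end[i] &
      GenomicRanges::end(genes) >= rnd$start[i] + 1L
    S4Vectors::mcols(genes)$gene_id[hit]
  }))))
  expect_equal(got, brute)
})

test_that("the Venn partition matches brute-force set algebra", {
  same <- list(a = c("g1", "g2"), b = c("g1", "g2"), c = c("g1", "g2"))
  v <- sharedSelectionGenes(same)
  expect_equal(v$sharedAll, c("g1", "g2"))
  expect_true(all(lengths(v$uniques) == 0))
  disj <- list(a = "g1", b = "g2", c = "g3")
  expect_length(sharedSelectionGenes(disj)$sharedAll, 0L)
  set.seed(5)
  pool <- paste0("g", 1:40)
  sets <- list(A = sample(pool, 20), B = sample(pool, 15),
               C = sample(pool, 25))
  v <- sharedSelectionGenes(sets)
  expect_equal(sort(v$sharedAll),
               sort(Reduce(intersect, sets)))
  expect_equal(sort(v$uniques$A),
               sort(setdiff(sets$A, union(sets$B, sets$C))))
  expect_equal(sum(v$counts), length(unique(unlist(sets))))
})

test_that("planted sweeps are flagged and quantified", {
  detected <- 0L
  nRep <- 10L
  for (r in seq_len(nRep)) {
    cfg <- simConfig(seed = 500L + r, chromLayout = c(cA = 3000000L),
                     snpDensity = 0.003,
                     nPerPop = c(POP1 = 15L, POP2 = 2L, POP3 = 12L),
                     nAdmixed = 0L, missingRate = 0,
                     geneSim = list(nGenes = 3L, codonRange = c(60L, 90L),
                                    exonRange = c(1L, 2L)),
                     sweeps = list(sweepSpec("POP3", "cA", 1000001L,
                                             1200000L, 0.15)))
    sim <- simulatePanel(cfg)
    ws <- windowSpec(100000L)
    piA <- windowedPi(sim$panel, sim$sampleInfo, "POP1", ws)
    piB <- windowedPi(sim$panel, sim$sampleInfo, "POP3", ws)
    fst <- wcFst(sim$panel, sim$sampleInfo, "POP1", "POP3", ws)$track
    rod <- rodTrack(piA, piB)
    jo <- jointOutliers(fst, rod, 0.95)
    hit <- any(jo$candidates$start >= 1000000 &
                 jo$candidates$end <= 1200000)
    if (hit) detected <- detected + 1L
  }
  expect_gte(detected, nRep - 1L)
})

test_that("diversity drop reports region against genome background", {
  cfg <- simConfig(seed = 41L, chromLayout = c(cA = 1500000L),
                   nPerPop = c(POP1 = 18L, POP2 = 2L, POP3 = 14L),
                   nAdmixed = 0L, missingRate = 0,
                   geneSim = list(nGenes = 2L, codonRange = c(60L, 90L),
                                  exonRange = c(1L, 2L)),
                   sweeps = list(sweepSpec("POP3", "cA", 600001L, 800000L,
                                           0.2)))
  sim <- simulatePanel(cfg)
  ws <- windowSpec(100000L, minSnps = 1L)
  piT <- windowedPi(sim$panel, sim$sampleInfo, "POP3", ws)
  dT <- tajimasD(sim$panel, sim$sampleInfo, "POP3", ws)
  region <- list(chrom = "cA", start = 600000L, end = 800000L)
  rep_ <- diversityDropReport(list(pi = piT, tajimaD = dT), region)
  expect_lt(rep_$ratio[rep_$track == "pi"], 0.45)
  ## a neutral region sits near the genome background
  neutral <- diversityDropReport(list(pi = piT),
                                 list(chrom = "cA", start = 0L,
                                      end = 400000L))
  expect_lt(abs(neutral$ratio[1] - 1), 0.35)
  expect_error(diversityDropReport(list(pi = piT),
                                   list(chrom = "cB", start = 0L,
                                        end = 1000L)),
               "overlaps no windows")
})
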