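## Windowed diversity and differentiation statistics.
##
## All window tracks are plain data.frames with columns
## chrom / start / end / n_snps / value, start-end being 0-based
## half-open coordinates (the one place the package departs from the
## 1-based inclusive convention of VCF/GFF3; conversion is centralized
## in .windowsToGRanges). Per-bp statistics use the window length as
## denominator, so sites not in the panel count as monomorphic.

#' Windowing scheme for genomic statistics
#'
#' Defaults follow the 100-kb non-overlapping convention used for the
#' headline diversity and sweep scans; a 50-kb sliding alternative is a
#' matter of `size`/`step`. `minSnps` gates the statistics whose
#' sampling variance explodes in near-empty windows (Tajima's D, Fst);
#' windowed pi treats absent sites as monomorphic instead.
#'
#' @param size window size in bp.
#' @param step step in bp (default `size`, i.e. non-overlapping).
#' @param minSnps minimum SNPs for a defined window value.
#' @export
windowSpec <- function(size = 100000L, step = size, minSnps = 5L) {
  stopifnot(step > 0, step <= size, minSnps >= 0)
  structure(list(size = as.integer(size), step = as.integer(step),
                 minSnps = as.integer(minSnps)),
            class = "windowSpec")
}

## chromosome lengths: declared seqlengths, else max position rounded up
.chromLengths <- function(panel, spec) {
  sl <- seqlengths(panel@loci)
  if (length(sl) == 0 || anyNA(sl)) {
    chrom <- as.character(seqnames(panel@loci))
    pos <- start(panel@loci)
    mx <- tapply(pos, factor(chrom, levels = seqlevels(panel@loci)), max)
    mx[is.na(mx)] <- spec$size
    sl <- ceiling(mx / spec$size) * spec$size
    names(sl) <- seqlevels(panel@loci)
  }
  sl
}

#' Tile chromosomes into windows
#'
#' @param chromLengths named vector of chromosome lengths.
#' @param spec a [windowSpec()].
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
makeWindows <- function(chromLengths, spec = windowSpec()) {
  out <- lapply(names(chromLengths), function(ch) {
    L <- chromLengths[[ch]]
    starts <- seq(0L, max(0L, L - 1L), by = spec$step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + spec$size, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.windowsToGRanges <- function(windows) {
  GRanges(windows$chrom, IRanges(windows$start + 1L, windows$end))
}

## map each variant to the window(s) containing it
.windowHits <- function(panel, windows) {
  ov <- findOverlaps(panel@loci, .windowsToGRanges(windows))
  list(site = queryHits(ov), win = subjectHits(ov))
}

.newTrack <- function(windows, n_snps, value, statistic, population) {
  df <- data.frame(chrom = windows$chrom, start = windows$start,
                   end = windows$end, n_snps = n_snps, value = value,
                   stringsAsFactors = FALSE)
  attr(df, "statistic") <- statistic
  attr(df, "population") <- population
  df
}

.checkAligned <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(a$start, b$start) ||
      !identical(a$end, b$end)) {
    stop("window tracks are not aligned (chrom/start/end differ)")
  }
}

#' Per-site nucleotide diversity
#'
#' For each variant, `pi = nRef * nAlt / choose(n, 2)` with `n` the
#' non-missing allele count in the chosen samples: the mean pairwise
#' difference over all allele pairs at the site. Sites with fewer than 2
#' non-missing alleles are `NaN`.
#'
#' @param panel a `GenotypePanel`.
#' @param sampleInfo sample metadata (needed when `population` given).
#' @param population population label, or NULL for all samples.
#' @return numeric vector, one value per variant.
#' @export
sitePi <- function(panel, sampleInfo = NULL, population = NULL) {
  samples <- if (!is.null(population)) popSamples(sampleInfo, population)
  ac <- alleleCounts(panel, samples)
  n <- ac$nAllele
  res <- ifelse(n >= 2,
                ac$nAlt * (n - ac$nAlt) / (n * (n - 1) / 2),
                NaN)
  res
}

#' Windowed nucleotide diversity
#'
#' Window value = sum of per-site pi over SNPs in the window divided by
#' the window length in bp (per-bp diversity; absent sites count as
#' monomorphic). A window with no genotyped SNPs therefore has value 0,
#' with `n_snps` recording the evidence.
#'
#' @inheritParams sitePi
#' @param spec a [windowSpec()].
#' @return a window track data.frame (see [windowSpec()]).
#' @export
windowedPi <- function(panel, sampleInfo = NULL, population = NULL,
                       spec = windowSpec()) {
  windows <- makeWindows(.chromLengths(panel, spec), spec)
  sp <- sitePi(panel, sampleInfo, population)
  sp[is.na(sp)] <- 0
  hits <- .windowHits(panel, windows)
  nw <- nrow(windows)
  piSum <- numeric(nw)
  cnt <- integer(nw)
  agg <- tapply(sp[hits$site], hits$win, sum)
  piSum[as.integer(names(agg))] <- agg
  tb <- table(hits$win)
  cnt[as.integer(names(tb))] <- as.integer(tb)
  .newTrack(windows, cnt, piSum / (windows$end - windows$start),
            "pi", ifelse(is.null(population), "ALL", population))
}

#' Genome-wide summary of a per-bp window track
#'
#' Length-weighted mean over windows with a defined value.
#'
#' @param track a window track.
#' @return scalar.
#' @export
genomeWideMean <- function(track) {
  w <- track$end - track$start
  ok <- is.finite(track$value)
  sum(track$value[ok] * w[ok]) / sum(w[ok])
}

#' Windowed Watterson's theta
#'
#' `S / a1` per window divided by window length, with `S` the number of
#' segregating sites and `a1 = sum(1/i, i < n)` for the window's modal
#' non-missing allele count.
#'
#' @inheritParams windowedPi
#' @export
windowedTheta <- function(panel, sampleInfo = NULL, population = NULL,
                          spec = windowSpec()) {
  samples <- if (!is.null(population)) popSamples(sampleInfo, population)
  ac <- alleleCounts(panel, samples)
  seg <- ac$nAlt > 0 & ac$nAlt < ac$nAllele
  windows <- makeWindows(.chromLengths(panel, spec), spec)
  hits <- .windowHits(panel, windows)
  nw <- nrow(windows)
  value <- rep(NaN, nw)
  cnt <- integer(nw)
  for (w in unique(hits$win)) {
    sites <- hits$site[hits$win == w]
    cnt[w] <- length(sites)
    S <- sum(seg[sites])
    nMode <- .modal(ac$nAllele[sites])
    if (S >= 1 && nMode >= 2) {
      a1 <- sum(1 / seq_len(nMode - 1))
      value[w] <- S / a1 / (windows$end[w] - windows$start[w])
    } else value[w] <- 0
  }
  .newTrack(windows, cnt, value, "thetaW",
            ifelse(is.null(population), "ALL", population))
}

.modal <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(0L)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Tajima's D constants for sample size n (alleles)
#' @param n number of alleles (>= 2).
#' @return list a1, a2, b1, b2, c1, c2, e1, e2.
#' @keywords internal
tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants evaluated at the window's modal non-missing allele count
#' (missing data make n vary site to site; the modal-n approximation is
#' standard practice). Windows with `S = 0`, `n < 4` or fewer than
#' `minSnps` SNPs are `NaN`.
#'
#' @inheritParams windowedPi
#' @export
tajimasD <- function(panel, sampleInfo = NULL, population = NULL,
                     spec = windowSpec()) {
  samples <- if (!is.null(population)) popSamples(sampleInfo, population)
  ac <- alleleCounts(panel, samples)
  n <- ac$nAllele
  sp <- ifelse(n >= 2, ac$nAlt * (n - ac$nAlt) / (n * (n - 1) / 2), 0)
  seg <- ac$nAlt > 0 & ac$nAlt < ac$nAllele
  windows <- makeWindows(.chromLengths(panel, spec), spec)
  hits <- .windowHits(panel, windows)
  nw <- nrow(windows)
  value <- rep(NaN, nw)
  cnt <- integer(nw)
  for (w in unique(hits$win)) {
    sites <- hits$site[hits$win == w]
    cnt[w] <- length(sites)
    if (length(sites) < spec$minSnps) next
    S <- sum(seg[sites])
    nMode <- .modal(n[sites])
    if (S < 1 || nMode < 4) next
    k <- tajimaConstants(nMode)
    varD <- k$e1 * S + k$e2 * S * (S - 1)
    if (varD <= 0) next
    value[w] <- (sum(sp[sites]) - S / k$a1) / sqrt(varD)
  }
  .newTrack(windows, cnt, value, "tajimaD",
            ifelse(is.null(population), "ALL", population))
}

## per-site Weir-Cockerham variance components for two populations;
## returns a data.frame of a, b, c (NaN rows excluded by `valid`)
.wcComponents <- function(panel, sampleInfo, popA, popB) {
  acA <- alleleCounts(panel, popSamples(sampleInfo, popA))
  acB <- alleleCounts(panel, popSamples(sampleInfo, popB))
  n1 <- acA$nGeno; n2 <- acB$nGeno
  valid <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  p1 <- ifelse(n1 > 0, acA$nAlt / (2 * n1), 0)
  p2 <- ifelse(n2 > 0, acB$nAlt / (2 * n2), 0)
  h1 <- ifelse(n1 > 0, acA$nHet / n1, 0)
  h2 <- ifelse(n2 > 0, acB$nHet / n2, 0)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  data.frame(a = a, b = b, c = cc, valid = valid)
}

#' Weir-Cockerham Fst (two populations, ratio-of-sums)
#'
#' Per-site variance components `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals)
#' are computed with per-site sample sizes; window and genome-wide
#' estimates are the weighted "ratio of sums"
#' `sum(a) / sum(a + b + c)`. Per-site components may be negative and
#' are retained before summation.
#'
#' @inheritParams windowedPi
#' @param popA,popB population labels.
#' @return list with `track` (window track) and `genomeWide` (scalar).
#' @export
wcFst <- function(panel, sampleInfo, popA, popB, spec = windowSpec()) {
  comp <- .wcComponents(panel, sampleInfo, popA, popB)
  windows <- makeWindows(.chromLengths(panel, spec), spec)
  hits <- .windowHits(panel, windows)
  nw <- nrow(windows)
  value <- rep(NaN, nw)
  cnt <- integer(nw)
  for (w in unique(hits$win)) {
    sites <- hits$site[hits$win == w]
    sites <- sites[comp$valid[sites]]
    cnt[w] <- length(sites)
    if (length(sites) < spec$minSnps) next
    num <- sum(comp$a[sites])
    den <- sum(comp$a[sites] + comp$b[sites] + comp$c[sites])
    value[w] <- if (den == 0) NaN else num / den
  }
  ok <- comp$valid
  gw <- sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  track <- .newTrack(windows, cnt, value, "fst", paste(popA, popB, sep = "-"))
  list(track = track, genomeWide = gw)
}

#' @rdname wcFst
#' @export
wcFstGenomeWide <- function(panel, sampleInfo, popA, popB) {
  comp <- .wcComponents(panel, sampleInfo, popA, popB)
  ok <- comp$valid
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' Ratio of two aligned diversity tracks
#'
#' `value = piA / piB` per window; `NaN` where `piB` is 0 or either
#' input undefined. The genome-wide median over defined windows is
#' attached as attribute `median`.
#'
#' @param trackA,trackB aligned window tracks (e.g. from [windowedPi()]).
#' @return a window track with attribute `median`.
#' @export
piRatioTrack <- function(trackA, trackB) {
  .checkAligned(trackA, trackB)
  value <- ifelse(is.finite(trackA$value) & is.finite(trackB$value) &
                    trackB$value > 0,
                  trackA$value / trackB$value, NaN)
  out <- .newTrack(trackA[, c("chrom", "start", "end")],
                   pmin(trackA$n_snps, trackB$n_snps), value, "piRatio",
                   paste(attr(trackA, "population"),
                         attr(trackB, "population"), sep = "/"))
  attr(out, "median") <- stats::median(value[is.finite(value)])
  out
}

#' Reduction of diversity (ROD) track
#'
#' `ROD = 1 - piB / piA`: large where population B (the putatively swept
#' population) has lost diversity relative to reference population A.
#' Set `mirror = TRUE` for the opposite orientation.
#'
#' @param trackA reference-population pi track.
#' @param trackB target-population pi track.
#' @param mirror swap the roles of A and B.
#' @return a window track.
#' @export
rodTrack <- function(trackA, trackB, mirror = FALSE) {
  if (mirror) { tmp <- trackA; trackA <- trackB; trackB <- tmp }
  .checkAligned(trackA, trackB)
  value <- ifelse(is.finite(trackA$value) & is.finite(trackB$value) &
                    trackA$value > 0,
                  1 - trackB$value / trackA$value, NaN)
  .newTrack(trackA[, c("chrom", "start", "end")],
            pmin(trackA$n_snps, trackB$n_snps), value, "rod",
            paste(attr(trackA, "population"),
                  attr(trackB, "population"), sep = "-"))
}

#' Write a window track as BED-like TSV
#'
#' Columns chrom, start, end, n_snps, value (0-based half-open).
#'
#' @param track a window track.
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
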