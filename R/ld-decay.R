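## Linkage disequilibrium decay.
##
## r2 is the squared Pearson correlation of unphased dosage vectors
## (Rogers-Huff composite estimate): no phasing assumption, standard for
## diploid resequencing panels.

#' Pairwise r-squared at varying physical distances
#'
#' Enumerates same-chromosome SNP pairs up to `maxDistance` apart and
#' computes the squared Pearson correlation of their dosage vectors over
#' samples non-missing at both sites. When the number of pairs in a
#' distance stratum (of `binWidth` bp) exceeds `maxPairsPerBin`, a
#' uniform subsample is taken under `seed` for reproducibility. Pairs
#' where either site has zero dosage variance are skipped.
#'
#' @param panel a `GenotypePanel`.
#' @param sampleInfo sample metadata (when `population` given).
#' @param population population label or NULL for all samples.
#' @param maxDistance maximum pair distance in bp.
#' @param binWidth stratum width for subsampling (and later binning).
#' @param maxPairsPerBin cap on pairs retained per distance stratum.
#' @param seed subsampling seed.
#' @return data.frame with columns `distance`, `r2`.
#' @export
pairwiseR2 <- function(panel, sampleInfo = NULL, population = NULL,
                       maxDistance = 500000L, binWidth = 1000L,
                       maxPairsPerBin = 2000L, seed = 1L) {
  d <- panel@dosage
  if (!is.null(population)) {
    d <- d[, match(popSamples(sampleInfo, population), colnames(d)),
           drop = FALSE]
  }
  chrom <- as.character(seqnames(panel@loci))
  pos <- start(panel@loci)
  set.seed(seed)
  iAll <- integer(0); jAll <- integer(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L) next
    p <- pos[idx]
    ## enumerate pairs (i, j > i) with p[j] - p[i] <= maxDistance
    hi <- findInterval(p + maxDistance, p)
    reps <- hi - seq_along(p)
    ii <- rep(seq_along(p), pmax(reps, 0L))
    jj <- ii + sequence(pmax(reps, 0L))
    iAll <- c(iAll, idx[ii])
    jAll <- c(jAll, idx[jj])
  }
  if (!length(iAll)) stop("no SNP pairs within maxDistance")
  dist <- pos[jAll] - pos[iAll]
  ## stratified subsampling per distance bin
  strat <- dist %/% binWidth
  keep <- unlist(lapply(split(seq_along(strat), strat), function(s) {
    if (length(s) > maxPairsPerBin) sample(s, maxPairsPerBin) else s
  }), use.names = FALSE)
  iAll <- iAll[keep]; jAll <- jAll[keep]; dist <- dist[keep]
  ## vectorized pairwise-complete correlation, in blocks to bound memory
  mask <- !is.na(d)
  dz <- d; dz[!mask] <- 0L
  storage.mode(dz) <- "double"
  storage.mode(mask) <- "double"
  r2 <- numeric(length(iAll))
  blk <- 50000L
  for (b in seq(1L, length(iAll), by = blk)) {
    sel <- b:min(b + blk - 1L, length(iAll))
    X <- dz[iAll[sel], , drop = FALSE]
    Y <- dz[jAll[sel], , drop = FALSE]
    M <- mask[iAll[sel], , drop = FALSE] * mask[jAll[sel], , drop = FALSE]
    X <- X * M; Y <- Y * M
    n <- rowSums(M)
    sx <- rowSums(X); sy <- rowSums(Y)
    sxx <- rowSums(X * X); syy <- rowSums(Y * Y); sxy <- rowSums(X * Y)
    vx <- n * sxx - sx^2
    vy <- n * syy - sy^2
    r2[sel] <- ifelse(n >= 3 & vx > 0 & vy > 0,
                      (n * sxy - sx * sy)^2 / (vx * vy), NA_real_)
  }
  ok <- !is.na(r2)
  data.frame(distance = dist[ok], r2 = r2[ok])
}

#' Bin an LD pair list into a decay curve
#'
#' Arithmetic mean of r2 per contiguous distance bin; empty bins are
#' `NaN`.
#'
#' @param pairs data.frame from [pairwiseR2()].
#' @param binWidth bin width in bp.
#' @param maxDistance upper edge of the last bin (default: observed max).
#' @return data.frame `binStart`, `binEnd`, `meanR2`, `nPairs`.
#' @export
binCurve <- function(pairs, binWidth = 1000L, maxDistance = NULL) {
  stopifnot(nrow(pairs) > 0)
  if (is.null(maxDistance)) maxDistance <- max(pairs$distance)
  edges <- seq(0L, ceiling(maxDistance / binWidth) * binWidth, by = binWidth)
  bin <- findInterval(pairs$distance, edges, rightmost.closed = FALSE,
                      left.open = TRUE)
  bin[pairs$distance == 0] <- 1L
  nb <- length(edges) - 1L
  meanR2 <- rep(NaN, nb)
  nPairs <- integer(nb)
  agg <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), mean)
  cnt <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), length)
  meanR2[!is.na(agg)] <- agg[!is.na(agg)]
  nPairs[!is.na(cnt)] <- cnt[!is.na(cnt)]
  data.frame(binStart = edges[-length(edges)], binEnd = edges[-1L],
             meanR2 = meanR2, nPairs = nPairs)
}

## shared crossing-point machinery: first distance at which the
## bin-midpoint-interpolated curve reaches `threshold`
.crossingDistance <- function(curve, threshold) {
  def <- which(is.finite(curve$meanR2))
  if (length(def) < 2L) stop("curve has fewer than 2 defined bins")
  mid <- (curve$binStart[def] + curve$binEnd[def]) / 2
  val <- curve$meanR2[def]
  if (val[1L] <= threshold) return(mid[1L])  # boundary rule: first midpoint
  below <- which(val <= threshold)
  if (!length(below)) return(Inf)
  k <- below[1L]
  ## linear interpolation between adjacent defined bin midpoints
  mid[k - 1L] + (mid[k] - mid[k - 1L]) *
    (val[k - 1L] - threshold) / (val[k - 1L] - val[k])
}

#' LD decay summaries
#'
#' `halfDecayDistance` returns the physical distance at which mean r2
#' first drops to half the maximum, the maximum being the first defined
#' bin's mean; `thresholdDistance` the distance at which it first drops
#' to `r2Threshold`. Both interpolate linearly between adjacent bin
#' midpoints and return `Inf` when the curve never crosses within range.
#'
#' @param curve data.frame from [binCurve()].
#' @return distance in bp (possibly `Inf`).
#' @export
halfDecayDistance <- function(curve) {
  def <- which(is.finite(curve$meanR2))
  if (length(def) < 2L) stop("curve has fewer than 2 defined bins")
  .crossingDistance(curve, curve$meanR2[def[1L]] / 2)
}

#' @rdname halfDecayDistance
#' @param r2Threshold absolute r2 threshold (e.g. 0.2).
#' @export
thresholdDistance <- function(curve, r2Threshold) {
  .crossingDistance(curve, r2Threshold)
}
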