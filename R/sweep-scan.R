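## Joint Fst x ROD outlier scan, gene overlap and cross-comparison
## intersection.

#' Joint Fst and ROD outlier windows
#'
#' Cutoffs are the empirical `quantile`-th quantiles of each track over
#' its defined (non-NaN) windows; candidate windows meet both cutoffs
#' simultaneously (`>=`, so degenerate distributions behave
#' predictably). Under independent null tracks the expected candidate
#' fraction is `(1 - quantile)^2`.
#'
#' @param fstTrack,rodTrack aligned window tracks.
#' @param quantile outlier quantile (default 0.95, the top-5% rule).
#' @return list `candidates` (data.frame of candidate windows with their
#'   Fst and ROD), `cutoffFst`, `cutoffRod`, `merged` (bookended union
#'   of adjacent candidate windows).
#' @export
jointOutliers <- function(fstTrack, rodTrack, quantile = 0.95) {
  .checkAligned(fstTrack, rodTrack)
  fst <- fstTrack$value
  rod <- rodTrack$value
  defined <- is.finite(fst) & is.finite(rod)
  if (sum(defined) < 20L) stop("fewer than 20 jointly defined windows")
  cutF <- stats::quantile(fst[is.finite(fst)], quantile, names = FALSE)
  cutR <- stats::quantile(rod[is.finite(rod)], quantile, names = FALSE)
  sel <- defined & fst >= cutF & rod >= cutR
  cand <- data.frame(chrom = fstTrack$chrom[sel],
                     start = fstTrack$start[sel],
                     end = fstTrack$end[sel],
                     fst = fst[sel], rod = rod[sel],
                     stringsAsFactors = FALSE)
  merged <- if (nrow(cand)) {
    gr <- GenomicRanges::reduce(GRanges(cand$chrom,
                                        IRanges(cand$start + 1L, cand$end)))
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
               end = end(gr), stringsAsFactors = FALSE)
  } else cand[, c("chrom", "start", "end")]
  list(candidates = cand, cutoffFst = cutF, cutoffRod = cutR,
       merged = merged)
}

#' Genes overlapping candidate windows
#'
#' A gene is reported when its span overlaps any window by at least 1 bp
#' (half-open window coordinates).
#'
#' @param windows data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param geneModels a [GeneModelSet()].
#' @return sorted character vector of gene ids.
#' @export
windowsToGenes <- function(windows, geneModels) {
  if (!nrow(windows)) return(character(0))
  w <- GRanges(windows$chrom, IRanges(windows$start + 1L, windows$end))
  ov <- findOverlaps(geneModels$genes, w, ignore.strand = TRUE)
  sort(unique(mcols(geneModels$genes)$gene_id[queryHits(ov)]))
}

#' Venn partition of candidate gene sets across comparisons
#'
#' @param geneSets named list of three (or more) character vectors.
#' @return list `sharedAll` (genes in every set), `counts` (named vector
#'   of exclusive region sizes keyed like `"A&B"`), `uniques` (per-set
#'   exclusive genes).
#' @export
sharedSelectionGenes <- function(geneSets) {
  stopifnot(length(geneSets) >= 2)
  nm <- names(geneSets)
  if (is.null(nm)) nm <- paste0("set", seq_along(geneSets))
  all <- sort(unique(unlist(geneSets)))
  member <- vapply(geneSets, function(s) all %in% s, logical(length(all)))
  if (length(all) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
  counts <- table(key)
  sharedAll <- all[rowSums(member) == length(geneSets)]
  uniques <- lapply(seq_along(geneSets), function(j) {
    all[member[, j] & rowSums(member) == 1L]
  })
  names(uniques) <- nm
  list(sharedAll = sharedAll,
       counts = stats::setNames(as.integer(counts), names(counts)),
       uniques = uniques)
}

#' Region versus genome-wide summary of sweep statistics
#'
#' For a candidate region, reports each statistic's mean inside the
#' region against its genome-wide mean (per population or comparison) --
#' the numbers behind a "sharp drop in diversity with high
#' differentiation" narrative.
#'
#' @param tracks named list of window tracks (any mix of pi, Fst,
#'   Tajima's D, ...).
#' @param region list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame: `track`, `regionMean`, `genomeMean`, `ratio`.
#' @export
diversityDropReport <- function(tracks, region) {
  stopifnot(length(tracks) >= 1)
  rows <- lapply(names(tracks), function(nmi) {
    tr <- tracks[[nmi]]
    sel <- tr$chrom == region$chrom & tr$start < region$end &
      tr$end > region$start
    if (!any(sel)) stop("region overlaps no windows of track ", nmi)
    rm_ <- mean(tr$value[sel], na.rm = TRUE)
    gm <- mean(tr$value, na.rm = TRUE)
    data.frame(track = nmi, regionMean = rm_, genomeMean = gm,
               ratio = rm_ / gm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
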