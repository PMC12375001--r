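## Core collection by greedy allele-coverage maximization
## (M-strategy-like): deterministic, with optional per-population
## quotas.

## per-sample allele presence over the polymorphic sites of the panel
.allelePresence <- function(panel) {
  d <- panel@dosage
  ac <- alleleCounts(panel)
  poly <- ac$nAlt > 0 & ac$nAlt < ac$nAllele
  dp <- d[poly, , drop = FALSE]
  list(refPresent = !is.na(dp) & dp < 2L,
       altPresent = !is.na(dp) & dp > 0L,
       nPoly = sum(poly))
}

#' Fraction of the panel's SNP alleles retained by a subset
#'
#' The allele universe is both alleles at every polymorphic site of the
#' full panel (2 x polymorphic-site count); an allele is retained when
#' at least one non-missing genotype of the subset carries it.
#'
#' @param panel the full `GenotypePanel`.
#' @param subset character sample ids.
#' @return fraction in `[0, 1]`.
#' @export
alleleRetention <- function(panel, subset) {
  stopifnot(length(subset) >= 1)
  idx <- match(subset, sampleIds(panel))
  if (anyNA(idx)) {
    stop("subset samples not in panel: ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  ap <- .allelePresence(panel)
  if (ap$nPoly == 0L) return(1)
  refCov <- rowSums(ap$refPresent[, idx, drop = FALSE]) > 0L
  altCov <- rowSums(ap$altPresent[, idx, drop = FALSE]) > 0L
  (sum(refCov) + sum(altCov)) / (2 * ap$nPoly)
}

#' Greedy core collection by allele coverage
#'
#' Starting from the empty set, repeatedly adds the sample covering the
#' most not-yet-retained alleles (ties broken by lexicographic sample
#' id). With `quotas`, candidates are restricted at each step to
#' populations whose quota is not yet met. Deterministic given panel
#' and quotas.
#'
#' @param panel the full `GenotypePanel`.
#' @param coreSize number of samples to select.
#' @param quotas optional named vector of per-population counts summing
#'   to `coreSize` (e.g. `c(POP1 = 10, POP2 = 8, POP3 = 8)`).
#' @param sampleInfo sample metadata (required with `quotas`).
#' @return list `selected` (ordered ids), `retentionCurve` (fraction
#'   after each addition), `finalRetention`, `quotas`.
#' @export
greedyCore <- function(panel, coreSize, quotas = NULL, sampleInfo = NULL) {
  ids <- sampleIds(panel)
  stopifnot(coreSize >= 1, coreSize <= length(ids))
  if (!is.null(quotas)) {
    stopifnot(!is.null(sampleInfo), sum(quotas) == coreSize)
    unknown <- setdiff(names(quotas), unique(sampleInfo$population))
    if (length(unknown)) {
      stop("quota references unknown population(s): ",
           paste(unknown, collapse = ", "))
    }
    popOf <- sampleInfo$population[match(ids, sampleInfo$sample_id)]
  }
  ap <- .allelePresence(panel)
  ord <- order(ids)  # lexicographic tie-break: scan candidates in id order
  refCov <- rep(FALSE, ap$nPoly)
  altCov <- rep(FALSE, ap$nPoly)
  selected <- character(0)
  curve <- numeric(0)
  taken <- rep(FALSE, length(ids))
  quotaLeft <- quotas
  total <- 2 * max(ap$nPoly, 1L)
  for (step in seq_len(coreSize)) {
    bestGain <- -1L
    bestIdx <- NA_integer_
    for (o in ord) {
      if (taken[o]) next
      if (!is.null(quotaLeft) &&
          (!popOf[o] %in% names(quotaLeft) || quotaLeft[[popOf[o]]] <= 0)) next
      gain <- sum(ap$refPresent[!refCov, o]) + sum(ap$altPresent[!altCov, o])
      if (gain > bestGain) { bestGain <- gain; bestIdx <- o }
    }
    if (is.na(bestIdx)) stop("no eligible candidate at step ", step)
    taken[bestIdx] <- TRUE
    refCov <- refCov | ap$refPresent[, bestIdx]
    altCov <- altCov | ap$altPresent[, bestIdx]
    selected <- c(selected, ids[bestIdx])
    curve <- c(curve, (sum(refCov) + sum(altCov)) / total)
    if (!is.null(quotaLeft)) {
      quotaLeft[[popOf[bestIdx]]] <- quotaLeft[[popOf[bestIdx]]] - 1L
    }
  }
  list(selected = selected, retentionCurve = curve,
       finalRetention = curve[length(curve)], quotas = quotas)
}

#' Cumulative allele retention along a sample order
#'
#' @param panel the full `GenotypePanel`.
#' @param order character sample ids in addition order.
#' @return numeric vector of retention fractions after each addition.
#' @export
retentionCurve <- function(panel, order) {
  idx <- match(order, sampleIds(panel))
  if (anyNA(idx)) stop("order contains samples not in the panel")
  ap <- .allelePresence(panel)
  total <- 2 * max(ap$nPoly, 1L)
  refCov <- rep(FALSE, ap$nPoly)
  altCov <- rep(FALSE, ap$nPoly)
  out <- numeric(length(idx))
  for (s in seq_along(idx)) {
    refCov <- refCov | ap$refPresent[, idx[s]]
    altCov <- altCov | ap$altPresent[, idx[s]]
    out[s] <- (sum(refCov) + sum(altCov)) / total
  }
  out
}

#' Heterozygosity retained by a subset, as a companion diversity metric
#'
#' Ratio of mean expected heterozygosity (2 p (1 - p) over non-missing
#' alleles) in the subset to that of the full panel.
#'
#' @inheritParams alleleRetention
#' @export
heterozygosityRetention <- function(panel, subset) {
  he <- function(ac) {
    p <- ifelse(ac$nAllele > 0, ac$nAlt / ac$nAllele, NA_real_)
    mean(2 * p * (1 - p), na.rm = TRUE)
  }
  idx <- match(subset, sampleIds(panel))
  if (anyNA(idx)) stop("subset samples not in panel")
  he(alleleCounts(panel, subset)) / he(alleleCounts(panel))
}
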