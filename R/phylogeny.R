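## Distance-based phylogeny: allele-sharing distances, neighbor joining
## with deterministic tie-breaking, SNP bootstrap support, newick I/O.
## Trees are ape "phylo" objects throughout.

#' Allele-sharing distance matrix
#'
#' `d_ij = mean over shared non-missing sites of |g_i - g_j| / 2`: 0 for
#' identical genotypes, 1 for opposite homozygotes at every shared site.
#'
#' @param panel a `GenotypePanel`.
#' @return symmetric numeric matrix with sample ids as dimnames and the
#'   per-pair count of sites used attached as attribute `nSites`.
#' @export
alleleSharingDistance <- function(panel) {
  d <- panel@dosage
  N <- ncol(d)
  ok <- !is.na(d)
  ## |a - b| decomposed over dosage indicator matrices: one crossprod
  ## per (dosage_i, dosage_j) combination with |i - j| > 0
  I0 <- (ok & d == 0L) + 0
  I1 <- (ok & d == 1L) + 0
  I2 <- (ok & d == 2L) + 0
  S <- crossprod(I0, I1) + crossprod(I1, I0) +
    crossprod(I1, I2) + crossprod(I2, I1) +
    2 * (crossprod(I0, I2) + crossprod(I2, I0))
  nS <- crossprod(ok + 0)
  if (any(nS == 0)) {
    bad <- which(nS == 0, arr.ind = TRUE)[1, ]
    stop("samples ", colnames(d)[bad[1]], " and ", colnames(d)[bad[2]],
         " share no non-missing sites")
  }
  D <- S / (2 * nS)
  diag(D) <- 0
  dimnames(D) <- list(colnames(d), colnames(d))
  storage.mode(nS) <- "integer"
  attr(D, "nSites") <- nS
  D
}

#' Neighbor joining with deterministic tie-breaking
#'
#' Saitou-Nei neighbor joining using the Studier-Keppler Q criterion.
#' Ties in Q are broken by the lexicographically smallest pair of
#' current taxon indices, making the output deterministic. Negative
#' branch lengths are clamped to zero with the deficit transferred to
#' the sibling edge. Recovers any additive distance matrix exactly.
#'
#' @param D symmetric distance matrix with zero diagonal and taxon
#'   dimnames.
#' @return an `ape::phylo` unrooted tree.
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  stopifnot(n >= 3)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  ## clusters carry their newick substring; ties in Q go to the smallest
  ## (i, j) pair in the current cluster order (original taxon order)
  nwk <- as.list(labels)
  Dw <- D
  while (nrow(Dw) > 3L) {
    m <- nrow(Dw)
    rs <- rowSums(Dw)
    Qm <- (m - 2) * Dw - outer(rs, rs, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    di <- 0.5 * Dw[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    dj <- Dw[i, j] - di
    if (di < 0) { dj <- dj - di; di <- 0 }   # clamp, deficit to sibling
    if (dj < 0) { di <- di - dj; dj <- 0 }
    merged <- paste0("(", nwk[[i]], ":", fmt(di), ",",
                     nwk[[j]], ":", fmt(dj), ")")
    newd <- 0.5 * (Dw[i, ] + Dw[j, ] - Dw[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    Dnew <- rbind(cbind(Dw[keep, keep, drop = FALSE], newd[keep]),
                  c(newd[keep], 0))
    nwk <- c(nwk[keep], merged)
    Dw <- Dnew
  }
  ## finish with the unrooted 3-cluster star
  dA <- (Dw[1, 2] + Dw[1, 3] - Dw[2, 3]) / 2
  dB <- (Dw[1, 2] + Dw[2, 3] - Dw[1, 3]) / 2
  dC <- (Dw[1, 3] + Dw[2, 3] - Dw[1, 2]) / 2
  txt <- paste0("(", nwk[[1]], ":", fmt(dA), ",", nwk[[2]], ":", fmt(dB),
                ",", nwk[[3]], ":", fmt(dC), ");")
  ape::read.tree(text = txt)
}

#' SNP bootstrap support for the neighbor-joining tree
#'
#' Resamples variants with replacement `nReplicates` times, rebuilds the
#' allele-sharing NJ tree per replicate, and annotates each internal
#' edge of the full-data tree with the percentage of replicate trees
#' containing the same bipartition (stored as internal node labels, the
#' usual newick convention).
#'
#' @param panel a `GenotypePanel`.
#' @param nReplicates bootstrap replicates (0 = no supports).
#' @param seed integer seed.
#' @return an `ape::phylo` with `node.label` supports (0-100).
#' @export
bootstrapSupport <- function(panel, nReplicates = 100L, seed = 1L) {
  tree <- neighborJoining(alleleSharingDistance(panel))
  if (nReplicates == 0L) return(tree)
  set.seed(seed)
  L <- nVariants(panel)
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    idx <- sort(sample.int(L, L, replace = TRUE))
    bp <- panel
    bp@dosage <- panel@dosage[idx, , drop = FALSE]
    bp@loci <- panel@loci[idx]
    reps[[r]] <- neighborJoining(alleleSharingDistance(bp))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.character(round(100 * counts / nReplicates))
  tree
}

#' Newick round-trip
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; supports are
#' carried as internal node labels.
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  ape::read.tree(path)
}
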