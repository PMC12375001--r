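## Population structure: PCA, admixture EM, cross-validated K.

#' Principal component analysis of a genotype panel
#'
#' Dosages are mean-imputed at missing calls, centered per site and
#' scaled by `sqrt(p * (1 - p))` with `p` the mean dosage / 2 (the
#' standard allele-frequency normalization), after dropping monomorphic
#' sites; the sample covariance is then eigendecomposed.
#'
#' @param panel a `GenotypePanel`.
#' @param nComponents number of components to return.
#' @return list with `coordinates` (samples x components),
#'   `explainedVariance` (fractions, non-increasing).
#' @export
pcaPanel <- function(panel, nComponents = 10L) {
  d <- t(panel@dosage)  # samples x variants
  storage.mode(d) <- "double"
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2L) stop("need at least 2 polymorphic sites")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  sdv <- sqrt(p * (1 - p))
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    x[is.na(x)] <- mu[j]
    d[, j] <- (x - mu[j]) / sdv[j]
  }
  n <- nrow(d)
  nComponents <- min(nComponents, n - 1L, ncol(d))
  if (nComponents < 1L) stop("too few samples for PCA")
  cov <- tcrossprod(d) / ncol(d)
  eig <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(nComponents), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nComponents)]), nComponents)
  rownames(coords) <- sampleIds(panel)
  colnames(coords) <- paste0("PC", seq_len(nComponents))
  list(coordinates = coords,
       explainedVariance = ev[seq_len(nComponents)] / sum(ev))
}

#' Maximum-likelihood admixture model fit by EM
#'
#' Maximizes the binomial admixture likelihood
#' `sum over observed (i, l) of g log(p) + (2 - g) log(1 - p)` with
#' `p_il = sum_k q_ik f_kl` over simplex-constrained ancestry fractions
#' `Q` and box-constrained cluster frequencies `F`, by EM
#' (FRAPPE-style updates). Missing genotypes are skipped in all sums.
#' `nRestarts` seeded restarts (Dirichlet(1) initial Q; overall
#' frequencies plus jitter for F) guard against local optima; the fit
#' with the highest final log-likelihood is returned.
#'
#' @param panel a `GenotypePanel`.
#' @param K number of ancestral clusters (>= 1).
#' @param seed integer seed for initialization.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param maxIter iteration cap per restart.
#' @param nRestarts number of random restarts.
#' @return an [AdmixtureFit-class].
#' @export
admixtureEM <- function(panel, K, seed = 1L, tol = 1e-4, maxIter = 500L,
                        nRestarts = 3L) {
  stopifnot(K >= 1)
  G <- t(panel@dosage)  # samples x loci
  storage.mode(G) <- "double"
  I <- nrow(G); L <- ncol(G)
  pHat <- pmin(pmax(colMeans(G, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
  if (K == 1L) {
    Q <- matrix(1, I, 1, dimnames = list(rownames(G), NULL))
    F <- matrix(pmin(pmax(pHat, 1e-6), 1 - 1e-6), 1L, L)
    W <- !is.na(G)
    P <- matrix(F, I, L, byrow = TRUE)
    ll <- sum((G * log(P) + (2 - G) * log1p(-P))[W])
    return(new("AdmixtureFit", Q = Q, F = F, logLik = ll,
               converged = TRUE, nIterations = 0L))
  }
  W <- (!is.na(G)) + 0
  Gz <- G
  Gz[is.na(Gz)] <- 0
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(deriveSeed(seed, r))
    Q0 <- matrix(stats::rgamma(I * K, 1), I, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(rep(pHat, each = K), K, L) *
      matrix(stats::runif(K * L, 0.5, 1.5), K, L)
    F0 <- pmin(pmax(F0, 1e-6), 1 - 1e-6)
    fit <- .emFit(Gz, W, Q0, F0, as.integer(maxIter), tol)
    if (is.null(best) || max(fit$logLik) > max(best$logLik)) best <- fit
  }
  rownames(best$Q) <- rownames(G)
  new("AdmixtureFit", Q = best$Q, F = best$F, logLik = best$logLik,
      converged = best$converged, nIterations = as.integer(best$nIterations))
}

#' Choose K by cross-validated genotype masking
#'
#' For each fold, a fraction of the observed genotype entries is masked
#' (set missing), the admixture model is fitted on the rest, and the
#' masked entries are scored by squared error between the held-out
#' dosage `g` and its fitted expectation `2 p_il`. The chosen K
#' minimizes the mean CV error; ties go to the smaller K. This masking
#' criterion mirrors the cross-validation used in practice to pick the
#' number of clusters.
#'
#' @param panel a `GenotypePanel`.
#' @param kRange candidate K values (default 2:5).
#' @param nFolds folds (default 5).
#' @param maskFraction fraction of observed entries masked per fold.
#' @param seed integer seed (masking and EM initialization).
#' @param tol,maxIter,nRestarts EM settings per fold fit. The defaults
#'   are looser than [admixtureEM()]'s: held-out prediction error
#'   stabilizes long before the likelihood crawl ends, so CV fits stop
#'   once the per-iteration gain drops below a few log-likelihood units.
#' @return list `kRange`, `cvError` (mean per K), `chosenK`.
#' @export
selectK <- function(panel, kRange = 2:5, nFolds = 5L, maskFraction = 0.1,
                    seed = 1L, tol = 5, maxIter = 100L, nRestarts = 1L) {
  stopifnot(length(kRange) >= 1)
  G <- t(panel@dosage)
  storage.mode(G) <- "double"
  obs <- which(!is.na(G))
  set.seed(deriveSeed(seed, 7919L))
  folds <- lapply(seq_len(nFolds), function(f) {
    sample(obs, round(maskFraction * length(obs)))
  })
  cvError <- numeric(length(kRange))
  for (ki in seq_along(kRange)) {
    K <- kRange[ki]
    errs <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      Gm <- G
      Gm[folds[[f]]] <- NA_real_
      pm <- panel
      pm@dosage <- t(Gm)
      storage.mode(pm@dosage) <- "integer"
      fit <- admixtureEM(pm, K, seed = deriveSeed(seed, 100L * ki + f),
                         tol = tol, maxIter = maxIter,
                         nRestarts = nRestarts)
      P <- fit@Q %*% fit@F  # samples x loci expected allele frequency
      pred <- 2 * P[folds[[f]]]
      errs[f] <- mean((G[folds[[f]]] - pred)^2)
    }
    cvError[ki] <- mean(errs)
  }
  chosen <- kRange[which.min(cvError)]  # which.min takes the first minimum
  list(kRange = kRange, cvError = cvError, chosenK = chosen)
}

#' Assign population labels from ancestry fractions
#'
#' Label = argmax over clusters; individuals whose maximum ancestry
#' fraction falls below `admixtureThreshold` are flagged `admixed`.
#'
#' @param Q samples x K ancestry matrix (or an [AdmixtureFit-class]).
#' @param admixtureThreshold flagging threshold (default 0.8).
#' @param labels cluster labels (default `POP1..POPK`).
#' @return data.frame `sample_id`, `population`, `maxQ`, `admixed`.
#' @export
assignPopulations <- function(Q, admixtureThreshold = 0.8, labels = NULL) {
  if (is(Q, "AdmixtureFit")) Q <- Q@Q
  K <- ncol(Q)
  if (is.null(labels)) labels <- paste0("POP", seq_len(K))
  top <- max.col(Q, ties.method = "first")
  maxQ <- Q[cbind(seq_len(nrow(Q)), top)]
  data.frame(sample_id = if (!is.null(rownames(Q))) rownames(Q) else
               paste0("S", seq_len(nrow(Q))),
             population = labels[top],
             maxQ = maxQ,
             admixed = maxQ < admixtureThreshold,
             stringsAsFactors = FALSE)
}
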