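# Bayesian admixture clustering, model-choice diagnostics, run alignment,
# threshold assignment, and distance-based clustering (DA, NJ, PCoA).

# map genotype matrices to 1-based allele indices per locus (0 = missing)
.index_alleles <- function(gm) {
  n <- n_accessions(gm); L <- n_loci(gm)
  g1 <- matrix(0L, n, L); g2 <- matrix(0L, n, L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    ok <- !is.na(gm$a1[, l])
    av <- sort(unique(c(gm$a1[ok, l], gm$a2[ok, l])))
    n_alleles[l] <- max(length(av), 1L)
    g1[ok, l] <- match(gm$a1[ok, l], av)
    g2[ok, l] <- match(gm$a2[ok, l], av)
  }
  list(g1 = g1, g2 = g2, n_alleles = n_alleles)
}

#' Admixture-model Gibbs sampler
#'
#' Bayesian clustering under the independent-allele-frequency admixture
#' model: allele-copy origins, cluster allele frequencies
#' (Dirichlet(lambda)) and per-accession membership vectors Q
#' (Dirichlet(alpha)) are Gibbs-sampled; the admixture hyperparameter alpha
#' follows a Metropolis random walk with a uniform prior on (0, 10]. With
#' `loc_prior`, each sampling location carries its own alpha vector, a
#' location-informed prior that assists clustering of weakly structured
#' data. The model-evidence proxy is `mean(lnL) - var(lnL)/2` over
#' post-burn-in sweeps.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters.
#' @param burnin,iters burn-in and retained sweeps.
#' @param alpha initial admixture parameter.
#' @param loc_prior optional sampling-location labels (one per accession).
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @return A `run_result` list: `Q` (n x K membership matrix), `lnP`
#'   (evidence proxy), `lnL` trace, `alpha` trace, `freqs` (posterior-mean
#'   cluster allele frequencies), `K`.
#' @export
admixture_mcmc <- function(gm, K, burnin = 2000, iters = 2000, alpha = 1,
                           loc_prior = NULL, lambda = 1) {
  if (K < 1) stop("K must be >= 1")
  if (K > n_accessions(gm)) stop("K exceeds the number of accessions")
  if (burnin < 0 || iters <= 0) stop("non-positive iterations")
  ix <- .index_alleles(gm)
  locg <- if (is.null(loc_prior)) integer(0)
          else as.integer(factor(loc_prior)) - 1L
  res <- cpp_admixture(ix$g1, ix$g2, ix$n_alleles, as.integer(K),
                       as.integer(burnin), as.integer(iters),
                       alpha, 10, locg, lambda)
  lnL <- res$lnL
  lnP <- mean(lnL) - stats::var(lnL) / 2
  Q <- res$Q
  rownames(Q) <- rownames(gm$a1)
  structure(list(Q = Q, lnP = lnP, lnL = lnL, alpha = res$alpha,
                 freqs = res$P, K = K), class = "run_result")
}

#' Run the admixture sampler over a K range
#'
#' @param gm a [genotype_matrix()].
#' @param K_range integer vector of K values (default 1--12, the
#'   conventional production scan; use a narrow range for quick looks).
#' @param n_runs independent runs per K (default 20; Evanno's delta K
#'   needs at least 2).
#' @param ... passed to [admixture_mcmc()].
#' @return A list with `lnP` (data frame `K`, `run`, `lnP`) and `runs`
#'   (nested list of `run_result`s indexed `[[as.character(K)]][[run]]`).
#' @export
admixture_scan <- function(gm, K_range = 1:12, n_runs = 20, ...) {
  rows <- list(); runs <- list()
  for (K in K_range) {
    runs[[as.character(K)]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      rr <- admixture_mcmc(gm, K, ...)
      runs[[as.character(K)]][[r]] <- rr
      rows[[length(rows) + 1]] <- data.frame(K = K, run = r, lnP = rr$lnP)
    }
  }
  list(lnP = do.call(rbind, rows), runs = runs)
}

#' Evanno delta-K table
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined for interior K with positive run-to-run standard deviation.
#'
#' @param lnp data frame with columns `K`, `run`, `lnP` (>= 3 consecutive
#'   K values, >= 2 runs each).
#' @return A `delta_k_table` data frame (`K`, `mean_lnP`, `sd_lnP`,
#'   `deltaK`) with the argmax K in `attr(, "best_K")`.
#' @export
evanno <- function(lnp) {
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  m <- tapply(lnp$lnP, lnp$K, mean)[as.character(ks)]
  s <- tapply(lnp$lnP, lnp$K, stats::sd)[as.character(ks)]
  if (any(tapply(lnp$lnP, lnp$K, length) < 2)) stop("need >= 2 runs per K")
  dk <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1)) {
    if (!is.na(s[i]) && s[i] > 0)
      dk[i] <- abs(m[i + 1] - 2 * m[i] + m[i - 1]) / s[i]
  }
  out <- data.frame(K = ks, mean_lnP = as.numeric(m), sd_lnP = as.numeric(s),
                    deltaK = dk)
  attr(out, "best_K") <- if (all(is.na(dk))) NA_integer_
                         else ks[which.max(dk)]
  class(out) <- c("delta_k_table", "data.frame")
  out
}

.perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# similarity of two aligned Q matrices: 1 - normalised L1 distance
.q_similarity <- function(Qa, Qb) 1 - sum(abs(Qa - Qb)) / (2 * nrow(Qa))

# best column permutation of Q against consensus C
.align_one <- function(Q, C) {
  K <- ncol(Q)
  if (K <= 6) {
    pm <- .perms(K)
    best <- -Inf; bp <- seq_len(K)
    for (r in seq_len(nrow(pm))) {
      s <- .q_similarity(Q[, pm[r, ], drop = FALSE], C)
      if (s > best) { best <- s; bp <- pm[r, ] }
    }
    list(perm = bp, sim = best)
  } else {
    # greedy column matching on correlation-like agreement
    agree <- crossprod(as.matrix(C), as.matrix(Q))  # C cols x Q cols
    perm <- integer(K)
    used <- rep(FALSE, K)
    for (ci in order(-apply(agree, 1, max))) {
      qi <- which.max(ifelse(used, -Inf, agree[ci, ]))
      perm[ci] <- qi; used[qi] <- TRUE
    }
    Qp <- Q[, perm, drop = FALSE]
    list(perm = perm, sim = .q_similarity(Qp, C))
  }
}

#' Align admixture runs and detect modes
#'
#' Cluster labels are permuted per run to maximise agreement with the
#' incumbent consensus (exhaustive over the K! permutations for K <= 6,
#' greedy matching above). Runs whose aligned similarity to the consensus
#' falls below 0.9 form separate modes; the consensus is the mean Q of the
#' largest mode.
#'
#' @param runs list of Q matrices (same K, same accession order), or of
#'   `run_result`s.
#' @param min_similarity similarity threshold separating modes.
#' @return A list with `consensus` (mean Q of the major mode), `modes`
#'   (mode id per run), `similarity` (per run, to the major-mode
#'   consensus), `aligned` (list of permuted Q matrices).
#' @export
align_runs <- function(runs, min_similarity = 0.9) {
  Qs <- lapply(runs, function(r) if (inherits(r, "run_result")) r$Q else as.matrix(r))
  K <- unique(vapply(Qs, ncol, integer(1)))
  if (length(K) != 1) stop("mixed K among runs")
  n <- unique(vapply(Qs, nrow, integer(1)))
  if (length(n) != 1) stop("runs disagree on accession count")
  C <- Qs[[1]]
  aligned <- vector("list", length(Qs))
  sims <- numeric(length(Qs))
  for (i in seq_along(Qs)) {
    al <- .align_one(Qs[[i]], C)
    aligned[[i]] <- Qs[[i]][, al$perm, drop = FALSE]
    sims[i] <- al$sim
  }
  modes <- integer(length(Qs))
  reps <- list()
  for (i in seq_along(aligned)) {
    placed <- FALSE
    for (mid in seq_along(reps)) {
      al <- .align_one(aligned[[i]], reps[[mid]])
      if (al$sim >= min_similarity) {
        aligned[[i]] <- aligned[[i]][, al$perm, drop = FALSE]
        modes[i] <- mid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1]] <- aligned[[i]]
      modes[i] <- length(reps)
    }
  }
  major <- as.integer(names(which.max(table(modes))))
  members <- which(modes == major)
  consensus <- Reduce(`+`, aligned[members]) / length(members)
  sims <- vapply(aligned, .q_similarity, numeric(1), Qb = consensus)
  list(consensus = consensus, modes = modes, similarity = sims,
       aligned = aligned)
}

#' Threshold assignment from membership coefficients
#'
#' An accession joins its argmax cluster when its largest membership
#' coefficient reaches the threshold (inclusive); otherwise it is
#' `"admixed"` (intermediate Q).
#'
#' @param Q membership matrix (rows sum to 1) or a `run_result`.
#' @param threshold assignment threshold in (0.5, 1]; default 0.800.
#' @return A character vector `cluster_1..cluster_K` / `"admixed"`, named
#'   by accession where Q has rownames.
#' @export
assign_clusters <- function(Q, threshold = 0.800) {
  if (inherits(Q, "run_result")) Q <- Q$Q
  stopifnot(threshold > 0.5, threshold <= 1)
  Q <- as.matrix(Q)
  top <- max.col(Q, ties.method = "first")
  lab <- ifelse(Q[cbind(seq_len(nrow(Q)), top)] >= threshold,
                paste0("cluster_", top), "admixed")
  stats::setNames(lab, rownames(Q))
}

#' Nei's DA distance between groups
#'
#' `DA = 1 - (1/L) sum_loci sum_alleles sqrt(x_i y_i)` (one minus the mean
#' Bhattacharyya affinity across loci shared by both groups).
#'
#' @param freqs an [allele_frequencies()] table.
#' @return A symmetric matrix of pairwise DA distances between groups.
#' @export
da_distance <- function(freqs) {
  cnts <- attr(freqs, "counts")
  N <- attr(freqs, "N")
  glev <- attr(freqs, "groups")
  D <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  for (a in seq_along(glev)) {
    for (b in seq_along(glev)) {
      if (b <= a) next
      shared <- which(N[, a] > 0 & N[, b] > 0)
      if (!length(shared)) stop("groups '", glev[a], "' and '", glev[b],
                                "' share no scored locus")
      aff <- vapply(shared, function(l) {
        cm <- cnts[[l]]
        sum(sqrt((cm[, a] / N[l, a]) * (cm[, b] / N[l, b])))
      }, numeric(1))
      D[a, b] <- D[b, a] <- 1 - mean(aff)
    }
  }
  D
}

#' Neighbour-joining tree rooted on an outgroup
#'
#' Saitou-Nei agglomeration with the rate-corrected Q criterion, ties
#' broken by the smallest index pair; negative branch lengths are clamped
#' to zero with the deficit moved to the sister edge. The tree is rooted at
#' the midpoint of the outgroup's pendant edge.
#'
#' @param dist symmetric zero-diagonal distance matrix with labels.
#' @param outgroup label to root on (optional; unrooted tree otherwise).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dist, outgroup = NULL) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!is.null(outgroup) && !outgroup %in% labels)
    stop("outgroup not among the taxa")
  # clusters carried as newick substrings; branch lengths assigned on join
  clades <- labels
  Dm <- D
  while (length(clades) > 2) {
    m <- length(clades)
    r <- rowSums(Dm)
    Qc <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Qc) <- Inf
    ij <- which(Qc == min(Qc), arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- ij[1]; j <- ij[2]
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    # clamp negatives, moving the deficit to the sister edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", clades[i], vi, clades[j], vj)
    dnew <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    keep <- setdiff(seq_len(m + 1), c(i, j))
    Dm <- Dm[keep, keep, drop = FALSE]
    clades <- c(clades, merged)[keep]
  }
  nwk <- sprintf("(%s:%.10g,%s:0);", clades[1], max(Dm[1, 2], 0), clades[2])
  tr <- ape::read.tree(text = nwk)
  if (!is.null(outgroup)) {
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    # root at the midpoint of the outgroup's pendant edge
    og <- which(tr$tip.label == outgroup)
    e_og <- which(tr$edge[, 2] == og)
    root_node <- ape::Ntip(tr) + 1L
    kids <- tr$edge[, 1] == root_node
    if (tr$edge[e_og, 1] == root_node) {
      half <- tr$edge.length[e_og] / 2
      other <- which(kids)[which(kids) != e_og]
      tr$edge.length[e_og] <- half
      tr$edge.length[other] <- tr$edge.length[other] + half
    }
  }
  tr
}

# GenAlEx-style squared individual genetic distance for codominant data:
# per locus 0 (identical genotypes), 1 (one shared allele or ii vs ij),
# 2 (ij vs kl), 3 (ii vs jk), 4 (ii vs jj); summed over scored loci.
.indiv_dist <- function(gm) {
  n <- n_accessions(gm); L <- n_loci(gm)
  D <- matrix(0, n, n, dimnames = list(rownames(gm$a1), rownames(gm$a1)))
  for (i in seq_len(n - 1)) {
    ai <- gm$a1[i, ]; bi <- gm$a2[i, ]
    hi <- ai != bi
    for (j in (i + 1):n) {
      aj <- gm$a1[j, ]; bj <- gm$a2[j, ]
      ok <- !is.na(ai) & !is.na(aj)
      if (!any(ok)) next
      # multiset intersection of two allele pairs = best of the 2 matchings
      s <- pmax((ai == aj) + (bi == bj), (ai == bj) + (bi == aj))[ok]
      hx <- hi[ok]; hy <- (aj != bj)[ok]
      d <- ifelse(s == 2, 0,
           ifelse(s == 1, 1,
           ifelse(hx & hy, 2, ifelse(hx | hy, 3, 4))))
      D[i, j] <- D[j, i] <- sum(d)
    }
  }
  D
}

#' Principal coordinate analysis of individual genotypes
#'
#' Squared inter-accession genetic distances (codominant
#' genotype-mismatch distance) are double-centred and
#' eigen-decomposed (classical MDS / covariance-standardised PCoA).
#'
#' @param gm a [genotype_matrix()] (>= 3 accessions).
#' @param k number of axes to return.
#' @return A list with `coordinates` (n x k), `eigenvalues` and
#'   `percent_variance` (share of the positive eigenvalues).
#' @export
pcoa_genotypes <- function(gm, k = 3) {
  if (n_accessions(gm) < 3) stop("need at least 3 accessions")
  D2 <- .indiv_dist(gm)
  if (all(D2 == 0)) stop("all genotypes identical: rank-0 configuration")
  mds <- stats::cmdscale(sqrt(D2), k = min(k, nrow(D2) - 1), eig = TRUE)
  pos <- mds$eig[mds$eig > 1e-12]
  pct <- 100 * mds$eig / sum(pos)
  list(coordinates = mds$points, eigenvalues = mds$eig,
       percent_variance = pct[seq_len(ncol(mds$points))])
}
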