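# Per-group diversity statistics, rarefaction, permutation tests,
# relatedness and group comparisons.

# internal: per-locus allele-count matrices (alleles x groups) plus a
# gene-copy count matrix (loci x groups). Only complete diploid calls
# contribute (missing cells are excluded locus-wise, never imputed).
.freq_counts <- function(gm, groups) {
  groups <- as.character(groups)
  glev <- unique(groups)
  L <- n_loci(gm)
  counts <- vector("list", L)
  N <- matrix(0L, L, length(glev), dimnames = list(gm$loci$name, glev))
  gidx <- match(groups, glev)
  for (l in seq_len(L)) {
    x1 <- gm$a1[, l]; x2 <- gm$a2[, l]
    ok <- !is.na(x1)
    av <- sort(unique(c(x1[ok], x2[ok])))
    cm <- matrix(0L, length(av), length(glev), dimnames = list(av, glev))
    f1 <- match(x1, av); f2 <- match(x2, av)
    for (g in seq_along(glev)) {
      sel <- ok & gidx == g
      if (any(sel)) {
        cm[, g] <- tabulate(c(f1[sel], f2[sel]), length(av))
        N[l, g] <- 2L * sum(sel)
      }
    }
    counts[[l]] <- cm
  }
  list(counts = counts, N = N, groups = glev, loci = gm$loci$name)
}

#' Allele frequency table
#'
#' Counts of gene copies per group, locus and allele; missing cells are
#' skipped (a genotype contributes only when both alleles are scored).
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping passed to [group_labels()].
#' @return A `freq_table` object: a long data frame (`group`, `locus`,
#'   `allele`, `count`, `freq`) with the gene-copy matrix in
#'   `attr(, "N")` and the internal per-locus count matrices in
#'   `attr(, "counts")`.
#' @export
allele_frequencies <- function(gm, by = "population") {
  groups <- group_labels(gm, by)
  if (any(table(groups) == 0)) stop("empty group")
  fc <- .freq_counts(gm, groups)
  rows <- list()
  for (l in seq_along(fc$counts)) {
    cm <- fc$counts[[l]]
    for (g in fc$groups) {
      cnt <- cm[, g]
      keep <- cnt > 0
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- data.frame(
        group = g, locus = fc$loci[l],
        allele = as.numeric(rownames(cm))[keep], count = cnt[keep],
        freq = cnt[keep] / fc$N[l, g], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "N") <- fc$N
  attr(out, "counts") <- fc$counts
  attr(out, "groups") <- fc$groups
  class(out) <- c("freq_table", "data.frame")
  out
}

# unbiased gene diversity from a count vector
.hs_unbiased <- function(cnt) {
  n <- sum(cnt)
  if (n < 2) return(NA_real_)
  p <- cnt / n
  (n / (n - 1)) * (1 - sum(p^2))
}

.pic <- function(cnt) {
  n <- sum(cnt)
  if (n < 1) return(NA_real_)
  p <- cnt / n
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))  # 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2
}

#' Per-group diversity statistics
#'
#' For each group: mean number of alleles per locus (A), unbiased gene
#' diversity `Hs = (N/(N-1)) (1 - sum p_i^2)`, observed heterozygosity Ho
#' (fraction of complete diploid calls that are heterozygous), polymorphism
#' information content PIC, and the inbreeding coefficient
#' `Fis = 1 - Ho/Hs` (NA at monomorphic loci). Group values are unweighted
#' means across loci.
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping passed to [group_labels()].
#' @return A data frame, one row per group, with columns `group`, `n`, `A`,
#'   `Hs`, `Ho`, `PIC`, `Fis`; per-locus detail in `attr(, "per_locus")`.
#' @export
diversity_stats <- function(gm, by = "population") {
  groups <- group_labels(gm, by)
  fc <- .freq_counts(gm, groups)
  glev <- fc$groups
  L <- length(fc$counts)
  per <- list()
  out <- data.frame(group = glev, n = as.integer(table(factor(groups, glev))),
                    A = NA_real_, Hs = NA_real_, Ho = NA_real_,
                    PIC = NA_real_, Fis = NA_real_, stringsAsFactors = FALSE)
  for (gi in seq_along(glev)) {
    g <- glev[gi]
    sel <- groups == g
    A <- Hs <- Ho <- PIC <- Fis <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      cnt <- fc$counts[[l]][, g]
      if (fc$N[l, g] < 2) next
      A[l] <- sum(cnt > 0)
      Hs[l] <- .hs_unbiased(cnt)
      PIC[l] <- .pic(cnt)
      x1 <- gm$a1[sel, l]; x2 <- gm$a2[sel, l]
      ok <- !is.na(x1)
      Ho[l] <- if (any(ok)) mean(x1[ok] != x2[ok]) else NA_real_
      Fis[l] <- if (!is.na(Hs[l]) && Hs[l] > 0) 1 - Ho[l] / Hs[l] else NA_real_
    }
    if (all(is.na(Hs))) stop("group '", g, "' has < 2 gene copies at every locus")
    per[[g]] <- data.frame(locus = fc$loci, A = A, Hs = Hs, Ho = Ho,
                           PIC = PIC, Fis = Fis, stringsAsFactors = FALSE)
    out$A[gi] <- mean(A, na.rm = TRUE)
    out$Hs[gi] <- mean(Hs, na.rm = TRUE)
    out$Ho[gi] <- mean(Ho, na.rm = TRUE)
    out$PIC[gi] <- mean(PIC, na.rm = TRUE)
    out$Fis[gi] <- if (all(is.na(Fis))) NA_real_ else mean(Fis, na.rm = TRUE)
  }
  attr(out, "per_locus") <- per
  out
}

# rarefied expected allele count for one locus's count vector at depth g
.ar_locus <- function(cnt, g) {
  N <- sum(cnt)
  if (N < g) return(NA_real_)
  # 1 - C(N - N_i, g)/C(N, g) summed over alleles, via lchoose for stability
  pr <- ifelse(N - cnt >= g, exp(lchoose(N - cnt, g) - lchoose(N, g)), 0)
  sum(1 - pr)
}

#' Rarefied allelic richness and private allele richness
#'
#' Standardises allele counts to a common sample of `g` gene copies by
#' hypergeometric rarefaction. `Ar` is the expected number of distinct
#' alleles in a subsample of `g` copies; `Ap` is the expected number of
#' alleles present in the focal group's subsample and absent from every
#' other group's subsample. Loci where any group has fewer than `g` copies
#' are dropped with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping passed to [group_labels()].
#' @param g rarefaction depth in gene copies (`g >= 1`); default 2, at which
#'   `Ar = 1 + Hs` (unbiased) exactly.
#' @return A data frame with columns `group`, `Ar`, `Ap`.
#' @export
rarefied_richness <- function(gm, by = "population", g = 2) {
  if (g < 1) stop("g must be >= 1")
  groups <- group_labels(gm, by)
  fc <- .freq_counts(gm, groups)
  glev <- fc$groups
  usable <- which(apply(fc$N, 1, function(x) all(x >= g)))
  if (length(usable) < length(fc$counts))
    warning(length(fc$counts) - length(usable),
            " locus/loci dropped: fewer than g copies in some group")
  if (!length(usable)) stop("no locus has >= g copies in every group")
  Ar <- Ap <- matrix(NA_real_, length(usable), length(glev),
                     dimnames = list(NULL, glev))
  for (i in seq_along(usable)) {
    l <- usable[i]
    cm <- fc$counts[[l]]
    # Q[i, k]: probability allele i shows up in group k's subsample
    Q <- matrix(0, nrow(cm), length(glev))
    for (k in seq_along(glev)) {
      Nk <- sum(cm[, k])
      Q[, k] <- 1 - ifelse(Nk - cm[, k] >= g,
                           exp(lchoose(Nk - cm[, k], g) - lchoose(Nk, g)), 0)
    }
    for (k in seq_along(glev)) {
      Ar[i, k] <- sum(Q[, k])
      others <- Q[, -k, drop = FALSE]
      Ap[i, k] <- sum(Q[, k] * apply(1 - others, 1, prod))
    }
  }
  data.frame(group = glev, Ar = colMeans(Ar), Ap = colMeans(Ap),
             row.names = NULL, stringsAsFactors = FALSE)
}

# multi-locus mean Fis for one group's two allele matrices
.fis_obs <- function(x1, x2) {
  L <- ncol(x1)
  fis <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    ok <- !is.na(x1[, l])
    if (sum(ok) < 2) next
    cnt <- table(c(x1[ok, l], x2[ok, l]))
    hs <- .hs_unbiased(as.numeric(cnt))
    if (is.na(hs) || hs == 0) next
    fis[l] <- 1 - mean(x1[ok, l] != x2[ok, l]) / hs
  }
  if (all(is.na(fis))) NA_real_ else mean(fis, na.rm = TRUE)
}

#' Permutation test for the inbreeding coefficient
#'
#' Alleles are permuted among individuals within the group, per locus
#' (randomised union of gametes), and the multi-locus mean Fis recomputed.
#' Two-sided p-value with +1 smoothing.
#'
#' @param gm a [genotype_matrix()].
#' @param group accession selector: a logical/index vector, or a group label
#'   combined with `by`.
#' @param by grouping used when `group` is a label.
#' @param n_perm number of permutations (>= 99).
#' @return A list with `fis`, `p_value`, `n_perm`.
#' @export
fis_permutation_test <- function(gm, group = NULL, by = "population",
                                 n_perm = 999) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  sel <- if (is.null(group)) rep(TRUE, n_accessions(gm))
         else if (is.character(group) && length(group) == 1)
           group_labels(gm, by) == group
         else group
  x1 <- gm$a1[sel, , drop = FALSE]; x2 <- gm$a2[sel, , drop = FALSE]
  obs <- .fis_obs(x1, x2)
  if (is.na(obs)) stop("monomorphic group: Fis undefined")
  L <- ncol(x1)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p1 <- x1; p2 <- x2
    for (l in seq_len(L)) {
      ok <- which(!is.na(x1[, l]))
      if (length(ok) < 2) next
      al <- sample(c(x1[ok, l], x2[ok, l]))
      p1[ok, l] <- al[seq_along(ok)]
      p2[ok, l] <- al[length(ok) + seq_along(ok)]
    }
    if (abs(.fis_obs(p1, p2)) >= abs(obs)) hits <- hits + 1L
  }
  list(fis = obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

# G statistic (log-likelihood ratio) on a two-locus genotype table
.g_stat <- function(ga, gb) {
  tb <- table(ga, gb)
  E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  idx <- tb > 0
  2 * sum(tb[idx] * log(tb[idx] / E[idx]))
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Within each group, the G (log-likelihood-ratio) statistic on the
#' two-locus genotype contingency table is compared to its permutation null
#' (one locus's genotypes shuffled among individuals). Group p-values are
#' combined over groups by Fisher's method.
#'
#' @param gm a [genotype_matrix()].
#' @param locus_a,locus_b locus names or indices.
#' @param by grouping passed to [group_labels()].
#' @param n_perm permutations per group.
#' @return A list with `per_group` (data frame `group`, `G`, `p`) and the
#'   Fisher-combined `p_value`.
#' @export
ld_test <- function(gm, locus_a, locus_b, by = "population", n_perm = 199) {
  la <- if (is.character(locus_a)) match(locus_a, gm$loci$name) else locus_a
  lb <- if (is.character(locus_b)) match(locus_b, gm$loci$name) else locus_b
  groups <- group_labels(gm, by)
  res <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    ok <- sel & !is.na(gm$a1[, la]) & !is.na(gm$a1[, lb])
    if (sum(ok) < 5) stop("fewer than 5 complete two-locus observations in group ", g)
    ga <- paste(pmin(gm$a1[ok, la], gm$a2[ok, la]),
                pmax(gm$a1[ok, la], gm$a2[ok, la]))
    gb <- paste(pmin(gm$a1[ok, lb], gm$a2[ok, lb]),
                pmax(gm$a1[ok, lb], gm$a2[ok, lb]))
    if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
      stop("monomorphic locus in group ", g)
    obs <- .g_stat(ga, gb)
    hits <- 0L
    for (b in seq_len(n_perm)) if (.g_stat(ga, sample(gb)) >= obs) hits <- hits + 1L
    res[[g]] <- data.frame(group = g, G = obs, p = (hits + 1) / (n_perm + 1),
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, res)
  rownames(per) <- NULL
  chi <- -2 * sum(log(per$p))
  list(per_group = per,
       p_value = stats::pchisq(chi, df = 2 * nrow(per), lower.tail = FALSE))
}

#' Pairwise relatedness by moment estimators
#'
#' Queller & Goodnight (1989, default) or Lynch & Ritland (1999) pairwise
#' relatedness, with reference allele frequencies taken from the full
#' matrix. Multi-locus estimates combine loci by the estimator's own
#' weights (summed numerators/denominators), averaged over the two
#' reference orderings of each pair.
#'
#' @param gm a [genotype_matrix()].
#' @param estimator `"queller_goodnight"` or `"lynch_ritland"`.
#' @return A symmetric `n x n` matrix of class `relatedness_matrix` with
#'   `NA` diagonal; pairs sharing no scored loci are `NA`.
#' @export
relatedness <- function(gm, estimator = c("queller_goodnight", "lynch_ritland")) {
  estimator <- match.arg(estimator)
  n <- n_accessions(gm); L <- n_loci(gm)
  freqs <- vector("list", L)
  for (l in seq_len(L)) {
    ok <- !is.na(gm$a1[, l])
    tb <- table(c(gm$a1[ok, l], gm$a2[ok, l]))
    freqs[[l]] <- stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  }
  rm <- matrix(NA_real_, n, n, dimnames = list(rownames(gm$a1), rownames(gm$a1)))
  pf <- function(l, a) freqs[[l]][as.character(a)]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num_xy <- den_xy <- num_yx <- den_yx <- 0
      wr_sum <- r_sum <- 0
      any_locus <- FALSE
      for (l in seq_len(L)) {
        a <- gm$a1[i, l]; b <- gm$a2[i, l]
        c_ <- gm$a1[j, l]; d <- gm$a2[j, l]
        if (is.na(a) || is.na(c_)) next
        any_locus <- TRUE
        pa <- pf(l, a); pb <- pf(l, b); pc <- pf(l, c_); pd <- pf(l, d)
        if (estimator == "queller_goodnight") {
          sxy <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
          num_xy <- num_xy + sxy - pa - pb
          den_xy <- den_xy + 1 + (a == b) - pa - pb
          num_yx <- num_yx + sxy - pc - pd
          den_yx <- den_yx + 1 + (c_ == d) - pc - pd
        } else {
          # Lynch & Ritland (1999), x as reference, then symmetrised
          lr_one <- function(a, b, c_, d, pa, pb) {
            Sac <- a == c_; Sad <- a == d; Sbc <- b == c_; Sbd <- b == d
            den <- (1 + (a == b)) * (pa + pb) - 4 * pa * pb
            if (den == 0) return(NULL)
            num <- pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb
            w <- ((1 + (a == b)) * (pa + pb) - 4 * pa * pb) / (2 * pa * pb)
            list(r = num / den, w = w)
          }
          r1 <- lr_one(a, b, c_, d, pa, pb)
          r2 <- lr_one(c_, d, a, b, pc, pd)
          for (r in list(r1, r2)) {
            if (!is.null(r)) { r_sum <- r_sum + r$w * r$r; wr_sum <- wr_sum + r$w }
          }
        }
      }
      if (!any_locus) next
      val <- if (estimator == "queller_goodnight") {
        rxy <- if (den_xy != 0) num_xy / den_xy else NA_real_
        ryx <- if (den_yx != 0) num_yx / den_yx else NA_real_
        mean(c(rxy, ryx), na.rm = TRUE)
      } else {
        if (wr_sum != 0) r_sum / wr_sum else NA_real_
      }
      rm[i, j] <- rm[j, i] <- val
    }
  }
  class(rm) <- c("relatedness_matrix", "matrix")
  rm
}

#' Prune accessions by pairwise relatedness
#'
#' Reports the percentage of pairs above the threshold and greedily removes
#' the accession participating in the most over-threshold pairs (ties:
#' lexicographically first id removed) until none remain.
#'
#' @param rm a [relatedness()] matrix.
#' @param threshold relatedness cut-off in (0, 1); pairs strictly above it
#'   count as related.
#' @return A list with `kept` (accession ids), `n_pairs_over` and
#'   `percent_over` (= 100 * n_pairs_over / C(n,2), 3 d.p. scale).
#' @export
prune_related <- function(rm, threshold = 0.500) {
  stopifnot(threshold > 0, threshold < 1)
  n <- nrow(rm)
  if (n < 2) stop("need at least 2 accessions")
  over <- !is.na(rm) & rm > threshold
  diag(over) <- FALSE
  n_over <- sum(over[upper.tri(over)])
  pct <- 100 * n_over / choose(n, 2)
  keep <- rownames(rm)
  ov <- over
  while (TRUE) {
    deg <- rowSums(ov)
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    drop <- worst[order(rownames(ov)[worst])][1]
    keep <- setdiff(keep, rownames(ov)[drop])
    ov <- ov[-drop, -drop, drop = FALSE]
  }
  list(kept = keep, n_pairs_over = n_over, percent_over = pct)
}

# Dunn pairwise z tests on ranks with tie correction
.dunn <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  glev <- unique(groups)
  mr <- tapply(r, groups, mean)[glev]
  ng <- tapply(r, groups, length)[glev]
  pairs <- utils::combn(glev, 2)
  p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- (mr[[a]] - mr[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z))
  }
  data.frame(a = pairs[1, ], b = pairs[2, ],
             p_adj = pmin(1, p * ncol(pairs)), stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with a compact letter display
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]) across
#' groups of per-locus statistics, followed by pairwise Dunn z tests with
#' Bonferroni correction. Groups sharing no letter differ at corrected
#' alpha = 0.05. Letters are built by a greedy sweep over groups sorted by
#' median: each maximal run of mutually non-different groups receives one
#' letter.
#'
#' @param values numeric vector of per-locus statistic values.
#' @param groups group label per value (>= 2 groups, >= 2 values each).
#' @param alpha significance level for the letter display.
#' @return A list with `H`, `p_value`, `letters` (named character vector)
#'   and the `pairwise` Dunn table.
#' @export
kw_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  glev <- unique(groups)
  if (length(glev) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 values per group")
  kt <- stats::kruskal.test(values, factor(groups))
  dn <- .dunn(values, groups)
  med <- sort(tapply(values, groups, stats::median))
  ord <- names(med)
  differs <- function(a, b) {
    row <- dn[(dn$a == a & dn$b == b) | (dn$a == b & dn$b == a), ]
    nrow(row) > 0 && row$p_adj[1] < alpha
  }
  m <- length(ord)
  # reach[i]: largest j such that no pair within ord[i..j] differs
  reach <- integer(m)
  for (i in seq_len(m)) {
    j <- i
    while (j < m &&
           !any(vapply(i:j, function(k) differs(ord[k], ord[j + 1]),
                       logical(1)))) j <- j + 1
    reach[i] <- j
  }
  letters_out <- stats::setNames(rep("", m), ord)
  lab <- 0
  for (i in seq_len(m)) {
    if (i > 1 && reach[i] <= reach[i - 1]) next  # nested interval
    lab <- lab + 1
    for (k in i:reach[i])
      letters_out[k] <- paste0(letters_out[k], letters[lab])
  }
  list(H = unname(kt$statistic), p_value = kt$p.value,
       letters = letters_out, pairwise = dn)
}
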