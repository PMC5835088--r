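# Quantitative-trait differentiation (QST), Weir-Cockerham FST with
# bootstrap CIs, an FST-outlier screen, and the selection verdict.

#' One-way variance components for a quantitative trait
#'
#' Random-effects decomposition from the one-way ANOVA expected mean
#' squares: `V_among = max(0, (MS_among - MS_within)/n0)` with
#' `n0 = (N - sum n_i^2 / N) / (a - 1)`, and `V_within = MS_within`.
#' Groups with a single accession are dropped with a warning.
#'
#' @param traits data frame with a `group` column and trait columns
#'   (see [simulate_traits()]).
#' @param trait name of the trait column.
#' @return A `variance_components` list: `MS_among`, `MS_within`, `n0`,
#'   `V_among`, `V_within`, `groups`, `n`.
#' @export
variance_components <- function(traits, trait) {
  x <- traits[[trait]]
  g <- as.character(traits$group)
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  sizes <- table(g)
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    warning("dropping group(s) with one accession: ",
            paste(singles, collapse = ", "))
    keep <- !g %in% singles
    x <- x[keep]; g <- g[keep]
    sizes <- table(g)
  }
  a <- length(sizes)
  if (a < 2) stop("need >= 2 usable groups")
  N <- length(x)
  gm_ <- tapply(x, g, mean)
  ss_among <- sum(sizes * (gm_[names(sizes)] - mean(x))^2)
  ss_within <- sum((x - gm_[g])^2)
  MSa <- ss_among / (a - 1)
  MSw <- ss_within / (N - a)
  n0 <- (N - sum(sizes^2) / N) / (a - 1)
  structure(list(MS_among = MSa, MS_within = MSw, n0 = n0,
                 V_among = max(0, (MSa - MSw) / n0), V_within = MSw,
                 groups = a, n = N), class = "variance_components")
}

#' Quantitative-trait differentiation
#'
#' `QST = V_among / (V_among + 2 V_within)` with V_among the genetic
#' variance among populations and V_within the genetic variance within
#' populations.
#'
#' @param vc a [variance_components()] result (or a list with `V_among`,
#'   `V_within`).
#' @return QST in \[0, 1\]; `NA` when both components are zero.
#' @export
qst <- function(vc) {
  va <- vc$V_among; vw <- vc$V_within
  if (va + 2 * vw == 0) return(NA_real_)
  va / (va + 2 * vw)
}

# Weir & Cockerham (1984) per-allele variance components for one locus.
# Returns the summed a, b, c over alleles.
.wc_locus <- function(a1, a2, groups) {
  ok <- !is.na(a1)
  if (sum(ok) == 0) return(c(a = 0, b = 0, c = 0))
  groups <- groups[ok]; a1 <- a1[ok]; a2 <- a2[ok]
  glev <- unique(groups)
  gi <- match(groups, glev)
  n_i <- tabulate(gi, length(glev))
  use <- n_i > 0
  if (sum(use) < 2) return(c(a = 0, b = 0, c = 0))
  glev <- glev[use]; n_i <- n_i[use]
  gi <- match(groups, glev)
  r <- length(glev)
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(c(a = 0, b = 0, c = 0))
  alleles <- unique(c(a1, a2))
  na <- length(alleles)
  if (na < 2) return(c(a = 0, b = 0, c = 0))
  f1 <- match(a1, alleles); f2 <- match(a2, alleles)
  # allele copy counts and per-allele heterozygote counts, per group
  cnt <- matrix(0, na, r)
  hetc <- matrix(0, na, r)
  het <- f1 != f2
  for (k in seq_len(r)) {
    sel <- gi == k
    cnt[, k] <- tabulate(c(f1[sel], f2[sel]), na)
    hh <- sel & het
    hetc[, k] <- tabulate(c(f1[hh], f2[hh]), na)
  }
  p_i <- cnt * rep(1 / (2 * n_i), each = na)   # na x r allele frequencies
  h_i <- hetc * rep(1 / n_i, each = na)        # na x r het frequencies
  pbar <- as.numeric(p_i %*% n_i) / (r * nbar)
  s2 <- as.numeric((p_i - pbar)^2 %*% n_i) / ((r - 1) * nbar)
  hbar <- as.numeric(h_i %*% n_i) / (r * nbar)
  A <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  B <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  C <- hbar / 2
  c(a = sum(A), b = sum(B), c = sum(C))
}

#' Weir-Cockerham multi-locus theta with a bootstrap CI
#'
#' Variance components a (among populations), b (among individuals within
#' populations) and c (within individuals) are accumulated per allele and
#' locus; the multi-locus estimate is `theta = sum a / sum(a + b + c)`.
#' The CI is the 2.5/97.5 percentile of theta over loci resampled with
#' replacement.
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping passed to [group_labels()].
#' @param n_boot bootstrap replicates over loci (0 skips the CI).
#' @return A list with `theta`, `ci` (length-2 vector), `per_locus`
#'   (data frame of per-locus components and theta).
#' @export
wc_fst <- function(gm, by = "population", n_boot = 10000) {
  groups <- group_labels(gm, by)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  L <- n_loci(gm)
  comp <- t(vapply(seq_len(L), function(l)
    .wc_locus(gm$a1[, l], gm$a2[, l], groups), numeric(3)))
  tot <- rowSums(comp)
  denom <- sum(tot)
  if (denom == 0) stop("monomorphic dataset: theta undefined")
  theta <- sum(comp[, 1]) / denom
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && L >= 2) {
    bt <- replicate(n_boot, {
      idx <- sample.int(L, L, replace = TRUE)
      s <- colSums(comp[idx, , drop = FALSE])
      if (sum(s) == 0) NA_real_ else s[1] / sum(s)
    })
    ci <- stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(theta = theta, ci = ci,
       per_locus = data.frame(locus = gm$loci$name, a = comp[, 1],
                              b = comp[, 2], c = comp[, 3],
                              theta = ifelse(tot > 0, comp[, 1] / tot, NA),
                              stringsAsFactors = FALSE))
}

#' FST-outlier screen (FDIST-style)
#'
#' Neutral island-model simulations are tuned so the mean simulated theta
#' matches the observed trimmed-mean per-locus theta; observed loci are
#' compared, conditional on expected-heterozygosity bins, to the simulated
#' 0.025-0.975 theta envelope and flagged outside it.
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping passed to [group_labels()].
#' @param n_sims neutral single-locus simulations (>= 1000 for production;
#'   any positive value for exploration).
#' @param n_bins heterozygosity bins for the envelope.
#' @param deme_size simulated diploid deme size.
#' @return A data frame per locus: `locus`, `He`, `theta`, `outlier`.
#' @export
fdist_outlier_scan <- function(gm, by = "population", n_sims = 1000,
                               n_bins = 10, deme_size = 500) {
  groups <- group_labels(gm, by)
  glev <- unique(groups)
  K <- length(glev)
  if (K < 2) stop("need >= 2 groups")
  L <- n_loci(gm)
  if (L < 2) stop("cannot calibrate from a single locus")
  n_per <- round(mean(table(groups)))
  obs <- wc_fst(gm, by = groups, n_boot = 0)$per_locus
  obs$He <- vapply(seq_len(L), function(l) {
    ok <- !is.na(gm$a1[, l])
    cnt <- as.numeric(table(c(gm$a1[ok, l], gm$a2[ok, l])))
    .hs_unbiased(cnt)
  }, numeric(1))
  target <- mean(obs$theta, trim = 0.1, na.rm = TRUE)
  target <- max(target, 1e-4)

  tip_pop <- rep(seq_len(K) - 1L, each = 2 * n_per)
  sim_groups <- rep(seq_len(K), each = n_per)
  odd <- 2 * seq_len(K * n_per) - 1
  mm <- mutation_model()
  sim_theta_he <- function(m, nsim) {
    t(vapply(seq_len(nsim), function(s) {
      sim <- cpp_sim_dataset(tip_pop, rep(deme_size, K), matrix(0, 0, 4), m,
                             mm$mu, mm$P, mm$sni, mm$allelic_range)
      al <- 2 * sim$state[, 1] + sim$offset[, 1]  # distinct off-ladder states
      a1 <- al[odd]; a2 <- al[odd + 1]
      cc <- .wc_locus(a1, a2, sim_groups)
      th <- if (sum(cc) > 0) cc[1] / sum(cc) else NA_real_
      he <- .hs_unbiased(tabulate(match(al, unique(al))))
      c(th, he)
    }, numeric(2)))
  }
  # bisection on migration rate (theta decreasing in m)
  lo <- 1e-5; hi <- 0.5
  mean_th <- function(m, nsim = 60) mean(sim_theta_he(m, nsim)[, 1], na.rm = TRUE)
  if (mean_th(hi) > target) {
    m_star <- hi
  } else if (mean_th(lo) < target) {
    stop("tuning failed to bracket the target theta")
  } else {
    for (it in 1:12) {
      mid <- sqrt(lo * hi)
      if (mean_th(mid) > target) lo <- mid else hi <- mid
    }
    m_star <- sqrt(lo * hi)
  }
  sims <- sim_theta_he(m_star, n_sims)
  sims <- sims[stats::complete.cases(sims), , drop = FALSE]
  # equal-count He bins; envelope per bin
  qb <- unique(stats::quantile(sims[, 2], probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(sims[, 2], qb, include.lowest = TRUE)
  env <- do.call(rbind, lapply(levels(bin), function(b) {
    th <- sims[bin == b, 1]
    data.frame(bin = b, lo = stats::quantile(th, 0.025, names = FALSE),
               hi = stats::quantile(th, 0.975, names = FALSE))
  }))
  obin <- cut(pmin(pmax(obs$He, min(sims[, 2])), max(sims[, 2])), qb,
              include.lowest = TRUE)
  lo_i <- env$lo[match(obin, env$bin)]
  hi_i <- env$hi[match(obin, env$bin)]
  data.frame(locus = obs$locus, He = obs$He, theta = obs$theta,
             outlier = !is.na(obs$theta) & (obs$theta < lo_i | obs$theta > hi_i),
             stringsAsFactors = FALSE)
}

#' Three-way QST-FST verdict
#'
#' Divergent selection when QST exceeds the FST CI's upper bound,
#' stabilizing selection when it falls below the lower bound, genetic
#' drift otherwise.
#'
#' @param qst_values named numeric vector of per-trait QST values.
#' @param fst a [wc_fst()] result (or list with `theta` and `ci`).
#' @return A data frame: `trait`, `QST`, `FST`, `ci_low`, `ci_high`,
#'   `verdict` in `divergent`/`stabilizing`/`drift`.
#' @export
compare_qst_fst <- function(qst_values, fst) {
  ci <- fst$ci
  if (anyNA(ci) || ci[1] > ci[2]) stop("malformed FST confidence interval")
  verdict <- ifelse(qst_values > ci[2], "divergent",
                    ifelse(qst_values < ci[1], "stabilizing", "drift"))
  data.frame(trait = names(qst_values) %||% seq_along(qst_values),
             QST = unname(qst_values), FST = fst$theta,
             ci_low = ci[1], ci_high = ci[2], verdict = unname(verdict),
             stringsAsFactors = FALSE)
}
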