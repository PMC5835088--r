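# Bottleneck detection: heterozygosity excess under a two-phase mutation
# model, and the Garza-Williamson M ratio.

# tune theta by bisection so that the equilibrium mean allele count matches
# k for a sample of n gene copies, then check acceptance is workable
.tune_theta <- function(n, k, p_smm, nsim = 100, min_accept = 0.02,
                        max_iter = 25) {
  lo <- 1e-3; hi <- 200
  # expand hi until mean k exceeds target (theta monotone in k)
  for (it in 1:10) {
    mk <- cpp_eq_kmean(n, hi, p_smm, k, nsim)[1]
    if (mk >= k) break
    hi <- hi * 4
  }
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    mk <- cpp_eq_kmean(n, mid, p_smm, k, nsim)[1]
    if (mk < k) lo <- mid else hi <- mid
  }
  theta <- sqrt(lo * hi)
  acc <- cpp_eq_kmean(n, theta, p_smm, k, max(nsim * 4, 200))[2]
  list(theta = theta, accept = acc, ok = acc >= min_accept)
}

#' Heterozygosity-excess bottleneck test (two-phase model)
#'
#' For every polymorphic locus, coalescent samples of the same size are
#' simulated at mutation-drift equilibrium under a two-phase model (a
#' fraction `p_smm` of mutations are single-step, the remainder
#' infinite-allele), retaining simulations whose allele count matches the
#' observed count (theta tuned by bisection). `Heq` is the mean unbiased
#' gene diversity of the accepted simulations. The across-locus test is a
#' one-tailed Wilcoxon signed-rank on the normal-scored excess: each
#' locus's `He - Heq` difference enters as the normal score of He's
#' mid-rank percentile within the simulated Heq distribution, keeping the
#' null symmetric (the conditional distribution of gene diversity given
#' the allele count is left-skewed, so ranking raw differences would be
#' anticonservative).
#'
#' @param gm a [genotype_matrix()].
#' @param group accession selector (logical/index vector, or a label with
#'   `by`); default all accessions.
#' @param by grouping used when `group` is a label.
#' @param p_smm proportion of single-step mutations (default 0.10, i.e.
#'   10 percent SMM and 90 percent IAM).
#' @param n_iter accepted equilibrium simulations per locus.
#' @return A `bottleneck_result` list: `per_locus` data frame (`locus`,
#'   `k`, `n_copies`, `He`, `Heq_mean`, `Heq_sd`, `std_diff`), `p_value`
#'   (one-tailed, excess), `n_loci_used`.
#' @export
heterozygosity_excess_test <- function(gm, group = NULL, by = "population",
                                       p_smm = 0.10, n_iter = 1000) {
  sel <- if (is.null(group)) rep(TRUE, n_accessions(gm))
         else if (is.character(group) && length(group) == 1)
           group_labels(gm, by) == group
         else group
  x1 <- gm$a1[sel, , drop = FALSE]; x2 <- gm$a2[sel, , drop = FALSE]
  L <- ncol(x1)
  rows <- list()
  n_poly <- 0
  for (l in seq_len(L)) {
    ok <- !is.na(x1[, l])
    n <- 2 * sum(ok)
    if (n < 4) next
    cnt <- as.numeric(table(c(x1[ok, l], x2[ok, l])))
    k <- length(cnt)
    if (k < 2) next  # monomorphic loci are excluded
    n_poly <- n_poly + 1
    he <- .hs_unbiased(cnt)
    tune <- .tune_theta(n, k, p_smm)
    sim <- cpp_eq_heq(n, tune$theta, p_smm, k, n_iter, 50L * n_iter)
    heq <- sim$heq
    if (length(heq) < max(20, n_iter / 10))
      stop("acceptance failure at locus ", gm$loci$name[l],
           ": got ", length(heq), " accepted simulations")
    m <- mean(heq); s <- stats::sd(heq)
    pct <- (sum(heq < he) + 0.5 * sum(heq == he) + 0.5) / (length(heq) + 1)
    rows[[length(rows) + 1]] <- data.frame(
      locus = gm$loci$name[l], k = k, n_copies = n, He = he,
      Heq_mean = m, Heq_sd = s,
      std_diff = if (s > 0) (he - m) / s else NA_real_,
      z_excess = stats::qnorm(pct),
      stringsAsFactors = FALSE)
  }
  if (n_poly == 0) stop("no polymorphic locus qualifies")
  per <- do.call(rbind, rows)
  if (sum(per$n_copies >= 10) < 4 || nrow(per) < 4)
    warning("fewer than 4 polymorphic loci with >= 10 gene copies; ",
            "the Wilcoxon step is weak")
  wt <- stats::wilcox.test(per$z_excess, alternative = "greater",
                           exact = FALSE, correct = TRUE)
  structure(list(per_locus = per, p_value = wt$p.value,
                 n_loci_used = nrow(per), p_smm = p_smm),
            class = "bottleneck_result")
}

#' Garza-Williamson M ratio
#'
#' Per polymorphic locus, `M = k / (r + 1)` with `k` the number of distinct
#' alleles and `r` the allele range in repeat units; the group value is the
#' unweighted mean over polymorphic loci. Off-ladder
#' (single-nucleotide-indel) alleles count toward `k` but contribute their
#' nearest ladder slot to the range. Group means below the conventional
#' threshold 0.68 flag a bottleneck.
#'
#' @param gm a [genotype_matrix()] coded in repeat units (see
#'   [to_repeat_units()]); size-coded matrices are converted on the fly.
#' @param by grouping passed to [group_labels()].
#' @param threshold flag level for the group mean (default 0.68).
#' @return A data frame (`group`, `M`, `n_loci`, `below_threshold`) with a
#'   per-locus matrix in `attr(, "per_locus")`.
#' @export
garza_williamson <- function(gm, by = "population", threshold = 0.68) {
  if (any(gm$loci$coding != "repeat_count")) gm <- to_repeat_units(gm)
  groups <- group_labels(gm, by)
  glev <- unique(groups)
  L <- n_loci(gm)
  Mmat <- matrix(NA_real_, L, length(glev), dimnames = list(gm$loci$name, glev))
  for (g in glev) {
    sel <- groups == g
    for (l in seq_len(L)) {
      al <- c(gm$a1[sel, l], gm$a2[sel, l])
      al <- al[!is.na(al)]
      if (length(al) < 2) next
      k <- length(unique(al))
      if (k < 2) next
      slot <- round(al - 1)  # nearest ladder position
      r <- max(slot) - min(slot)
      Mmat[l, g] <- k / (r + 1)
    }
    if (all(is.na(Mmat[, g]))) stop("no polymorphic locus in group ", g)
  }
  out <- data.frame(group = glev, M = colMeans(Mmat, na.rm = TRUE),
                    n_loci = colSums(!is.na(Mmat)), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$below_threshold <- out$M < threshold
  attr(out, "per_locus") <- Mmat
  out
}
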