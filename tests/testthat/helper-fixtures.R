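# Shared fixtures and independent oracles, all built in code.

# tiny deterministic genotype matrix: 4 accessions x 2 loci, 2 populations
toy_gm <- function() {
  a1 <- rbind(c(150, 201), c(150, 204), c(152, 201), c(154, 204))
  a2 <- rbind(c(150, 204), c(152, 201), c(152, 204), c(154, 204))
  rownames(a1) <- paste0("acc", 1:4)
  colnames(a1) <- c("Lx", "Ly")
  meta <- data.frame(accession = paste0("acc", 1:4),
                     population = c("p1", "p1", "p2", "p2"),
                     region = c("LFZ", "LFZ", "SWC", "SWC"),
                     status = c("wild", "wild", "cultivated", "cultivated"),
                     stringsAsFactors = FALSE)
  genotype_matrix(a1, a2, loci = data.frame(name = colnames(a1),
                                            motif_length = c(2L, 3L),
                                            coding = "size_bp"),
                  metadata = meta)
}

# single-group matrix from explicit genotype pairs at one locus
one_locus_gm <- function(pairs) {
  a1 <- matrix(vapply(pairs, `[`, numeric(1), 1), ncol = 1)
  a2 <- matrix(vapply(pairs, `[`, numeric(1), 2), ncol = 1)
  genotype_matrix(a1, a2)
}

# mutation-drift-equilibrium matrix under the two-phase model; labels
# encode the SMM ladder (pure SMM gives true allele-size geometry)
eq_gm <- function(n_dip, L, theta, p_smm) {
  a1 <- matrix(NA_real_, n_dip, L); a2 <- a1
  for (l in seq_len(L)) {
    al <- 100 + 2 * (cherrydemog:::cpp_eq_locus(2L * n_dip, theta, p_smm) - 5e5)
    a1[, l] <- al[seq(1, 2 * n_dip, 2)]
    a2[, l] <- al[seq(2, 2 * n_dip, 2)]
  }
  genotype_matrix(a1, a2)
}

# single population that crashed from N_old to N_now t_crash generations ago
crash_gm <- function(n_dip, L, N_now, N_old, t_crash, mu = 5e-4, P = 0) {
  spec <- list(tip_pop = rep(0L, 2 * n_dip), sizes = N_now,
               events = matrix(c(t_crash, 0, 0, N_old), 1, 4), mig = 0)
  a1 <- matrix(NA_real_, n_dip, L); a2 <- a1
  mm <- mutation_model(mu = mu, P = P)
  for (l in seq_len(L)) {
    g <- sample_genealogy(spec)
    tips <- apply_mutations(g, mm)
    sz <- 100 + 2 * tips$state + tips$offset
    a1[, l] <- sz[seq(1, 2 * n_dip, 2)]
    a2[, l] <- sz[seq(2, 2 * n_dip, 2)]
  }
  genotype_matrix(a1, a2)
}

# random genotype matrix with optional populations (used in round-trips and
# the rarefaction identity)
random_gm <- function(n = 12, L = 3, n_pops = 3, max_allele = 8,
                      miss_rate = 0) {
  a1 <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  if (miss_rate > 0) {
    miss <- matrix(stats::runif(n * L) < miss_rate, n, L)
    a1[miss] <- NA; a2[miss] <- NA
  }
  rownames(a1) <- paste0("i", seq_len(n))
  colnames(a1) <- paste0("L", seq_len(L))
  pops <- sort(rep_len(paste0("pop", seq_len(n_pops)), n))
  meta <- data.frame(accession = rownames(a1), population = pops,
                     region = "unknown", status = "wild",
                     stringsAsFactors = FALSE)
  genotype_matrix(a1, a2, metadata = meta)
}

# --- independent oracles ---------------------------------------------------

# Weir & Cockerham (1984) theta written as a direct per-allele loop
# transcription, independent of the package's vectorised implementation
wc_theta_oracle <- function(a1m, a2m, groups) {
  num <- den <- 0
  for (l in seq_len(ncol(a1m))) {
    x1 <- a1m[, l]; x2 <- a2m[, l]
    keep <- !is.na(x1)
    if (!any(keep)) next
    g <- groups[keep]; x1 <- x1[keep]; x2 <- x2[keep]
    pops <- unique(g)
    r <- length(pops)
    if (r < 2) next
    n_i <- sapply(pops, function(p) sum(g == p))
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    for (al in unique(c(x1, x2))) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        sel <- g == pops[k]
        p_i[k] <- sum(c(x1[sel], x2[sel]) == al) / (2 * n_i[k])
        h_i[k] <- sum((x1[sel] == al) + (x2[sel] == al) == 1) / n_i[k]
      }
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# exhaustive rarefaction: average number of distinct alleles over all
# subsamples of g gene copies (N <= 8)
ar_exhaustive <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(seq_along(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}
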