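test_that("diversity statistics reproduce hand-computed values", {
  # genotypes AA, AB, AB, BB at one locus: p = 0.5
  gm <- one_locus_gm(list(c(1, 1), c(1, 2), c(1, 2), c(2, 2)))
  ds <- diversity_stats(gm)
  expect_equal(ds$Ho, 0.5)
  expect_equal(ds$Hs, (8 / 7) * 0.5)
  expect_equal(ds$Fis, 1 - 0.5 / ((8 / 7) * 0.5))
  expect_equal(ds$A, 2)
  # two equifrequent alleles: PIC = 1 - 0.5 - 2 * 0.25 * 0.25
  gm2 <- one_locus_gm(list(c(1, 1), c(2, 2), c(1, 1), c(2, 2)))
  expect_equal(diversity_stats(gm2)$PIC, 0.375)
  # monomorphic locus
  gm3 <- one_locus_gm(list(c(1, 1), c(1, 1)))
  ds3 <- diversity_stats(gm3)
  expect_equal(ds3$Hs, 0)
  expect_equal(ds3$PIC, 0)
  expect_true(is.na(ds3$Fis))
})

test_that("statistics are invariant to allele relabelling", {
  set.seed(301)
  gm <- random_gm(10, 3, n_pops = 1)
  relab <- gm
  relab$a1 <- gm$a1 * 7 + 3
  relab$a2 <- gm$a2 * 7 + 3
  expect_equal(diversity_stats(gm)[, c("A", "Hs", "Ho", "PIC", "Fis")],
               diversity_stats(relab)[, c("A", "Hs", "Ho", "PIC", "Fis")])
})

test_that("allele counts are additive across grouping levels", {
  set.seed(302)
  gm <- random_gm(12, 2, n_pops = 3)
  by_pop <- allele_frequencies(gm, "population")
  overall <- allele_frequencies(gm, rep("all", 12))
  agg <- stats::aggregate(count ~ locus + allele, data = by_pop, sum)
  merged <- merge(agg, overall, by = c("locus", "allele"))
  expect_equal(merged$count.x, merged$count.y)
})

test_that("rarefaction matches exhaustive enumeration for small samples", {
  set.seed(303)
  for (rep in 1:25) {
    N <- sample(4:8, 1)
    k <- sample(1:3, 1)
    counts <- as.numeric(table(sample.int(k, N, replace = TRUE)))
    g <- sample(seq_len(N - 1), 1)
    # build a diploid matrix carrying exactly these gene copies
    copies <- rep(seq_along(counts), counts)
    n_dip <- floor(N / 2)
    used <- copies[seq_len(2 * n_dip)]
    a1 <- matrix(used[seq(1, 2 * n_dip, 2)], ncol = 1)
    a2 <- matrix(used[seq(2, 2 * n_dip, 2)], ncol = 1)
    gm <- genotype_matrix(a1, a2)
    g_use <- min(g, 2 * n_dip - 1)
    ar <- rarefied_richness(gm, g = g_use)$Ar
    expect_equal(ar, ar_exhaustive(as.numeric(table(used)), g_use),
                 tolerance = 1e-12)
  }
})

test_that("a private allele's Ap contribution grows toward 1", {
  # allele 9 private to group A at frequency 1/2; group B fixed for allele 1
  a1 <- matrix(c(9, 9, 9, 1, 1, 1), ncol = 1)
  a2 <- matrix(c(1, 1, 1, 1, 1, 1), ncol = 1)
  rownames(a1) <- paste0("i", 1:6)
  meta <- data.frame(accession = paste0("i", 1:6),
                     population = rep(c("A", "B"), each = 3),
                     region = "r", status = "wild")
  gm <- genotype_matrix(a1, a2, metadata = meta)
  ap2 <- rarefied_richness(gm, g = 2)$Ap[1]
  ap5 <- rarefied_richness(gm, g = 5)$Ap[1]
  expect_gt(ap5, ap2)
  expect_equal(ap5, 1, tolerance = 1e-9)
})

test_that("Fis under Hardy-Weinberg simulation is centred on zero", {
  set.seed(304)
  fis <- replicate(40, {
    d <- simulate_island(1, 800, 0, n_loci = 19, n_per_deme = 30)
    diversity_stats(d$gm)$Fis
  })
  expect_lt(abs(mean(fis)), 0.02)
})

test_that("the Fis permutation test flags heterozygote-deficient groups", {
  set.seed(305)
  d <- simulate_island(1, 800, 0, n_loci = 19, n_per_deme = 50)
  gm <- d$gm
  # force strong inbreeding: half the individuals become homozygous
  sel <- sample.int(50, 25)
  gm$a2[sel, ] <- gm$a1[sel, ]
  res <- fis_permutation_test(gm, n_perm = 199)
  expect_gt(res$fis, 0.2)
  expect_lt(res$p_value, 0.01)
  expect_error(fis_permutation_test(gm, n_perm = 10), "n_perm")
  mono <- one_locus_gm(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_error(fis_permutation_test(mono, n_perm = 99), "monomorphic")
})

test_that("the LD permutation test detects perfect linkage", {
  set.seed(306)
  d <- simulate_island(1, 2000, 0, n_loci = 1, n_per_deme = 30)
  a1 <- cbind(d$gm$a1, d$gm$a1); colnames(a1) <- c("A", "B")
  a2 <- cbind(d$gm$a2, d$gm$a2); colnames(a2) <- colnames(a1)
  gm <- genotype_matrix(a1, a2)
  res <- ld_test(gm, "A", "B", n_perm = 99)
  expect_lte(res$per_group$p, 1 / 100)
  mono <- genotype_matrix(cbind(a1[, 1], rep(1, 30)),
                          cbind(a2[, 1], rep(1, 30)))
  expect_error(ld_test(mono, 1, 2, n_perm = 99), "monomorphic")
})

test_that("moment relatedness estimators recover pedigree expectations", {
  set.seed(307)
  L <- 19
  freqs <- lapply(seq_len(L), function(l) {
    p <- stats::rgamma(8, 1); p / sum(p)
  })
  draw <- function() vapply(freqs, function(p)
    sample.int(length(p), 1, prob = p), integer(1))
  n_pairs <- 150
  a1 <- matrix(0, 2 * n_pairs, L); a2 <- a1
  for (i in seq_len(n_pairs)) {
    p1a <- draw(); p1b <- draw()        # parent
    kid_a <- ifelse(stats::runif(L) < 0.5, p1a, p1b)  # inherited copy
    kid_b <- draw()                      # other parent's copy
    a1[2 * i - 1, ] <- p1a; a2[2 * i - 1, ] <- p1b
    a1[2 * i, ] <- kid_a;  a2[2 * i, ] <- kid_b
  }
  gm <- genotype_matrix(a1, a2)
  for (est in c("queller_goodnight", "lynch_ritland")) {
    rm_ <- relatedness(gm, estimator = est)
    po <- vapply(seq_len(n_pairs), function(i) rm_[2 * i - 1, 2 * i],
                 numeric(1))
    unrel <- vapply(seq_len(n_pairs - 1), function(i) rm_[2 * i - 1, 2 * i + 1],
                    numeric(1))
    expect_lt(abs(mean(po) - 0.5), 0.05)
    expect_lt(abs(mean(unrel)), 0.05)
  }
  expect_error(relatedness(gm, "unknown"), "arg")
})

test_that("relatedness pruning follows the greedy over-threshold rule", {
  rm_ <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  rm_["a", "b"] <- rm_["b", "a"] <- 0.9
  rm_["b", "c"] <- rm_["c", "b"] <- 0.8
  diag(rm_) <- NA
  res <- prune_related(rm_, 0.5)
  expect_equal(res$n_pairs_over, 2L)
  expect_equal(res$percent_over, 100 * 2 / 6)
  expect_setequal(res$kept, c("a", "c", "d"))  # b has the most links
})

test_that("Kruskal-Wallis letters separate disjoint groups, merge equal ones", {
  set.seed(308)
  v1 <- c(stats::runif(19, 0, 1), stats::runif(19, 5, 6))
  g1 <- rep(c("lo", "hi"), each = 19)
  k1 <- kw_letters(v1, g1)
  expect_lt(k1$p_value, 0.001)
  expect_true(k1$letters["lo"] != k1$letters["hi"])
  v2 <- stats::rnorm(57)
  g2 <- rep(c("x", "y", "z"), each = 19)
  k2 <- kw_letters(v2, g2)
  expect_equal(length(unique(k2$letters)), 1L)
  expect_error(kw_letters(v1, rep("one", 38)), "2 groups")
})
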