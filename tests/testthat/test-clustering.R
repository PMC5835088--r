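test_that("K = 1 collapses to full membership and duplicates agree", {
  set.seed(401)
  d <- simulate_island(2, 300, 0.01, n_loci = 8, n_per_deme = 10)
  r1 <- admixture_mcmc(d$gm, K = 1, burnin = 50, iters = 100)
  expect_true(all(r1$Q == 1))
  expect_true(is.finite(r1$lnP))
  # duplicated accession rows get near-identical Q
  gm <- d$gm
  a1 <- rbind(gm$a1, dup = gm$a1[1, ]); rownames(a1)[21] <- "dup"
  a2 <- rbind(gm$a2, gm$a2[1, ]); rownames(a2) <- rownames(a1)
  meta <- rbind(gm$metadata, gm$metadata[1, ])
  meta$accession[21] <- "dup"
  gm2 <- genotype_matrix(a1, a2, loci = gm$loci, metadata = meta)
  r2 <- admixture_mcmc(gm2, K = 2, burnin = 500, iters = 1000)
  expect_lt(max(abs(r2$Q[1, ] - r2$Q[21, ])), 0.2)
  expect_error(admixture_mcmc(d$gm, K = 50), "exceeds")
})

test_that("planted three-deme structure is recovered at high membership", {
  set.seed(402)
  d <- simulate_island(3, 1000, 6.5e-4, n_loci = 19, n_per_deme = 30)
  r <- admixture_mcmc(d$gm, K = 3, burnin = 800, iters = 800)
  lab <- assign_clusters(r, 0.8)
  tb <- table(lab, d$gm$metadata$population)
  tb <- tb[rownames(tb) != "admixed", , drop = FALSE]
  expect_gte(sum(apply(tb, 2, max)) / 90, 0.85)
})

test_that("Evanno's delta K behaves on constructed evidence tables", {
  lin <- expand.grid(K = 1:5, run = 1:3)
  # means exactly linear in K, equal within-K spread: second difference 0
  lin$lnP <- -1000 + 7 * lin$K + c(-1, 0, 1)[lin$run]
  ev <- evanno(lin)
  expect_equal(ev$deltaK[2:4], c(0, 0, 0))
  # a kink at K = 3 dominates
  set.seed(403)
  kink <- expand.grid(K = 1:5, run = 1:3)
  mean_ln <- c(-2000, -1500, -1200, -1190, -1185)
  kink$lnP <- mean_ln[kink$K] + stats::rnorm(nrow(kink), 0, 5)
  expect_equal(attr(evanno(kink), "best_K"), 3L)
  # zero run-to-run spread => NA, not an error
  flat <- expand.grid(K = 1:3, run = 1:2)
  flat$lnP <- c(-10, -5, -4)[flat$K]
  expect_true(is.na(evanno(flat)$deltaK[2]))
  # invariant to adding a constant
  ev2 <- evanno(transform(kink, lnP = lnP + 500))
  expect_equal(ev2$deltaK, evanno(kink)$deltaK)
})

test_that("run alignment undoes label switching and isolates noise modes", {
  set.seed(404)
  Q <- matrix(stats::rgamma(60 * 3, 0.4), 60, 3)
  Q <- Q / rowSums(Q)
  perm <- Q[, c(3, 1, 2)]
  al <- align_runs(list(Q, perm))
  expect_equal(al$modes, c(1L, 1L))
  expect_equal(al$aligned[[2]], Q, ignore_attr = TRUE)
  expect_gte(min(al$similarity), 0.999)
  noise <- matrix(1 / 3, 60, 3)
  al2 <- align_runs(list(Q, Q, noise))
  expect_equal(al2$modes, c(1L, 1L, 2L))
  expect_error(align_runs(list(Q, Q[, 1:2])), "mixed K")
})

test_that("threshold assignment is inclusive at the boundary", {
  Q <- rbind(c(0.85, 0.10, 0.05),
             c(0.50, 0.30, 0.20),
             c(0.80, 0.15, 0.05))
  expect_equal(unname(assign_clusters(Q, 0.800)),
               c("cluster_1", "admixed", "cluster_1"))
})

test_that("DA distance matches hand computation and its bounds", {
  # one locus; group A: alleles 1/2 equifrequent; group B fixed for 1
  a1 <- matrix(c(1, 2, 1, 1), ncol = 1)
  a2 <- matrix(c(1, 2, 1, 1), ncol = 1)
  rownames(a1) <- paste0("i", 1:4)
  meta <- data.frame(accession = paste0("i", 1:4),
                     population = c("A", "A", "B", "B"),
                     region = "r", status = "wild")
  gm <- genotype_matrix(a1, a2, metadata = meta)
  D <- da_distance(allele_frequencies(gm))
  expect_equal(D["A", "B"], 1 - sqrt(0.5))
  # identical profiles -> 0; disjoint alleles -> 1
  a1b <- matrix(c(1, 2, 1, 2, 7, 8, 7, 8), ncol = 1)
  meta2 <- data.frame(accession = paste0("i", 1:8),
                      population = rep(c("A", "B", "C", "D"), each = 2),
                      region = "r", status = "wild")
  rownames(a1b) <- meta2$accession
  gm2 <- genotype_matrix(a1b, a1b, metadata = meta2)
  D2 <- da_distance(allele_frequencies(gm2))
  expect_equal(D2["A", "B"], 0)
  expect_equal(D2["A", "C"], 1)
})

test_that("neighbour joining recovers additive trees and their distances", {
  set.seed(405)
  for (rep in 1:20) {
    tr <- ape::rtree(6)
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    # additive input distances are reproduced along the tree paths
    De <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(De, D, tolerance = 1e-6)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("three-taxon trees use the closed-form branch lengths", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 5
  D["a", "c"] <- D["c", "a"] <- 9
  D["b", "c"] <- D["c", "b"] <- 10
  tr <- nj_tree(D)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[c("a", "b", "c"), c("a", "b", "c")], D, tolerance = 1e-9)
})

test_that("outgroup rooting splits the outgroup's pendant edge", {
  set.seed(406)
  tr <- ape::rtree(6)
  D <- ape::cophenetic.phylo(tr)
  out <- rownames(D)[1]
  rooted <- nj_tree(D, outgroup = out)
  expect_true(ape::is.rooted(rooted))
  og_edge <- which(rooted$edge[, 2] == which(rooted$tip.label == out))
  root_children <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  expect_true(which(rooted$tip.label == out) %in% root_children)
})

test_that("principal coordinates reflect the genotype distance geometry", {
  # three mutually equidistant homozygotes: two equal positive eigenvalues
  a <- matrix(c(1, 2, 3), ncol = 1)
  gm <- genotype_matrix(a, a)
  pc <- pcoa_genotypes(gm, k = 2)
  eig <- pc$eigenvalues[pc$eigenvalues > 1e-9]
  expect_length(eig, 2)
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  # duplicated accession lands on identical coordinates
  a2 <- matrix(c(1, 2, 3, 3), ncol = 1)
  pc2 <- pcoa_genotypes(genotype_matrix(a2, a2), k = 2)
  expect_equal(pc2$coordinates[3, ], pc2$coordinates[4, ], tolerance = 1e-9)
  expect_error(pcoa_genotypes(genotype_matrix(matrix(1, 3, 1),
                                              matrix(1, 3, 1))), "identical")
})
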