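test_that("summary vectors have the fixed layout and direct values", {
  # two groups, one locus, repeat-coded mean sizes 10 vs 13
  a1 <- matrix(c(10, 10, 13, 13), ncol = 1)
  meta <- data.frame(accession = paste0("i", 1:4),
                     population = c("A", "A", "B", "B"),
                     region = "r", status = "wild")
  rownames(a1) <- meta$accession
  gm <- genotype_matrix(a1, a1,
                        loci = data.frame(name = "L1", motif_length = 2L,
                                          coding = "repeat_count"),
                        metadata = meta)
  s <- abc_summary(gm)
  expect_equal(unname(s["dmu2_A.B"]), 9)
  # identical mean sizes: zero distance
  a2 <- matrix(c(10, 12, 11, 11), ncol = 1)
  rownames(a2) <- meta$accession
  gm2 <- genotype_matrix(a2, a2,
                         loci = data.frame(name = "L1", motif_length = 2L,
                                           coding = "repeat_count"),
                         metadata = meta)
  expect_equal(unname(abc_summary(gm2)["dmu2_A.B"]), 0)
  # three groups: 3 x 2 group stats + 3 x 2 pair stats
  set.seed(801)
  d <- simulate_island(3, 300, 0.01, n_loci = 5, n_per_deme = 8)
  s3 <- abc_summary(d$gm)
  expect_length(s3, 12)
  expect_true(all(grepl("^(A|Hs|Fst|dmu2)_", names(s3))))
  # permutation invariance in accession order within groups
  idx <- c(sample(1:8), sample(9:16), sample(17:24))
  expect_equal(abc_summary(d$gm[idx, ]), s3)
})

test_that("reference tables replay exactly under a seed and obey priors", {
  set.seed(802); r1 <- build_reference(models = c(1, 3), n_per_model = 6,
                                       sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  set.seed(802); r2 <- build_reference(models = c(1, 3), n_per_model = 6,
                                       sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  expect_identical(r1, r2)
  expect_equal(as.numeric(table(r1$model)), c(6, 6))
  b <- prior_set()$bounds
  expect_true(all(r1$mu >= b$mu[1] & r1$mu <= b$mu[2]))
  expect_true(all(r1$T2 >= b$T2[1] & r1$T2 <= b$T2[2]))
  expect_true(all(r1$T2 > r1$T1))
})

test_that("pre-evaluation flags impossible observations, passes typical ones", {
  set.seed(803)
  ref <- build_reference(models = 1, n_per_model = 80,
                         sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  obs <- unlist(ref[4, attr(ref, "stat_names")])
  names(obs) <- sub("^S_", "", names(obs))
  pe <- preevaluate(obs, ref)
  expect_length(pe$flagged, 0)
  bad <- obs
  bad[grep("dmu2", names(bad))] <- 10 * max(ref$S_dmu2_WC.CC1) + 100
  expect_true(length(preevaluate(bad, ref)$flagged) >= 1)
  expect_error(preevaluate(obs, ref[integer(0), ]), "empty")
})

test_that("model choice degenerates correctly and normalises", {
  set.seed(804)
  ref1 <- build_reference(models = 2, n_per_model = 60,
                          sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  obs <- unlist(ref1[10, attr(ref1, "stat_names")])
  names(obs) <- sub("^S_", "", names(obs))
  mp <- select_model(obs, ref1, tolerance = 0.2)
  expect_equal(unname(mp$rejection), 1)
  expect_equal(unname(mp$logistic), 1)
  # two models: probabilities sum to one; rejection invariant to row
  # duplication
  set.seed(805)
  ref2 <- build_reference(models = c(1, 2), n_per_model = 50,
                          sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  mp2 <- select_model(obs, ref2, tolerance = 0.1)
  expect_equal(sum(mp2$rejection), 1)
  expect_equal(sum(mp2$logistic), 1, tolerance = 1e-6)
  refdup <- rbind(ref2, ref2)
  for (a in c("stat_names", "priors")) attr(refdup, a) <- attr(ref2, a)
  class(refdup) <- class(ref2)
  mp_all <- select_model(obs, ref2, tolerance = 1)
  mp_dup <- select_model(obs, refdup, tolerance = 1)
  expect_equal(mp_dup$rejection, mp_all$rejection)
})

test_that("uninformative statistics reduce the regression to rejection", {
  set.seed(806)
  ref <- build_reference(models = 2, n_per_model = 120,
                         sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  # overwrite all statistics with a constant: zero-information design
  for (sn in attr(ref, "stat_names")) ref[[sn]] <- 1
  obs <- stats::setNames(rep(1, 12), sub("^S_", "", attr(ref, "stat_names")))
  ep <- suppressWarnings(estimate_params(obs, ref, 2, tolerance = 0.5))
  ret <- ceiling(0.5 * nrow(ref))
  # with all-equal distances the retained set is the first ntol rows and
  # the adjustment must reproduce plain rejection quantiles
  expect_equal(ep$summary$median[ep$summary$parameter == "N3"],
               unname(stats::quantile(ref$N3[seq_len(ret)], 0.5, type = 1)),
               tolerance = 0.05 * diff(range(ref$N3)))
  # posterior summaries always inside prior bounds
  b <- prior_set()$bounds
  expect_true(all(ep$summary$q025[1:5] >= b$N1[1] - 1e-6))
  expect_true(all(ep$summary$q975[1:5] <= b$N1[2] + 1e-6))
})

test_that("generations convert to years with half-up rounding", {
  expect_equal(generations_to_years(872), 3924)
  expect_equal(generations_to_years(497), 2237)
  expect_equal(generations_to_years(355), 1598)
  expect_equal(generations_to_years(875), 3938)
  expect_equal(generations_to_years(1560), 7020)
  expect_equal(generations_to_years(0), 0)
  expect_error(generations_to_years(-1), "negative")
})

test_that("confusion matrices conserve pod mass", {
  set.seed(807)
  ref <- build_reference(models = c(1, 2), n_per_model = 120,
                         sample_sizes = c(WC = 8, CC1 = 8, CC2 = 8))
  ce <- confusion_errors(ref, n_pods = 6, focal_model = 2, tolerance = 0.1)
  expect_true(ce$type_I >= 0 && ce$type_I <= 1)
  expect_true(ce$mean_type_II >= 0 && ce$mean_type_II <= 1)
  expect_equal(unname(rowSums(ce$assignment)), c(1, 1))
})

test_that("posterior-predictive checks pass for self-generated data", {
  set.seed(808)
  ref <- build_reference(models = 2, n_per_model = 150,
                         sample_sizes = c(WC = 10, CC1 = 10, CC2 = 10))
  obs <- unlist(ref[40, attr(ref, "stat_names")])
  names(obs) <- sub("^S_", "", names(obs))
  ep <- suppressWarnings(estimate_params(obs, ref, 2, tolerance = 0.2))
  mc <- model_check(ep, obs, n_rep = 30,
                    sample_sizes = c(WC = 10, CC1 = 10, CC2 = 10))
  expect_lte(sum(mc$flagged), 3)
  expect_true(all(mc$p >= 0 & mc$p <= 1))
})
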