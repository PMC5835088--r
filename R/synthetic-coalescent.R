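# Structured-coalescent simulator of microsatellite genotypes: the
# synthetic-data generator and the ABC simulation engine.

#' Generalized stepwise mutation model
#'
#' @param mu mean mutation rate per locus per generation.
#' @param P geometric step parameter in \[0, 1): the continuation
#'   probability, so step magnitudes are 1, 2, 3, ... with
#'   `P(k) = (1 - P) P^(k-1)` and mean `1/(1 - P)`.
#' @param sni single-nucleotide-indel rate per locus per generation;
#'   SNI events toggle a +/-1 bp off-ladder offset.
#' @param allelic_range number of contiguous ladder states (default 40, the
#'   bounded window conventional for microsatellite coalescent simulation).
#' @param per_locus optional matrix/data frame with columns `mu`, `P`, `sni`
#'   giving per-locus rates (overrides the means locus-wise).
#' @return A `mutation_model` object.
#' @export
mutation_model <- function(mu = 5e-4, P = 0.22, sni = 1e-7,
                           allelic_range = 40, per_locus = NULL) {
  stopifnot(mu >= 0, P >= 0, P < 1, sni >= 0, allelic_range >= 2)
  structure(list(mu = mu, P = P, sni = sni, allelic_range = allelic_range,
                 per_locus = per_locus), class = "mutation_model")
}

.model_rates <- function(model, n_loci) {
  if (!is.null(model$per_locus)) {
    pl <- as.data.frame(model$per_locus)
    stopifnot(nrow(pl) == n_loci)
    list(mu = pl$mu, P = pl$P, sni = pl$sni)
  } else {
    list(mu = rep(model$mu, n_loci), P = rep(model$P, n_loci),
         sni = rep(model$sni, n_loci))
  }
}

#' Demographic scenario for the four domestication models
#'
#' Builds a split-with-bottleneck demography for populations WC (wild),
#' CC1 and CC2 (cultivated). In forward time, a cultivated population
#' founded at time T (generations ago) has bottleneck size `Nb` from its
#' founding until `T - Db` and its current size from then on; WC keeps the
#' constant size N3. Ancestries per model: (1) CC1 from WC at T2, CC2 from
#' WC at T1; (2) CC2 from WC at T2, CC1 from WC at T1; (3) CC2 from WC at
#' T2, CC1 from CC2 at T1; (4) CC1 from WC at T2, CC2 from CC1 at T1.
#' T2 > T1 (the first event is older). Bottleneck durations longer than the
#' population's age are truncated to the founding time.
#'
#' @param model_id integer 1..4.
#' @param params named vector/list with `N1`, `N2`, `N3`, `N1b`, `N2b`,
#'   `T1`, `T2`, `Db1`, `Db2` (sizes diploid, times in generations ago).
#' @param sample_sizes named diploid sample counts for `WC`, `CC1`, `CC2`.
#' @return A `scenario_spec` object.
#' @export
scenario_from_model <- function(model_id, params,
                                sample_sizes = c(WC = 30, CC1 = 30, CC2 = 30)) {
  stopifnot(model_id %in% 1:4)
  p <- as.list(params)
  need <- c("N1", "N2", "N3", "N1b", "N2b", "T1", "T2", "Db1", "Db2")
  if (!all(need %in% names(p))) stop("params must contain ", paste(need, collapse = ", "))
  if (p$T2 <= p$T1) stop("time ordering violated: T2 must exceed T1")
  if (any(unlist(p[c("N1", "N2", "N3", "N1b", "N2b")]) <= 0)) stop("sizes must be positive")
  if (p$T1 <= 0 || p$Db1 < 0 || p$Db2 < 0) stop("times must be positive")
  founding <- switch(model_id,
    `1` = c(CC1 = p$T2, CC2 = p$T1),
    `2` = c(CC1 = p$T1, CC2 = p$T2),
    `3` = c(CC1 = p$T1, CC2 = p$T2),
    `4` = c(CC1 = p$T2, CC2 = p$T1))
  ancestor <- switch(model_id,
    `1` = c(CC1 = "WC", CC2 = "WC"),
    `2` = c(CC1 = "WC", CC2 = "WC"),
    `3` = c(CC1 = "CC2", CC2 = "WC"),
    `4` = c(CC1 = "WC", CC2 = "CC1"))
  db <- c(CC1 = min(p$Db1, founding[["CC1"]]), CC2 = min(p$Db2, founding[["CC2"]]))
  pops <- c("WC", "CC1", "CC2")
  structure(list(
    model_id = model_id, pops = pops, params = p,
    founding = founding, ancestor = ancestor, db = db,
    sizes_now = c(WC = p$N3, CC1 = p$N1, CC2 = p$N2),
    sizes_bottleneck = c(CC1 = p$N1b, CC2 = p$N2b),
    sample_sizes = sample_sizes[pops]
  ), class = "scenario_spec")
}

# event table for the C++ engine (columns: time, type, a, b), 0-based pops
.scenario_events <- function(spec) {
  pops <- spec$pops
  pid <- stats::setNames(seq_along(pops) - 1L, pops)
  ev <- NULL
  for (cc in c("CC1", "CC2")) {
    t_found <- spec$founding[[cc]]
    t_start <- t_found - spec$db[[cc]]  # bottleneck begins here, backwards
    if (spec$db[[cc]] > 0 && t_start > 0)
      ev <- rbind(ev, c(t_start, 0, pid[[cc]], spec$sizes_bottleneck[[cc]]))
    ev <- rbind(ev, c(t_found, 1, pid[[cc]], pid[[spec$ancestor[[cc]]]]))
  }
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  sizes0 <- spec$sizes_now[pops]
  for (cc in c("CC1", "CC2")) {
    if (spec$db[[cc]] > 0 && spec$founding[[cc]] - spec$db[[cc]] <= 0)
      sizes0[[cc]] <- spec$sizes_bottleneck[[cc]]  # bottleneck reaches the present
  }
  list(events = ev, sizes0 = unname(sizes0), pid = pid)
}

.tip_pops <- function(sample_sizes) {
  rep(seq_along(sample_sizes) - 1L, times = 2 * sample_sizes)
}

#' Sample a genealogy under a scenario
#'
#' Structured coalescent: within each epoch, k lineages in a population of
#' diploid size N coalesce at rate k(k-1)/(4N) per generation; at a split
#' time (backwards) the derived population's lineages move to the ancestor.
#'
#' @param spec a [scenario_from_model()] object, or a list with elements
#'   `tip_pop` (0-based population per sampled gene copy), `sizes`
#'   (initial diploid sizes), `events` (event matrix) and `mig` for generic
#'   demographies.
#' @return A `genealogy`: list with `parent` (1-based, 0 = root), `time`
#'   (generations ago, tips at 0) and `n_tips`. Tips are ordered by
#'   population, two gene copies per diploid.
#' @export
sample_genealogy <- function(spec) {
  if (inherits(spec, "scenario_spec")) {
    se <- .scenario_events(spec)
    tip_pop <- .tip_pops(spec$sample_sizes)
    g <- cpp_genealogy(tip_pop, se$sizes0, se$events, 0)
  } else {
    ev <- spec$events
    if (is.null(ev)) ev <- matrix(0, 0, 4)
    g <- cpp_genealogy(spec$tip_pop, spec$sizes, ev, spec$mig %||% 0)
  }
  structure(list(parent = g$parent + 1L, time = g$time,
                 n_tips = (length(g$parent) + 1L) %/% 2L),
            class = "genealogy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop mutations on a genealogy
#'
#' Mutation events are Poisson along branches at the model's rate; each
#' event moves the repeat count by a geometric(P) magnitude with random
#' sign, redrawn when it would leave the bounded ladder. The root state is
#' the centre of the window. SNI events toggle a +/-1 bp off-ladder offset.
#'
#' @param tree a [sample_genealogy()] result.
#' @param model a [mutation_model()].
#' @return A data frame with `state` (repeat count on the ladder) and
#'   `offset` (bp off-ladder offset) per tip.
#' @export
apply_mutations <- function(tree, model) {
  res <- cpp_mutate(tree$parent - 1L, tree$time, tree$n_tips,
                    model$mu, model$P, model$sni, model$allelic_range)
  data.frame(state = res$state, offset = res$offset)
}

# compose allele sizes (bp) from ladder states and offsets
.states_to_sizes <- function(state, offset, motif = 2, base = 100) {
  base + motif * state + offset
}

.assemble_gm <- function(sim, pop_names, sample_sizes, motif = 2,
                         region = NULL, status = NULL) {
  n_dip <- sum(sample_sizes)
  odd <- 2 * seq_len(n_dip) - 1
  a1 <- .states_to_sizes(sim$state[odd, , drop = FALSE],
                         sim$offset[odd, , drop = FALSE], motif)
  a2 <- .states_to_sizes(sim$state[odd + 1, , drop = FALSE],
                         sim$offset[odd + 1, , drop = FALSE], motif)
  pops <- rep(pop_names, times = sample_sizes)
  ids <- paste0(pops, "_", unlist(lapply(sample_sizes, seq_len)))
  rownames(a1) <- ids
  colnames(a1) <- paste0("L", seq_len(ncol(a1)))
  meta <- data.frame(accession = ids, population = pops,
                     region = if (is.null(region)) pops else rep(region, sample_sizes),
                     status = if (is.null(status)) "wild" else rep(status, sample_sizes),
                     stringsAsFactors = FALSE)
  genotype_matrix(a1, a2,
                  loci = data.frame(name = colnames(a1), motif_length = motif,
                                    coding = "size_bp", stringsAsFactors = FALSE),
                  metadata = meta)
}

#' Simulate a multi-locus microsatellite dataset under a scenario
#'
#' Independent genealogy + mutation draws per locus; diploid genotypes are
#' formed by pairing consecutive sampled gene copies within populations
#' (exchangeable, hence random pairing). Allele states are reported as
#' fragment sizes `100 + motif * state + offset` so the result behaves like
#' genotyped band sizes.
#'
#' @param spec a [scenario_from_model()] object.
#' @param model a [mutation_model()].
#' @param n_loci number of loci.
#' @return A `simulated_dataset`: list with `gm` (a [genotype_matrix()]) and
#'   `truth` (the generating parameters).
#' @export
simulate_dataset <- function(spec, model = mutation_model(), n_loci = 19) {
  se <- .scenario_events(spec)
  tip_pop <- .tip_pops(spec$sample_sizes)
  r <- .model_rates(model, n_loci)
  sim <- cpp_sim_dataset(tip_pop, se$sizes0, se$events, 0,
                         r$mu, r$P, r$sni, model$allelic_range)
  status <- c("wild", "cultivated", "cultivated")
  gm <- .assemble_gm(sim, spec$pops, spec$sample_sizes, status = status)
  structure(list(gm = gm, truth = spec$params, model_id = spec$model_id),
            class = "simulated_dataset")
}

#' Simulate an island model
#'
#' Symmetric K-deme island model: constant deme size N, migration rate m
#' per lineage per generation to a uniformly chosen other deme.
#'
#' @param K number of demes.
#' @param N diploid deme size.
#' @param m migration rate per lineage per generation.
#' @param n_loci loci to simulate.
#' @param n_per_deme diploids sampled per deme.
#' @param model a [mutation_model()].
#' @param isolation_time with `m = 0` and `K > 1` the demes are treated as
#'   long-isolated fragments of one ancestral population that merged this
#'   many generations ago (default `40 * N`, deep enough for within-deme
#'   fixation), since fully disconnected demes share no ancestor.
#' @return A `simulated_dataset` whose populations are `deme1..demeK`.
#' @export
simulate_island <- function(K, N, m, n_loci = 19, n_per_deme = 30,
                            model = mutation_model(),
                            isolation_time = 40 * N) {
  stopifnot(K >= 1, m >= 0, m <= 1, N > 0)
  tip_pop <- rep(seq_len(K) - 1L, each = 2 * n_per_deme)
  events <- matrix(0, 0, 4)
  if (m == 0 && K > 1) {
    events <- cbind(isolation_time, 1, seq_len(K - 1), 0)
  }
  r <- .model_rates(model, n_loci)
  sim <- cpp_sim_dataset(tip_pop, rep(N, K), events, m,
                         r$mu, r$P, r$sni, model$allelic_range)
  gm <- .assemble_gm(sim, paste0("deme", seq_len(K)), rep(n_per_deme, K))
  structure(list(gm = gm, truth = list(K = K, N = N, m = m)),
            class = "simulated_dataset")
}

#' Simulate quantitative traits with controlled differentiation
#'
#' Group effects are drawn with variance `v_among` and accession values add
#' noise with variance `v_within`, so the expected QST is
#' `v_among / (v_among + 2 v_within)`.
#'
#' @param groups group labels.
#' @param v_among,v_within among-/within-group variances.
#' @param n_per_group accessions per group (recycled).
#' @param trait name of the trait column.
#' @return A data frame with `accession`, `group` and one trait column.
#' @export
simulate_traits <- function(groups, v_among, v_within, n_per_group = 30,
                            trait = "trait") {
  stopifnot(v_among >= 0, v_within >= 0)
  n_per_group <- rep_len(n_per_group, length(groups))
  eff <- stats::rnorm(length(groups), 0, sqrt(v_among))
  val <- unlist(lapply(seq_along(groups), function(i)
    eff[i] + stats::rnorm(n_per_group[i], 0, sqrt(v_within))))
  g <- rep(groups, times = n_per_group)
  out <- data.frame(accession = paste0(g, "_", unlist(lapply(n_per_group, seq_len))),
                    group = g, stringsAsFactors = FALSE)
  out[[trait]] <- val
  out
}

#' Prior set for the demographic parameters
#'
#' Defaults: diploid sizes N1, N2, N3, N1b, N2b uniform on \[10, 1e4\];
#' T2 uniform on \[697, 1700\] generations; T1 uniform on \[10, 1700\]
#' truncated to T1 < T2; Db_i uniform on \[1, T_i\]; mean mutation rate
#' uniform on \[1e-4, 1e-3\]; mean geometric coefficient P uniform on
#' \[0.1, 0.3\]; mean SNI rate log-uniform on \[1e-8, 1e-5\]. Per-locus
#' rates are drawn from Gamma(shape 2) around the dataset means, truncated
#' to wide legal supports.
#'
#' @param ... named two-element numeric vectors overriding any of the
#'   default bounds (`N1`, `N2`, `N3`, `N1b`, `N2b`, `T1`, `T2`, `mu`,
#'   `P`, `sni`).
#' @return A `prior_set` object (list of `c(lower, upper)` bounds plus
#'   per-locus truncation bounds).
#' @export
prior_set <- function(...) {
  b <- list(N1 = c(10, 1e4), N2 = c(10, 1e4), N3 = c(10, 1e4),
            N1b = c(10, 1e4), N2b = c(10, 1e4),
            T1 = c(10, 1700), T2 = c(697, 1700),
            mu = c(1e-4, 1e-3), P = c(0.1, 0.3), sni = c(1e-8, 1e-5))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(b)) stop("unknown prior: ", nm)
    stopifnot(length(over[[nm]]) == 2, all(over[[nm]] > 0) || nm == "P")
    b[[nm]] <- over[[nm]]
  }
  if (b$T2[2] <= b$T1[1]) stop("T2 support must allow T2 > T1")
  structure(list(bounds = b,
                 locus_bounds = list(mu = c(1e-6, 1e-2), P = c(0.005, 0.95),
                                     sni = c(1e-9, 1e-4))),
            class = "prior_set")
}

# Gamma(shape 2, mean m) truncated to [lo, hi]
.rgamma_trunc <- function(n, m, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  for (it in 1:200) {
    x <- stats::rgamma(length(todo), shape = 2, scale = m / 2)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  out[todo] <- pmin(pmax(m, lo), hi)
  out
}

#' Draw a parameter vector from the priors
#'
#' Dataset-level means are drawn from their priors (`sni` log-uniformly),
#' with `T2 > T1` enforced by rejection and `Db_i <= T_i` by construction
#' (`Db_i ~ U[1, T_i]`); per-locus mutation parameters are then drawn from
#' Gamma(shape 2) distributions centred on the drawn means, truncated to
#' their legal supports.
#'
#' @param priors a [prior_set()].
#' @param n_loci number of loci (per-locus draws).
#' @return A list with `means` (named numeric vector: N1..N2b, T1, T2,
#'   Db1, Db2, mu, P, sni) and `per_locus` (data frame with columns `mu`,
#'   `P`, `sni`).
#' @export
draw_from_priors <- function(priors, n_loci = 19) {
  b <- priors$bounds
  runifb <- function(nm) stats::runif(1, b[[nm]][1], b[[nm]][2])
  for (it in 1:1000) {
    T2 <- runifb("T2"); T1 <- runifb("T1")
    if (T2 > T1) break
    if (it == 1000) stop("impossible truncation: T2 > T1 unreachable")
  }
  means <- c(N1 = runifb("N1"), N2 = runifb("N2"), N3 = runifb("N3"),
             N1b = runifb("N1b"), N2b = runifb("N2b"),
             T1 = T1, T2 = T2,
             Db1 = stats::runif(1, 1, T1), Db2 = stats::runif(1, 1, T2),
             mu = runifb("mu"), P = runifb("P"),
             sni = exp(stats::runif(1, log(b$sni[1]), log(b$sni[2]))))
  lb <- priors$locus_bounds
  per <- data.frame(
    mu = .rgamma_trunc(n_loci, means[["mu"]], lb$mu[1], lb$mu[2]),
    P = .rgamma_trunc(n_loci, means[["P"]], lb$P[1], lb$P[2]),
    sni = .rgamma_trunc(n_loci, means[["sni"]], lb$sni[1], lb$sni[2]))
  list(means = means, per_locus = per)
}
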