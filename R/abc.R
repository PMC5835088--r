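# Approximate Bayesian computation over the four domestication scenarios:
# summary statistics, reference tables, model choice, regression posteriors,
# model checking and error rates.

.param_names <- c("N1", "N2", "N3", "N1b", "N2b", "T1", "T2", "Db1", "Db2",
                  "mu", "P", "sni")

#' ABC summary-statistic vector
#'
#' Fixed-order statistics for three (or more) groups: per group the mean
#' number of alleles and mean unbiased gene diversity across loci; per
#' unordered group pair the multi-locus Weir-Cockerham FST and Goldstein's
#' `(delta mu)^2` (squared difference of mean allele size in repeat units,
#' averaged over loci). Twelve statistics for three groups.
#'
#' @param gm a [genotype_matrix()]; converted to repeat units internally.
#' @param by grouping passed to [group_labels()] (groups in the order of
#'   first appearance define the vector layout).
#' @return A named numeric vector of class `summary_stat_vector`.
#' @export
abc_summary <- function(gm, by = "population") {
  groups <- group_labels(gm, by)
  gmr <- to_repeat_units(gm)
  glev <- unique(groups)
  if (any(table(groups) == 0)) stop("empty group")
  fc <- .freq_counts(gmr, groups)
  L <- length(fc$counts)
  out <- numeric(0)
  meansize <- matrix(NA_real_, L, length(glev), dimnames = list(NULL, glev))
  for (g in glev) {
    A <- Hs <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      cnt <- fc$counts[[l]][, g]
      if (fc$N[l, g] < 2) next
      A[l] <- sum(cnt > 0)
      Hs[l] <- .hs_unbiased(cnt)
      av <- as.numeric(rownames(fc$counts[[l]]))
      meansize[l, g] <- sum(av * cnt) / fc$N[l, g]
    }
    if (all(is.na(A))) stop("group '", g, "' unusable (all loci missing)")
    out <- c(out, stats::setNames(c(mean(A, na.rm = TRUE), mean(Hs, na.rm = TRUE)),
                                  paste0(c("A_", "Hs_"), g)))
  }
  if (length(glev) >= 2) {
    pr <- utils::combn(glev, 2)
    for (k in seq_len(ncol(pr))) {
      a <- pr[1, k]; b <- pr[2, k]
      sel <- groups %in% c(a, b)
      comp <- vapply(seq_len(L), function(l)
        .wc_locus(gmr$a1[sel, l], gmr$a2[sel, l], groups[sel]), numeric(3))
      denom <- sum(comp)
      if (denom == 0) stop("monomorphic pair ", a, "-", b)
      th <- sum(comp[1, ]) / denom
      dmu2 <- mean((meansize[, a] - meansize[, b])^2, na.rm = TRUE)
      out <- c(out, stats::setNames(c(th, dmu2),
                                    paste0(c("Fst_", "dmu2_"), a, ".", b)))
    }
  }
  if (anyNA(out)) stop("degenerate groups produced NaN statistics")
  class(out) <- c("summary_stat_vector", "numeric")
  out
}

#' Build an ABC reference table
#'
#' Streams draw-from-priors, simulate, summarize for each model; every row
#' records the model id, the generating parameter vector and the summary
#' statistics. Simulation failures are resampled and counted.
#'
#' @param models integer vector of model ids (subset of 1..4).
#' @param priors a [prior_set()].
#' @param n_per_model simulations per model.
#' @param sample_sizes named diploid counts for WC, CC1, CC2.
#' @param n_loci loci per simulated dataset.
#' @param allelic_range bounded ladder width.
#' @return A `reference_table` data frame: `model`, parameter columns,
#'   statistic columns (prefixed `S_`); attributes `stat_names`, `priors`,
#'   `n_failures`.
#' @export
build_reference <- function(models = 1:4, priors = prior_set(),
                            n_per_model = 1000,
                            sample_sizes = c(WC = 30, CC1 = 30, CC2 = 30),
                            n_loci = 19, allelic_range = 40) {
  rows <- vector("list", length(models) * n_per_model)
  ri <- 0; fails <- 0
  for (mid in models) {
    for (s in seq_len(n_per_model)) {
      repeat {
        dr <- draw_from_priors(priors, n_loci)
        spec <- scenario_from_model(mid, as.list(dr$means[1:9]),
                                    sample_sizes = sample_sizes)
        mm <- mutation_model(allelic_range = allelic_range,
                             per_locus = dr$per_locus)
        res <- tryCatch({
          sim <- simulate_dataset(spec, mm, n_loci = n_loci)
          abc_summary(sim$gm, by = "population")
        }, error = function(e) NULL)
        if (!is.null(res)) break
        fails <- fails + 1
        if (fails > 100 + length(models) * n_per_model)
          stop("too many simulation failures")
      }
      ri <- ri + 1
      rows[[ri]] <- c(model = mid, dr$means, stats::setNames(as.numeric(res),
                                                             paste0("S_", names(res))))
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  attr(tab, "stat_names") <- grep("^S_", names(tab), value = TRUE)
  attr(tab, "priors") <- priors
  attr(tab, "n_failures") <- fails
  class(tab) <- c("reference_table", "data.frame")
  tab
}

.ref_stats <- function(ref) {
  as.matrix(ref[, attr(ref, "stat_names"), drop = FALSE])
}

.obs_vec <- function(observed, ref) {
  sn <- attr(ref, "stat_names")
  v <- as.numeric(observed)
  nm <- paste0("S_", names(observed))
  if (!is.null(names(observed)) && all(sn %in% nm)) v <- v[match(sn, nm)]
  if (length(v) != length(sn)) stop("observed vector does not match the reference statistics")
  v
}

#' Prior-predictive pre-evaluation
#'
#' Locates each observed statistic within the simulated cloud (percentile
#' per statistic) and projects the reference and the observation onto the
#' first two principal components; statistics outside the simulated 1-99
#' percentile range are flagged.
#'
#' @param observed an [abc_summary()] vector.
#' @param ref a [build_reference()] table.
#' @return A list: `percentiles` (named), `flagged` (character),
#'   `pca_ref` (scores), `pca_obs`.
#' @export
preevaluate <- function(observed, ref) {
  if (nrow(ref) == 0) stop("empty reference table")
  S <- .ref_stats(ref)
  v <- .obs_vec(observed, ref)
  pct <- vapply(seq_along(v), function(j) mean(S[, j] <= v[j]), numeric(1))
  names(pct) <- colnames(S)
  flagged <- colnames(S)[pct < 0.01 | pct > 0.99]
  mu <- colMeans(S); sdv <- pmax(apply(S, 2, stats::sd), 1e-12)
  Z <- sweep(sweep(S, 2, mu), 2, sdv, `/`)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  zobs <- (v - mu) / sdv
  list(percentiles = pct, flagged = flagged,
       pca_ref = pc$x[, 1:2, drop = FALSE],
       pca_obs = drop(zobs %*% pc$rotation[, 1:2, drop = FALSE]))
}

# retain the tolerance fraction nearest the observed point; returns indices
# and (normalised) distances. min_keep floors the retained count so the
# downstream regressions stay identifiable on scaled-down references.
.abc_retain <- function(observed, ref, tolerance, min_keep = 100) {
  S <- .ref_stats(ref)
  v <- .obs_vec(observed, ref)
  sdv <- pmax(apply(S, 2, stats::sd), 1e-12)
  Z <- sweep(S, 2, sdv, `/`)
  z <- v / sdv
  d <- sqrt(rowSums(sweep(Z, 2, z)^2))
  ntol <- max(2, min(nrow(ref), max(min_keep, ceiling(tolerance * nrow(ref)))))
  idx <- order(d)[seq_len(ntol)]
  list(idx = idx, dist = d[idx], dmax = max(d[idx]), sdv = sdv)
}

#' ABC model choice: rejection and polychotomous logistic regression
#'
#' Retains the `tolerance` fraction of simulations nearest the observed
#' statistics (Euclidean distance on reference-standardised statistics).
#' The rejection estimate is the model frequency among retained rows; the
#' regression estimate fits a multinomial logistic regression of the model
#' id on linear-discriminant projections of the statistics (Epanechnikov
#' distance weights) and evaluates it at the observed point.
#'
#' @param observed an [abc_summary()] vector.
#' @param ref a [build_reference()] table (>= 2 models for the regression).
#' @param tolerance retained fraction (default 0.01).
#' @return A `model_posterior` list: `rejection`, `logistic` (named
#'   probability vectors summing to 1), `tolerance`, `n_retained`.
#' @export
select_model <- function(observed, ref, tolerance = 0.01) {
  models <- sort(unique(ref$model))
  ret <- .abc_retain(observed, ref, tolerance)
  retm <- factor(ref$model[ret$idx], levels = models)
  rej <- as.numeric(table(retm)) / length(ret$idx)
  names(rej) <- models
  if (any(rej == 0))
    warning("model(s) absent from the retained set: ",
            paste(models[rej == 0], collapse = ", "))
  logi <- rej
  if (length(models) > 1 && length(unique(retm)) > 1) {
    S <- .ref_stats(ref)[ret$idx, , drop = FALSE]
    v <- .obs_vec(observed, ref)
    w <- 1 - (ret$dist / max(ret$dmax, 1e-12))^2
    w <- pmax(w, 1e-6)
    logi <- tryCatch({
      ld <- MASS::lda(x = S, grouping = retm)
      proj <- as.matrix(S) %*% ld$scaling
      pobs <- matrix(v, 1) %*% ld$scaling
      df <- data.frame(mod = retm, proj)
      fit <- nnet::multinom(mod ~ ., data = df, weights = w, trace = FALSE,
                            maxit = 200)
      nd <- as.data.frame(pobs)
      colnames(nd) <- colnames(proj)
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      out <- stats::setNames(rep(0, length(models)), models)
      if (is.matrix(pr)) {
        out[colnames(pr)] <- as.numeric(pr[1, ])
      } else if (length(pr) > 1) {
        out[names(pr)] <- as.numeric(pr)
      } else {
        # two retained model levels: probability of the second level
        lev <- levels(droplevels(retm))
        out[lev[1]] <- 1 - pr
        out[lev[2]] <- pr
      }
      out
    }, error = function(e) rej)
    logi <- logi / sum(logi)
  }
  structure(list(rejection = rej, logistic = logi, tolerance = tolerance,
                 n_retained = length(ret$idx)), class = "model_posterior")
}

.logit <- function(x) log(x / (1 - x))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# weighted quantiles (type-7-like on the weighted ECDF)
.wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Local-linear-regression parameter posteriors
#'
#' Beaumont-style adjustment: the retained parameters are logit-transformed
#' to their prior bounds, regressed on the standardised statistics with
#' Epanechnikov weights by distance, adjusted to the observed point and
#' back-transformed. Falls back to plain rejection quantiles when the
#' regression is singular.
#'
#' @param observed an [abc_summary()] vector.
#' @param ref a [build_reference()] table.
#' @param model model id whose rows are used.
#' @param tolerance retained fraction within the model's rows.
#' @return A `param_posterior` list: `summary` data frame (`parameter`,
#'   `median`, `q025`, `q975`), `adjusted` (matrix of adjusted draws),
#'   `weights`, `fallback` flag.
#' @export
estimate_params <- function(observed, ref, model, tolerance = 0.01) {
  sub <- ref[ref$model == model, , drop = FALSE]
  for (a in c("stat_names", "priors")) attr(sub, a) <- attr(ref, a)
  if (nrow(sub) < 100 / tolerance)
    warning("fewer than ", ceiling(100 / tolerance),
            " rows for stable regression")
  ret <- .abc_retain(observed, sub, tolerance, min_keep = 200)
  S <- .ref_stats(sub)[ret$idx, , drop = FALSE]
  v <- .obs_vec(observed, sub)
  sdv <- ret$sdv
  Z <- sweep(S, 2, sdv, `/`)
  z <- v / sdv
  w <- pmax(1 - (ret$dist / max(ret$dmax, 1e-12))^2, 1e-6)
  priors <- attr(ref, "priors")
  pars <- as.matrix(sub[ret$idx, .param_names, drop = FALSE])
  # parameter bounds for the logit transform (from the prior supports,
  # padded so boundary draws stay finite)
  bnd <- vapply(.param_names, function(p) {
    x <- sub[[p]]
    r <- range(x)
    pad <- 1e-8 + 1e-6 * diff(r)
    c(r[1] - pad, r[2] + pad)
  }, numeric(2))
  adj <- matrix(NA_real_, nrow(pars), ncol(pars),
                dimnames = list(NULL, .param_names))
  fallback <- FALSE
  X <- cbind(1, sweep(Z, 2, z))  # regression in centred statistic space
  for (j in seq_len(ncol(pars))) {
    lo <- bnd[1, j]; hi <- bnd[2, j]
    y <- .logit((pars[, j] - lo) / (hi - lo))
    fit <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      adj[, j] <- pars[, j]
      fallback <- TRUE
    } else {
      # value at the observed point + residuals
      ystar <- fit$coefficients[1] + fit$residuals
      adj[, j] <- lo + (hi - lo) * .inv_logit(ystar)
    }
  }
  qs <- t(apply(adj, 2, .wquantile, w = w, probs = c(0.5, 0.025, 0.975)))
  structure(list(
    summary = data.frame(parameter = .param_names, median = qs[, 1],
                         q025 = qs[, 2], q975 = qs[, 3],
                         stringsAsFactors = FALSE, row.names = NULL),
    adjusted = adj, weights = w, fallback = fallback,
    model = model), class = "param_posterior")
}

#' Posterior-predictive model check
#'
#' Simulates datasets at parameter vectors drawn (with weights) from the
#' adjusted posterior sample and reports, per summary statistic, the
#' fraction of simulated values at or above the observed one; values
#' outside (0.025, 0.975) are flagged.
#'
#' @param fitted an [estimate_params()] result.
#' @param observed the observed [abc_summary()] vector.
#' @param n_rep posterior-predictive simulations.
#' @param sample_sizes,n_loci,allelic_range simulation layout (match the
#'   reference).
#' @return A data frame: `stat`, `p`, `flagged`.
#' @export
model_check <- function(fitted, observed, n_rep = 100,
                        sample_sizes = c(WC = 30, CC1 = 30, CC2 = 30),
                        n_loci = 19, allelic_range = 40) {
  adj <- fitted$adjusted
  w <- fitted$weights / sum(fitted$weights)
  sims <- matrix(NA_real_, n_rep, length(observed))
  kept <- 0
  for (r in seq_len(n_rep)) {
    i <- sample.int(nrow(adj), 1, prob = w)
    p <- as.list(adj[i, ])
    res <- tryCatch({
      spec <- scenario_from_model(fitted$model, p[1:9], sample_sizes)
      mm <- mutation_model(mu = p$mu, P = min(p$P, 0.95), sni = p$sni,
                           allelic_range = allelic_range)
      sim <- simulate_dataset(spec, mm, n_loci = n_loci)
      as.numeric(abc_summary(sim$gm))
    }, error = function(e) NULL)
    if (!is.null(res)) { kept <- kept + 1; sims[kept, ] <- res }
  }
  sims <- sims[seq_len(kept), , drop = FALSE]
  pv <- vapply(seq_along(observed), function(j)
    mean(sims[, j] >= as.numeric(observed)[j]), numeric(1))
  data.frame(stat = names(observed), p = pv,
             flagged = pv < 0.025 | pv > 0.975, stringsAsFactors = FALSE)
}

#' Model-choice error rates from pseudo-observed datasets
#'
#' Simulates pseudo-observed datasets under every model from the priors and
#' assigns each by highest posterior probability against the reference.
#' Type I error: fraction of focal-model pods not assigned to the focal
#' model. Mean type II error: mean, over the other models, of the fraction
#' of their pods assigned to the focal model.
#'
#' @param ref a [build_reference()] table.
#' @param n_pods pods per model.
#' @param focal_model focal model id (default 2).
#' @param tolerance retention fraction for [select_model()].
#' @param method `"logistic"` or `"rejection"` assignment.
#' @return A list: `type_I`, `mean_type_II`, `assignment` (confusion
#'   matrix, rows = generating model).
#' @export
confusion_errors <- function(ref, n_pods = 50, focal_model = 2,
                             tolerance = 0.01, method = c("logistic", "rejection")) {
  method <- match.arg(method)
  models <- sort(unique(ref$model))
  priors <- attr(ref, "priors")
  sn <- attr(ref, "stat_names")
  n_loci_guess <- 19
  conf <- matrix(0, length(models), length(models),
                 dimnames = list(models, models))
  for (mid in models) {
    for (s in seq_len(n_pods)) {
      repeat {
        dr <- draw_from_priors(priors, n_loci_guess)
        res <- tryCatch({
          spec <- scenario_from_model(mid, as.list(dr$means[1:9]))
          mm <- mutation_model(per_locus = dr$per_locus)
          sim <- simulate_dataset(spec, mm, n_loci = n_loci_guess)
          abc_summary(sim$gm)
        }, error = function(e) NULL)
        if (!is.null(res)) break
      }
      mp <- select_model(res, ref, tolerance)
      pp <- if (method == "logistic") mp$logistic else mp$rejection
      win <- models[which.max(pp)]
      conf[as.character(mid), as.character(win)] <-
        conf[as.character(mid), as.character(win)] + 1
    }
  }
  conf <- conf / n_pods
  fi <- as.character(focal_model)
  type1 <- 1 - conf[fi, fi]
  others <- setdiff(rownames(conf), fi)
  type2 <- mean(conf[others, fi])
  list(type_I = type1, mean_type_II = type2, assignment = conf)
}

#' Convert generations to calendar years
#'
#' Years = generations x generation time, rounded half-up to the nearest
#' integer for reporting (internal arithmetic is unrounded).
#'
#' @param g generations (>= 0).
#' @param generation_time years per generation (default 4.5, the mean for a
#'   perennial tree with a 3-6 year juvenile phase).
#' @return Integer years.
#' @export
generations_to_years <- function(g, generation_time = 4.5) {
  if (any(g < 0)) stop("negative generations")
  floor(g * generation_time + 0.5)
}
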