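# Directional relative migration networks (divMigrate-style Nm method).

# Nei's multi-locus G_ST between two frequency profiles given as lists of
# per-locus frequency vectors aligned on common allele sets
.gst_profiles <- function(fx, fy) {
  hs <- ht <- numeric(length(fx))
  for (l in seq_along(fx)) {
    x <- fx[[l]]; y <- fy[[l]]
    hs[l] <- 0.5 * ((1 - sum(x^2)) + (1 - sum(y^2)))
    m <- (x + y) / 2
    ht[l] <- 1 - sum(m^2)
  }
  Hs <- mean(hs); Ht <- mean(ht)
  if (Ht <= 0) return(NA_real_)
  (Ht - Hs) / Ht
}

# Wright island-model transform, isolated so a refined Nm estimator can be
# swapped in
.gst_to_nm <- function(gst) {
  if (is.na(gst) || gst <= 0) return(Inf)
  (1 / gst - 1) / 4
}

.group_freq_profiles <- function(freqs) {
  cnts <- attr(freqs, "counts")
  N <- attr(freqs, "N")
  glev <- attr(freqs, "groups")
  lapply(stats::setNames(glev, glev), function(g) {
    lapply(seq_along(cnts), function(l) {
      if (N[l, g] == 0) return(NULL)
      cnts[[l]][, g] / N[l, g]
    })
  })
}

# point-estimate edge table
.nm_edges <- function(profiles, glev) {
  pairs <- expand.grid(from = glev, to = glev, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  nm <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- profiles[[pairs$from[r]]]
    b <- profiles[[pairs$to[r]]]
    shared <- which(!vapply(a, is.null, logical(1)) &
                    !vapply(b, is.null, logical(1)))
    if (!length(shared)) { nm[r] <- NA; next }
    # hypothetical pooled population: unweighted mean of the two profiles
    pool <- lapply(shared, function(l) (a[[l]] + b[[l]]) / 2)
    # directional Nm a->b: differentiation of the recipient b from the pool
    gst <- .gst_profiles(b[shared], pool)
    nm[r] <- .gst_to_nm(gst)
  }
  pairs$Nm <- nm
  finite <- is.finite(nm)
  mx <- if (any(finite)) max(nm[finite]) else NA_real_
  pairs$relative <- ifelse(is.finite(nm), nm / mx, ifelse(is.na(nm), NA, 1))
  if (all(is.infinite(nm[!is.na(nm)]))) pairs$relative[!is.na(nm)] <- 1
  pairs
}

#' Directional relative migration network
#'
#' For each ordered pair of groups (a, b), a hypothetical pooled population
#' is built with allele frequencies equal to the unweighted mean of the two
#' groups; the directional migration into b is the Wright island-model
#' transform `Nm = (1/G_ST - 1)/4` of Nei's G_ST between b and the pool.
#' Relative migration divides all ordered edges by the maximum.
#'
#' @param freqs an [allele_frequencies()] table (>= 2 groups).
#' @return A `migration_network`: data frame of ordered edges (`from`,
#'   `to`, `Nm`, `relative`).
#' @export
directional_migration <- function(freqs) {
  glev <- attr(freqs, "groups")
  if (length(glev) < 2) stop("need >= 2 groups")
  profiles <- .group_freq_profiles(freqs)
  out <- .nm_edges(profiles, glev)
  rownames(out) <- NULL
  class(out) <- c("migration_network", "data.frame")
  out
}

#' Bootstrap a migration network
#'
#' Individuals are resampled with replacement within groups; an ordered
#' pair's directional asymmetry is significant when the bootstrap
#' percentile intervals of the two directions' relative migration do not
#' overlap at level `alpha`.
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping passed to [group_labels()].
#' @param n_boot bootstrap replicates (>= 100).
#' @param alpha significance level for the percentile intervals.
#' @return A `migration_network` with columns `ci_low`, `ci_high` and
#'   `significant` added.
#' @export
bootstrap_network <- function(gm, by = "population", n_boot = 1000,
                              alpha = 0.05) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  groups <- group_labels(gm, by)
  if (any(table(groups) < 2)) stop("groups must have >= 2 accessions")
  point <- directional_migration(allele_frequencies(gm, groups))
  boot_rel <- matrix(NA_real_, n_boot, nrow(point))
  idx_by_group <- split(seq_along(groups), groups)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_group, function(ii)
      sample(ii, length(ii), replace = TRUE)))
    gmb <- gm[idx, ]
    net <- directional_migration(allele_frequencies(gmb, groups[idx]))
    key <- paste(net$from, net$to)
    boot_rel[b, ] <- net$relative[match(paste(point$from, point$to), key)]
  }
  point$ci_low <- apply(boot_rel, 2, stats::quantile,
                        probs = alpha / 2, na.rm = TRUE)
  point$ci_high <- apply(boot_rel, 2, stats::quantile,
                         probs = 1 - alpha / 2, na.rm = TRUE)
  sig <- logical(nrow(point))
  for (r in seq_len(nrow(point))) {
    rev <- which(point$from == point$to[r] & point$to == point$from[r])
    sig[r] <- length(rev) == 1 &&
      (point$ci_low[r] > point$ci_high[rev] ||
       point$ci_high[r] < point$ci_low[rev])
  }
  point$significant <- sig
  point
}

#' Filter migration edges by relative strength
#'
#' Keeps edges whose relative migration is strictly over the threshold
#' (an edge exactly at the threshold is removed).
#'
#' @param net a `migration_network`.
#' @param min_relative threshold (default 0.35).
#' @return The filtered network.
#' @export
filter_edges <- function(net, min_relative = 0.35) {
  out <- net[!is.na(net$relative) & net$relative > min_relative, , drop = FALSE]
  rownames(out) <- NULL
  out
}
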