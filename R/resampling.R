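# Resampling statistics: breakpoint-spacer proximity shuffle test, RF
# topology-shift test, allelic vs non-allelic permutation test, and
# boundary feature enrichment simulation.
#
# All empirical p-values use the add-one rule
# p = (1 + #{null at least as extreme}) / (n_perm + 1), which can never
# return 0 and is exactly uniform on its support under an exchangeable
# null.

perm_result <- function(observed, null, alternative, seed, ...) {
  extreme <- switch(alternative,
                    less = sum(null <= observed),
                    greater = sum(null >= observed),
                    two.sided = sum(abs(null) >= abs(observed)))
  res <- list(observed = observed, null = null,
              p = (1 + extreme) / (length(null) + 1),
              alternative = alternative, n_perm = length(null),
              seed = seed, ...)
  class(res) <- "perm_result"
  res
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %.6g, p = %.4g (n_perm = %d)\n",
              x$alternative, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Breakpoint-to-spacer proximity shuffle test
#'
#' Tests whether exchange breakpoints lie closer to SD spacers than
#' expected by chance. The observed statistic is the mean nearest-spacer
#' distance over breakpoints; each null replicate redraws every
#' breakpoint uniformly within its own cap and recomputes the mean
#' (alternative "less": closer than expected). A one-sided Wilcoxon
#' rank-sum comparison of the observed per-breakpoint distances against
#' the pooled null distances is reported alongside as `p_wilcoxon`.
#'
#' @param breakpoints data.frame with `seq_id` (cap) and `pos` columns.
#' @param spacers spacer intervals across the caps.
#' @param cap_extents interval data.frame giving each cap's extent.
#' @param n_perm shuffle replicates.
#' @param seed integer seed.
#' @return a `perm_result` with extra fields `distances` and
#'   `p_wilcoxon`.
#' @export
breakpoint_shuffle_test <- function(breakpoints, spacers, cap_extents,
                                    n_perm = 1000, seed = 1) {
  stopifnot(nrow(breakpoints) >= 1)
  ext <- cap_extents[match(breakpoints$seq_id, cap_extents$seq_id), ]
  if (any(is.na(ext$start)) || any(breakpoints$pos < ext$start) ||
      any(breakpoints$pos >= ext$end)) {
    stop("breakpoint outside its cap extent", call. = FALSE)
  }
  dist_for <- function(cap, pos) {
    sp <- spacers[spacers$seq_id == cap, , drop = FALSE]
    nearest_spacer_distance(pos, sp)
  }
  obs_d <- unlist(lapply(unique(breakpoints$seq_id), function(cap) {
    dist_for(cap, breakpoints$pos[breakpoints$seq_id == cap])
  }))
  observed <- mean(obs_d)
  null <- with_seed(seed, {
    draws <- matrix(NA_real_, nrow(breakpoints), n_perm)
    for (i in seq_len(nrow(breakpoints))) {
      draws[i, ] <- floor(runif(n_perm, ext$start[i], ext$end[i]))
    }
    null_d <- matrix(NA_real_, nrow(breakpoints), n_perm)
    for (cap in unique(breakpoints$seq_id)) {
      rows <- which(breakpoints$seq_id == cap)
      sp <- spacers[spacers$seq_id == cap, , drop = FALSE]
      null_d[rows, ] <- matrix(nearest_spacer_distance(as.numeric(draws[rows, ]),
                                                       sp),
                               length(rows), n_perm)
    }
    list(means = colMeans(null_d), all = as.numeric(null_d))
  })
  pw <- suppressWarnings(wilcox.test(obs_d, null$all,
                                     alternative = "less")$p.value)
  perm_result(observed, null$means, "less", seed,
              distances = obs_d, p_wilcoxon = pw)
}

#' Phylogenetic topology-shift test for recombination
#'
#' Splits the alignment into two equal halves and asks whether each
#' half's tree topology is shifted away from the full-alignment signal
#' more than resampling noise allows. Replicate trees are built from
#' resampled columns of the full alignment and their majority consensus
#' is the reference topology; the null sample is the RF distance of each
#' replicate tree to that consensus, and the observed statistics are the
#' RF distances of the two half-alignment trees to the same consensus
#' (one-sided "greater", add-one rule).
#'
#' With the default `null = "half_subsample"`, replicates draw
#' `ceiling(L/2)` columns without replacement -- exactly the sampling
#' process that produces a half alignment under a homogeneous null -- so
#' the observed and null statistics are exchangeable and the p-value is
#' calibrated. `null = "full_bootstrap"` uses classic full-length
#' bootstrap replicates instead; its null trees are noisier-centred on
#' their own consensus, which makes the p conservative or
#' anti-conservative depending on signal strength.
#'
#' @param msa alignment (>= 4 tips).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param model distance model.
#' @param null replicate design for the null sample (see Details).
#' @return list with `p_first_half`, `p_second_half`, `observed` (RF of
#'   each half tree), `null` (RF sample), `consensus`, and the two half
#'   trees.
#' @export
topology_shift_test <- function(msa, n_boot = 1000, seed = 1,
                                model = "JC",
                                null = c("half_subsample",
                                         "full_bootstrap")) {
  null <- match.arg(null)
  m <- as_msa(msa)
  stopifnot(nrow(m) >= 4)
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    stop("no phylogenetic signal: all sequences identical", call. = FALSE)
  }
  L <- ncol(m)
  half <- ceiling(L / 2)
  t1 <- build_nj_tree(compute_distances(m[, 1:half, drop = FALSE], model))
  t2 <- build_nj_tree(compute_distances(m[, (half + 1):L, drop = FALSE],
                                        model))
  bc <- if (null == "half_subsample") {
    bootstrap_consensus(m, n_boot = n_boot, seed = seed, model = model,
                        resample_cols = half, replace = FALSE)
  } else {
    bootstrap_consensus(m, n_boot = n_boot, seed = seed, model = model)
  }
  cons_keys <- tree_bipartitions(bc$consensus)
  rf_to_cons <- function(tr) {
    b <- tree_bipartitions(tr)
    length(setdiff(b, cons_keys)) + length(setdiff(cons_keys, b))
  }
  null <- vapply(bc$replicates, rf_to_cons, numeric(1))
  obs <- c(first = rf_to_cons(t1), second = rf_to_cons(t2))
  list(p_first_half = (1 + sum(null >= obs[1])) / (n_boot + 1),
       p_second_half = (1 + sum(null >= obs[2])) / (n_boot + 1),
       observed = obs, null = null, consensus = bc$consensus,
       tree_first = t1, tree_second = t2, n_boot = n_boot, seed = seed)
}

#' Permutation test for a difference of group mean identities
#'
#' Two-sided label-permutation test on the difference of group means,
#' e.g. allelic vs non-allelic cap pair identities.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return a `perm_result` (alternative "two.sided").
#' @export
group_identity_permutation_test <- function(values_a, values_b,
                                            n_perm = 10000, seed = 1) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  observed <- mean(values_a) - mean(values_b)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1))
  })
  perm_result(observed, null, "two.sided", seed)
}

# coverage function of sorted disjoint intervals: total covered bp in
# [0, x) per chromosome; used for fast overlap under permutation
flatten_targets <- function(targets) {
  lapply(split(targets, targets$seq_id), function(t) {
    ir <- IRanges::reduce(IRanges::IRanges(t$start + 1, t$end))
    s <- IRanges::start(ir) - 1; e <- IRanges::end(ir)
    list(s = s, e = e, cum = c(0, cumsum(e - s)))
  })
}

cov_at <- function(ft, x) {
  j <- findInterval(x, ft$s)
  ifelse(j == 0, 0, ft$cum[pmax(j, 1)] +
           pmin(pmax(x - ft$s[pmax(j, 1)], 0), ft$e[pmax(j, 1)] -
                  ft$s[pmax(j, 1)]))
}

# per-feature overlap bp with flattened targets (same chromosome)
feat_overlap_bp <- function(ft, s, e) cov_at(ft, e) - cov_at(ft, s)

#' Feature enrichment permutation test
#'
#' Tests whether features (genes, SDs, insertions) are enriched in target
#' regions (e.g. 2 Mbp cap boundaries). The observed statistic is the
#' number of features overlapping targets (`mode = "count"`) or the
#' total overlap (`mode = "bp"`); each null replicate repositions every
#' feature uniformly on its own chromosome with length preserved
#' (one-sided "greater"). The fold change is the feature density inside
#' targets over the genome-wide density.
#'
#' @param features,targets interval data.frames on shared chromosome
#'   names.
#' @param genome_sizes named numeric vector of chromosome lengths.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param mode "count" or "bp".
#' @return list with `fold` and `result` (a `perm_result`).
#' @export
feature_enrichment_test <- function(features, targets, genome_sizes,
                                    n_perm = 1000, seed = 1,
                                    mode = c("count", "bp")) {
  mode <- match.arg(mode)
  stopifnot(all(features$seq_id %in% names(genome_sizes)),
            all(targets$seq_id %in% names(genome_sizes)))
  ft <- flatten_targets(targets)
  stat <- function(s, e, chrom) {
    ov <- numeric(length(s))
    for (cn in unique(chrom)) {
      idx <- chrom == cn
      ov[idx] <- if (cn %in% names(ft)) {
        feat_overlap_bp(ft[[cn]], s[idx], e[idx])
      } else 0
    }
    if (mode == "count") sum(ov > 0) else sum(ov)
  }
  observed <- stat(features$start, features$end, features$seq_id)
  len <- features$end - features$start
  sizes <- genome_sizes[features$seq_id]
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ns <- floor(runif(nrow(features), 0, pmax(1, sizes - len)))
      stat(ns, ns + len, features$seq_id)
    }, numeric(1))
  })
  res <- perm_result(observed, null, "greater", seed)
  target_bp <- sum(vapply(ft, function(f) f$cum[length(f$cum)], numeric(1)))
  genome_bp <- sum(genome_sizes)
  dens_in <- if (mode == "count") observed / target_bp else
    observed / target_bp
  dens_all <- if (mode == "count") nrow(features) / genome_bp else
    sum(len) / genome_bp
  list(fold = dens_in / dens_all, result = res)
}
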