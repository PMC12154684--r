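# Distance-based phylogenetics for SD spacers: p/JC distances with
# pairwise deletion, neighbor-joining, bootstrap + majority-rule
# consensus, Robinson-Foulds distances, and strict-clock calibration.

#' Coerce sequences to an alignment matrix
#'
#' @param x named character vector of equal-length aligned sequences over
#'   A/C/G/T/N/-, or an already-built character matrix (tips x sites).
#' @return character matrix with one row per tip.
#' @export
as_msa <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(!is.null(names(x)))
  L <- unique(nchar(x))
  if (length(L) != 1) stop("alignment rows differ in length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' Pairwise distances from an alignment
#'
#' Sites with a gap or N in either row of a pair are excluded (pairwise
#' deletion). `model = "p"` returns the raw proportion of mismatches;
#' `model = "JC"` applies the Jukes-Cantor correction
#' `d = -(3/4) * log(1 - 4p/3)`.
#'
#' @param msa alignment ([as_msa()] input).
#' @param model "JC" or "p".
#' @return a `dist` object.
#' @export
compute_distances <- function(msa, model = c("JC", "p")) {
  model <- match.arg(model)
  m <- as_msa(msa)
  n <- nrow(m)
  stopifnot(n >= 2)
  ok <- m %in% DNA_BASES
  dim(ok) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     rownames(m)[i], rownames(m)[j]), call. = FALSE)
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (model == "JC") {
        if (p >= 0.75) {
          stop(sprintf("JC distance undefined (p >= 0.75) between '%s' and '%s'",
                       rownames(m)[i], rownames(m)[j]), call. = FALSE)
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  as.dist(d)
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining on a distance matrix; negative estimated
#' branch lengths are clamped to zero.
#'
#' @param D a `dist` or symmetric matrix, n >= 3 taxa.
#' @return an unrooted `phylo`.
#' @export
build_nj_tree <- function(D) {
  D <- as.dist(D)
  stopifnot(attr(D, "Size") >= 3)
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# canonical keys for the non-trivial bipartitions of a tree: each key is
# the sorted tip-label set of the side NOT containing the alphabetically
# first tip, joined with "|"
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4) return(character(0))
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the non-trivial bipartition sets
#' of two trees on the same tips; `normalized = TRUE` divides by
#' `2 * (n - 3)`.
#'
#' @param t1,t2 `phylo` objects with identical tip sets.
#' @param normalized return the value scaled to `[0,1]`.
#' @return integer count, or a fraction when normalized.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different tip sets", call. = FALSE)
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n <= 3) return(0)
    return(rf / (2 * (n - 3)))
  }
  rf
}

#' Bootstrap replicate trees and majority-rule consensus
#'
#' Columns are resampled with replacement `n_boot` times; a
#' neighbor-joining tree is built per replicate, and the strict
#' majority-rule (>50 percent) consensus is returned with per-clade
#' supports (bipartition frequencies x 100) as node labels.
#'
#' @param msa alignment.
#' @param n_boot number of replicates (honored exactly).
#' @param seed integer seed.
#' @param model distance model passed to [compute_distances()].
#' @param resample_cols number of columns drawn per replicate (defaults
#'   to the alignment length).
#' @param replace draw columns with replacement (classic bootstrap,
#'   default) or without (subsampling/jackknife replicates).
#' @return list with `replicates` (list of `phylo`) and `consensus`
#'   (`phylo`, node labels = supports; root label empty).
#' @export
bootstrap_consensus <- function(msa, n_boot = 100, seed = 1, model = "JC",
                                resample_cols = NULL, replace = TRUE) {
  stopifnot(n_boot >= 1)
  m <- as_msa(msa)
  L <- ncol(m)
  if (is.null(resample_cols)) resample_cols <- L
  n <- nrow(m)
  pairs <- t(utils::combn(n, 2))
  use_fast <- nrow(pairs) * L <= 5e7
  if (use_fast) {
    # per-pair site indicators so each replicate is a matrix product
    ok <- m %in% DNA_BASES
    dim(ok) <- dim(m)
    CM <- ok[pairs[, 1], , drop = FALSE] & ok[pairs[, 2], , drop = FALSE]
    MM <- CM & (m[pairs[, 1], , drop = FALSE] != m[pairs[, 2], , drop = FALSE])
    storage.mode(CM) <- "double"
    storage.mode(MM) <- "double"
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(L, resample_cols, replace = replace)
      if (use_fast) {
        w <- tabulate(idx, L)
        den <- as.numeric(CM %*% w)
        if (any(den == 0)) {
          stop("no comparable sites in a bootstrap replicate", call. = FALSE)
        }
        p <- as.numeric(MM %*% w) / den
        if (model == "JC") {
          if (any(p >= 0.75)) {
            stop("JC distance undefined (p >= 0.75) in a bootstrap replicate",
                 call. = FALSE)
          }
          p <- -0.75 * log(1 - 4 * p / 3)
        }
        D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
        D[pairs] <- p
        build_nj_tree(as.dist(D + t(D)))
      } else {
        build_nj_tree(compute_distances(m[, idx, drop = FALSE], model))
      }
    })
  })
  cons <- ape::consensus(reps, p = 0.5)
  keys <- lapply(reps, tree_bipartitions)
  tab <- table(unlist(keys))
  # per-internal-node support on the consensus
  labs <- cons$tip.label
  n <- length(labs)
  ref <- sort(labs)[1]
  pp <- ape::prop.part(cons)
  node_lab <- character(cons$Nnode)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) < 2 || length(side) > n - 2) { node_lab[i] <- ""; next }
    if (ref %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    f <- if (key %in% names(tab)) 100 * tab[[key]] / n_boot else 0
    node_lab[i] <- formatC(f, format = "fg")
  }
  cons$node.label <- node_lab
  list(replicates = reps, consensus = cons)
}

# balanced node-to-tip height: each node's height is the mean over its
# children of (edge length + child height), so each child subtree
# contributes equally regardless of its tip count (under a clock every
# child side estimates the same age, and this keeps an outgroup's long
# basal branch from biasing the root height)
node_heights <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  h <- numeric(nnode)      # per-node balanced depth to tips
  s <- numeric(nnode)      # running child sums
  cnt <- integer(nnode)
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    if (ch > ntip && cnt[ch] > 0) h[ch] <- s[ch] / cnt[ch]
    s[p] <- s[p] + eo$edge.length[i] + h[ch]
    cnt[p] <- cnt[p] + 1L
  }
  root <- ntip + 1L
  h[root] <- s[root] / cnt[root]
  h[(ntip + 1):nnode]
}

#' Calibrate a tree to absolute time under a strict clock
#'
#' Roots the tree on the outgroup, computes node heights (mean node-to-tip
#' path length, substitutions/site), and fits a single substitution rate
#' by least squares over the calibrated nodes (`height ~ rate * age`).
#' Node ages are `height / rate`, tips are at age 0, and branch lengths of
#' the returned tree are rescaled to million years. When bootstrap
#' replicate trees are supplied, each is calibrated the same way and the
#' 2.5/97.5 percentiles of each node's replicate ages form its CI (nodes
#' are matched across replicates by their descendant tip set).
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param outgroup tip label(s) to root on.
#' @param calibrations list of `list(tips = c(...), age = MY)` entries;
#'   each node is the MRCA of its tip set after rooting.
#' @param boot_trees optional list of replicate trees (e.g. from
#'   [bootstrap_consensus()]).
#' @return list with `tree` (rooted, branch lengths in MY), `rate`
#'   (substitutions/site/MY), and `ages` (data.frame: node id, member
#'   key, age, and CI bounds when replicates were given).
#' @export
calibrate_tree <- function(tree, outgroup, calibrations,
                           boot_trees = NULL) {
  stopifnot(all(outgroup %in% tree$tip.label), length(calibrations) >= 1)
  for (cal in calibrations) {
    if (!all(cal$tips %in% tree$tip.label)) {
      stop("calibration node not present: tips ",
           paste(setdiff(cal$tips, tree$tip.label), collapse = ","),
           call. = FALSE)
    }
  }
  fit_one <- function(tr) {
    rt <- ape::root(tr, outgroup, resolve.root = TRUE)
    h <- node_heights(rt)
    ntip <- length(rt$tip.label)
    hc <- vapply(calibrations, function(cal) {
      node <- if (length(cal$tips) == 1) {
        stop("calibration needs >= 2 tips", call. = FALSE)
      } else ape::getMRCA(rt, cal$tips)
      h[node - ntip]
    }, numeric(1))
    ages <- vapply(calibrations, `[[`, numeric(1), "age")
    r <- sum(hc * ages) / sum(ages^2)
    list(tree = rt, h = h, rate = r)
  }
  main <- fit_one(tree)
  rt <- main$tree
  ntip <- length(rt$tip.label)
  pp <- ape::prop.part(rt)
  keys <- vapply(pp, function(cl) paste(sort(rt$tip.label[cl]),
                                        collapse = "|"), "")
  ages <- main$h / main$rate
  out <- data.frame(node = ntip + seq_along(ages), members = keys,
                    age = ages)
  if (!is.null(boot_trees)) {
    boot_ages <- matrix(NA_real_, length(boot_trees), length(ages))
    for (b in seq_along(boot_trees)) {
      fb <- fit_one(boot_trees[[b]])
      nb <- length(fb$tree$tip.label)
      for (i in seq_along(pp)) {
        tips <- rt$tip.label[pp[[i]]]
        node <- if (length(tips) >= 2) ape::getMRCA(fb$tree, tips) else NA
        if (!is.na(node)) {
          boot_ages[b, i] <- fb$h[node - nb] / fb$rate
        }
      }
    }
    out$ci_lo <- apply(boot_ages, 2, quantile, 0.025, na.rm = TRUE)
    out$ci_hi <- apply(boot_ages, 2, quantile, 0.975, na.rm = TRUE)
  }
  cal_tree <- rt
  cal_tree$edge.length <- rt$edge.length / main$rate
  list(tree = cal_tree, rate = main$rate, ages = out)
}

#' Mean terminal branch length
#'
#' Arithmetic mean of the terminal (tip) branch lengths over a tip
#' subset; on a calibrated tree the value is in million years.
#'
#' @param tree a `phylo`.
#' @param tips tip labels (default: all).
#' @return mean branch length.
#' @export
terminal_branch_mean <- function(tree, tips = tree$tip.label) {
  stopifnot(all(tips %in% tree$tip.label))
  idx <- match(tips, tree$tip.label)
  e <- match(idx, tree$edge[, 2])
  mean(tree$edge.length[e])
}
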