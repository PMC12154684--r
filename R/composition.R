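# Cap x variant composition matrix, hierarchical clustering of caps with
# bootstrap support, and the two-step k-means higher-order block typing.

#' Build the cap x variant composition matrix
#'
#' Rows are caps with at least `min_units_per_cap` satellite units
#' (mirrors the "at least 2,000 pChts" screen); columns are variants with
#' global count strictly greater than `min_variant_count` (the "n>100"
#' abundance screen). Each cell is the count of the variant in the cap
#' divided by the total number of units in that cap -- all units, so row
#' sums can be below 1 when rare variants are filtered from the columns.
#'
#' @param catalog a `variant_catalog` (from [classify_variants()] or
#'   [simulate_variant_catalog()]).
#' @param min_variant_count global-count threshold (strict).
#' @param min_units_per_cap per-cap unit threshold (inclusive).
#' @return numeric matrix, caps x variants.
#' @export
build_composition_matrix <- function(catalog, min_variant_count = 100,
                                     min_units_per_cap = 2000) {
  counts <- catalog$counts
  totals <- rowSums(counts)
  keep_caps <- totals >= min_units_per_cap
  keep_vars <- colSums(counts) > min_variant_count
  m <- counts[keep_caps, keep_vars, drop = FALSE] / totals[keep_caps]
  m
}

# label sets of all clades (merge nodes) of an hclust, as sorted keys
hclust_clade_keys <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) hc$labels[-m[1]] else members[[m[1]]],
                      if (m[2] < 0) hc$labels[-m[2]] else members[[m[2]]])
  }
  vapply(members, function(x) paste(sort(x), collapse = "|"), "")
}

#' Hierarchically cluster caps by variant composition
#'
#' Distance is 1 minus the Pearson correlation between composition rows;
#' linkage is average (UPGMA). Support for each observed cluster is the
#' percentage of `nboot` column-resampled dendrograms containing exactly
#' the same leaf subset (a plain bootstrap proportion).
#'
#' @param m composition matrix from [build_composition_matrix()].
#' @param nboot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `hclust` (the dendrogram), `support` (data.frame:
#'   members key, support percentage per internal node, in merge order).
#' @export
hcluster_caps <- function(m, nboot = 100, seed = 1) {
  stopifnot(nrow(m) >= 3)
  rv <- apply(m, 1, sd)
  if (any(rv == 0)) {
    stop("zero-variance composition row: correlation undefined for cap '",
         rownames(m)[which(rv == 0)[1]], "'", call. = FALSE)
  }
  capdist <- function(x) as.dist(1 - cor(t(x)))
  hc <- hclust(capdist(m), method = "average")
  keys <- hclust_clade_keys(hc)
  hits <- numeric(length(keys))
  n_valid <- 0
  with_seed(seed, {
    for (b in seq_len(nboot)) {
      mb <- m[, sample.int(ncol(m), ncol(m), replace = TRUE), drop = FALSE]
      rvb <- apply(mb, 1, sd)
      if (any(rvb == 0)) next  # degenerate resample: no dendrogram
      kb <- hclust_clade_keys(hclust(capdist(mb), method = "average"))
      hits <- hits + (keys %in% kb)
      n_valid <- n_valid + 1
    }
  })
  list(hclust = hc,
       support = data.frame(members = keys,
                            support = 100 * hits / max(1, n_valid)),
       nboot = nboot, n_valid = n_valid)
}

# k-means++ seeding followed by Lloyd iterations; ties and restarts under
# the caller's RNG state
kmeanspp <- function(x, k, nstart = 10, iter.max = 50) {
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(nrow(x), 1), ]
    d2 <- rowSums((x - matrix(centers[1, ], nrow(x), ncol(x),
                              byrow = TRUE))^2)
    for (j in seq_len(k - 1)) {
      if (all(d2 == 0)) {
        pick <- sample.int(nrow(x), 1)
      } else {
        pick <- sample.int(nrow(x), 1, prob = d2)
      }
      centers[j + 1, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], nrow(x),
                                         ncol(x), byrow = TRUE))^2))
    }
    fit <- suppressWarnings(kmeans(x, centers, iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# mean silhouette width of a labelling over a precomputed dist
mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(as.integer(factor(labels)), d)[, "sil_width"])
}

#' Cluster satellite variants by cap co-occurrence
#'
#' Each variant is described by its count in each cap divided by its
#' global count (rows sum to 1); variants that tend to occur in the same
#' caps cluster together. k-means (k-means++ seeding, `nstart` restarts)
#' is run for each k in `k_range` and the k maximising the mean Euclidean
#' silhouette is chosen. If even the best silhouette is at most 0.1 a
#' "no co-occurrence structure" warning is raised.
#'
#' @param catalog a `variant_catalog`.
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @param nstart k-means restarts per k.
#' @return list with `labels` (integer per variant, named by column),
#'   `k`, and `silhouette` (data.frame k, mean_width).
#' @export
cluster_variants <- function(catalog, k_range = 2:12, seed = 1,
                             nstart = 10) {
  counts <- catalog$counts
  x <- t(counts) / pmax(1, colSums(counts))
  n_distinct <- nrow(unique(x))
  k_range <- k_range[k_range < nrow(x) & k_range <= n_distinct]
  if (!length(k_range)) {
    warning("no co-occurrence structure: variants indistinguishable",
            call. = FALSE)
    return(list(labels = setNames(rep(1L, nrow(x)), rownames(x)), k = 1L,
                silhouette = data.frame(k = integer(),
                                        mean_width = numeric())))
  }
  d <- dist(x)
  with_seed(seed, {
    fits <- lapply(k_range, function(k) kmeanspp(x, k, nstart = nstart))
    sil <- vapply(fits, function(f) mean_silhouette(f$cluster, d),
                  numeric(1))
    best <- which.max(sil)
    if (sil[best] <= 0.1) {
      warning("no co-occurrence structure: best silhouette <= 0.1",
              call. = FALSE)
    }
    list(labels = setNames(fits[[best]]$cluster, rownames(x)),
         k = k_range[best],
         silhouette = data.frame(k = k_range, mean_width = sil))
  })
}

#' Assign higher-order block types to windows
#'
#' Caps are divided into non-overlapping windows (20 kbp by default);
#' each window is described by the fraction of its satellite units in
#' each variant cluster, and a second k-means (silhouette-chosen k)
#' labels the windows. Labels `k1..kK` are ordered by decreasing
#' genome-wide abundance; windows containing no units are labelled
#' `"unassigned"` and excluded from clustering.
#'
#' @param units data.frame with seq_id, start, end and either a `cluster`
#'   column or a `variant_id` column resolved through `clusters`.
#' @param cap_extents interval data.frame of cap extents to tile.
#' @param clusters optional output of [cluster_variants()].
#' @param window window size, bp.
#' @param k_range candidate block-type counts.
#' @param seed integer seed.
#' @param nstart k-means restarts per k.
#' @return list with `windows` (seq_id, start, end, label), `k`,
#'   `silhouette`, and `features` (window x cluster fractions).
#' @export
assign_block_types <- function(units, cap_extents, clusters = NULL,
                               window = 20000, k_range = 2:12, seed = 1,
                               nstart = 10) {
  if (is.null(units$cluster)) {
    stopifnot(!is.null(clusters), !is.null(units$variant_id))
    units$cluster <- unname(clusters$labels[sprintf("v%d", units$variant_id)])
  }
  wins <- do.call(rbind, lapply(seq_len(nrow(cap_extents)), function(i) {
    s <- seq(cap_extents$start[i], cap_extents$end[i] - 1, by = window)
    data.frame(seq_id = cap_extents$seq_id[i], start = s,
               end = pmin(s + window, cap_extents$end[i]))
  }))
  wkey <- function(seq_id, start) paste(seq_id, start %/% window)
  units$win <- wkey(units$seq_id, units$start)
  wins$key <- wkey(wins$seq_id, wins$start)
  cl_levels <- sort(unique(units$cluster))
  tab <- table(factor(units$win, wins$key), factor(units$cluster, cl_levels))
  feat <- matrix(as.numeric(tab), nrow(wins), length(cl_levels),
                 dimnames = list(wins$key, as.character(cl_levels)))
  tot <- rowSums(feat)
  nonempty <- tot > 0
  feat <- feat / pmax(1, tot)
  x <- feat[nonempty, , drop = FALSE]
  n_distinct <- nrow(unique(x))
  k_range <- k_range[k_range < nrow(x) & k_range <= n_distinct]
  if (!length(k_range)) {
    # a single effective composition: every non-empty window is one type
    lab <- rep("unassigned", nrow(wins))
    lab[nonempty] <- "k1"
    wins$label <- lab
    wins$key <- NULL
    return(list(windows = wins, k = 1L,
                silhouette = data.frame(k = integer(),
                                        mean_width = numeric()),
                features = feat))
  }
  d <- dist(x)
  with_seed(seed, {
    fits <- lapply(k_range, function(k) kmeanspp(x, k, nstart = nstart))
    sil <- vapply(fits, function(f) mean_silhouette(f$cluster, d),
                  numeric(1))
    best <- which.max(sil)
    cl <- fits[[best]]$cluster
    # rename clusters k1..kK by decreasing genome-wide abundance
    ord <- order(-as.integer(table(factor(cl, seq_len(k_range[best])))))
    rank <- match(cl, ord)
    lab <- rep("unassigned", nrow(wins))
    lab[nonempty] <- sprintf("k%d", rank)
    wins$label <- lab
    wins$key <- NULL
    list(windows = wins, k = k_range[best],
         silhouette = data.frame(k = k_range, mean_width = sil),
         features = feat)
  })
}
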