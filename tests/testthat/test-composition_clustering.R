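make_catalog <- function(counts) {
  out <- list(variants = data.frame(variant_id = seq_len(ncol(counts)),
                                    sequence = NA, count = colSums(counts)),
              counts = counts)
  class(out) <- "variant_catalog"
  out
}

test_that("composition matrix applies both abundance screens", {
  counts <- matrix(c(2000, 0, 0,
                     1000, 900, 99,
                     51, 1800, 149), 3, 3, byrow = TRUE,
                   dimnames = list(c("capA", "capB", "capC"),
                                   c("v1", "v2", "v3")))
  m <- build_composition_matrix(make_catalog(counts),
                                min_variant_count = 100,
                                min_units_per_cap = 2000)
  # capB has 1999 units -> excluded; v3 global count 248 kept, v2 2700 kept
  expect_false("capB" %in% rownames(m))
  expect_true(all(c("capA", "capC") %in% rownames(m)))
  # single-variant cap: cell 1.0
  expect_equal(m["capA", "v1"], 1.0)
  # denominator counts all units (including filtered columns)
  expect_equal(m["capC", "v2"], 1800 / 2000)

  # strict > threshold: a variant with exactly 100 copies is dropped
  counts2 <- cbind(counts, v4 = c(100, 0, 0))
  m2 <- build_composition_matrix(make_catalog(counts2))
  expect_false("v4" %in% colnames(m2))
  # direct recount oracle for retained columns
  keep <- colSums(counts2) > 100
  expect_identical(colnames(m2), colnames(counts2)[keep])
})

test_that("cap dendrogram distances behave at the correlation extremes", {
  m <- rbind(a = c(0.5, 0.3, 0.2, 0.0),
             b = c(0.5, 0.3, 0.2, 0.0),
             c = c(0.0, 0.2, 0.3, 0.5))
  hc <- hcluster_caps(m, nboot = 50, seed = 1)
  d <- as.matrix(stats::cophenetic(hc$hclust))
  expect_equal(d["a", "b"], 0)        # identical rows merge at 0
  expect_equal(hc$support$support[hc$support$members == "a|b"], 100)
  # perfectly anticorrelated pairs merge at the distance maximum of 2
  m2 <- rbind(a = c(1, 2, 3), a2 = c(2, 4, 6),
              b = c(3, 2, 1), b2 = c(6, 4, 2))
  hc2 <- hcluster_caps(m2, nboot = 10, seed = 1)
  expect_equal(max(hc2$hclust$height), 2, tolerance = 1e-9)

  mz <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1))
  expect_error(hcluster_caps(mz, 10, 1), "cap 'a'")
})

test_that("planted lineages split at the top with high support", {
  cat2 <- simulate_variant_catalog(n_caps = 20, n_groups = 2,
                                   variants_per_group = 40,
                                   units_per_cap = 5000, seed = 44)
  m <- build_composition_matrix(cat2)
  expect_equal(nrow(m), 20)
  hc <- hcluster_caps(m, nboot = 100, seed = 3)
  grp <- cat2$truth_cap_group[match(rownames(m), rownames(cat2$counts))]
  for (g in 1:2) {
    key <- paste(sort(rownames(m)[grp == g]), collapse = "|")
    expect_gte(hc$support$support[hc$support$members == key], 95)
  }
})

test_that("variant clustering recovers planted co-occurrence groups", {
  cat6 <- simulate_variant_catalog(n_caps = 20, n_groups = 6,
                                   variants_per_group = 25,
                                   units_per_cap = 5000, seed = 42)
  cv <- cluster_variants(cat6, seed = 1)
  expect_equal(cv$k, 6)
  expect_gte(mclust::adjustedRandIndex(cv$labels, cat6$truth_group), 0.9)

  # fully separable two-pool case: near-perfect silhouette at k = 2
  c2 <- simulate_variant_catalog(n_caps = 10, n_groups = 2,
                                 variants_per_group = 30,
                                 units_per_cap = 4000, background = 0,
                                 seed = 91)
  cv2 <- cluster_variants(c2, seed = 1)
  expect_equal(cv2$k, 2)
  expect_gt(max(cv2$silhouette$mean_width), 0.9)

  # structureless catalog: silhouette stays low and the pipeline warns
  set.seed(8)
  flat <- matrix(rpois(20 * 60, 1000), 20, 60,
                 dimnames = list(sprintf("cap%02d", 1:20),
                                 sprintf("v%d", 1:60)))
  expect_warning(cvf <- cluster_variants(make_catalog(flat), seed = 2),
                 "no co-occurrence structure")
  expect_lte(max(cvf$silhouette$mean_width), 0.1)
})

test_that("block typing recovers planted window archetypes", {
  bw <- simulate_block_windows(n_caps = 20, windows_per_cap = 40,
                               n_types = 8, seed = 43)
  bt <- assign_block_types(bw$units, bw$cap_extents, seed = 2)
  expect_equal(bt$k, 8)
  expect_gte(label_match_accuracy(bw$truth$type, bt$windows$label), 0.95)
  # windows tile each cap
  w1 <- bt$windows[bt$windows$seq_id == "cap01", ]
  expect_equal(w1$start, seq(0, by = 20000, length.out = nrow(w1)))
  # labels ordered by abundance: k1 at least as common as k2
  tab <- table(bt$windows$label)
  expect_gte(tab[["k1"]], tab[["k2"]])
})

test_that("uniform-composition caps give one effective type and empty windows are unassigned", {
  units <- data.frame(seq_id = "cap01",
                      start = c(seq(0, 19000, 1000), seq(20000, 39000, 1000)),
                      end = NA, cluster = 1)
  units$end <- units$start + 32
  ext <- intervals("cap01", 0, 80000)  # windows 3 and 4 empty
  bt <- assign_block_types(units, ext, k_range = 2:4, seed = 1)
  lab <- bt$windows$label
  expect_equal(bt$k, 1)
  expect_equal(lab[3:4], c("unassigned", "unassigned"))
  expect_equal(lab[1:2], c("k1", "k1"))
})
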