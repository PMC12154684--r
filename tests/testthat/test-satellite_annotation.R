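test_that("the consensus and its reverse complement scan to single units", {
  cons <- pcht_consensus()
  u <- scan_units(setNames(cons, "c"))
  expect_equal(nrow(u), 1)
  expect_equal(c(u$start, u$end), c(0, 32))
  expect_equal(u$identity, 1)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  u2 <- scan_units(setNames(rc, "c"))
  expect_equal(nrow(u2), 1)
  expect_equal(u2$strand, "-")
  expect_identical(u2$unit_sequence, cons)

  expect_error(scan_units("ACGT", consensus = "ACGN"), "non-ACGT")
})

test_that("tandem array scan matches the exhaustive sliding oracle", {
  set.seed(77)
  cons <- pcht_consensus()
  units <- replicate(100, {
    x <- strsplit(cons, "")[[1]]
    hit <- which(runif(32) < 0.02)
    if (length(hit)) {
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(x, collapse = "")
  })
  seq <- paste(units, collapse = "")
  got <- scan_units(setNames(seq, "t"))
  oracle <- oracle_scan_units(seq, cons)
  expect_equal(nrow(got), 100)
  expect_equal(nrow(oracle), 100)
  expect_true(all(abs(got$start - oracle$start) <= 1))
})

test_that("variant classification groups identical strings and orders by count", {
  cons <- pcht_consensus()
  mut <- sub("^G", "T", cons)
  units <- data.frame(seq_id = c("a", "a", "a", "b"),
                      unit_sequence = c(cons, cons, mut, cons))
  cat <- classify_variants(units)
  expect_equal(nrow(cat$variants), 2)
  expect_equal(cat$variants$sequence[1], cons)  # most abundant first
  expect_equal(cat$variants$count, c(3, 1))
  expect_equal(unname(cat$counts["a", ]), c(2, 1))
  expect_equal(unname(cat$counts["b", ]), c(1, 0))

  # planted frequencies recovered exactly
  set.seed(3)
  vs <- vapply(1:5, function(i) {
    x <- strsplit(cons, "")[[1]]; x[i] <- "A"; x[i + 5] <- "C"
    paste(x, collapse = "")
  }, "")
  freq <- c(40, 25, 20, 10, 5)
  pool <- sample(rep(vs, freq))
  cat2 <- classify_variants(data.frame(seq_id = "c", unit_sequence = pool))
  expect_equal(nrow(cat2$variants), length(unique(vs)))
  expect_equal(sort(cat2$variants$count, decreasing = TRUE), sort(freq, TRUE))
})

test_that("arrays merge across small gaps and split across large ones", {
  u <- intervals("c", c(0, 32, 64), c(32, 64, 96), strand = "+")
  u$identity <- 1
  a <- merge_arrays(u)
  expect_equal(nrow(a), 1)
  expect_equal(a$unit_count, 3)
  expect_equal(c(a$start, a$end), c(0, 96))

  u2 <- intervals("c", c(0, 32, 30064, 30096), c(32, 64, 30096, 30128),
                  strand = "+")
  u2$identity <- 1
  a2 <- merge_arrays(u2)
  expect_equal(nrow(a2), 2)
})

test_that("spacers are the large complement gaps of the arrays", {
  ext <- intervals("c", 0, 100000)
  a <- intervals("c", c(0, 40000), c(30000, 100000))
  sp <- call_spacers(ext, a)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$start, sp$end), c(30000, 40000))

  # one array filling the cap: no spacers
  sp0 <- call_spacers(ext, intervals("c", 0, 100000))
  expect_equal(nrow(sp0), 0)
})

test_that("full annotation recovers planted arrays and spacers", {
  cfg <- cap_config(n_arrays = 8, array_len_mean = 12000,
                    array_len_sd = 3000, spacer_len = 6000, cap_count = 1,
                    seed = 13)
  cs <- simulate_cap_set(cfg)
  cap <- cs$caps[1]
  units <- scan_units(cap)
  truth_u <- cs$truth$units
  # scan recall and precision vs planted truth
  expect_gte(interval_recall(truth_u, units), 0.99)
  expect_gte(interval_recall(units, truth_u), 0.99)
  expect_false(any(units$start[-1] < units$end[-nrow(units)]))  # no overlap

  arrays <- merge_arrays(units, max_gap = 1000)
  truth_a <- cs$truth$arrays
  expect_equal(nrow(arrays), nrow(truth_a))
  jac <- vapply(seq_len(nrow(truth_a)), function(i) {
    interval_jaccard <- function(s1, e1, s2, e2) {
      inter <- max(0, min(e1, e2) - max(s1, s2))
      inter / ((e1 - s1) + (e2 - s2) - inter)
    }
    max(vapply(seq_len(nrow(arrays)), function(j) {
      interval_jaccard(truth_a$start[i], truth_a$end[i],
                       arrays$start[j], arrays$end[j])
    }, numeric(1)))
  }, numeric(1))
  expect_gte(min(jac), 0.99)

  ext <- intervals(names(cap), 0, nchar(cap))
  sp <- call_spacers(ext, arrays, min_spacer_len = 5000)
  truth_s <- cs$truth$spacers
  expect_equal(nrow(sp), nrow(truth_s))  # 7 planted spacers
  expect_true(all(abs(sp$start - truth_s$start) <= 100))
  expect_true(all(abs(sp$end - truth_s$end) <= 100))

  # arrays + spacers + sub-threshold gaps tile the cap extent
  lvl <- rbind(arrays[, c("start", "end")], sp[, c("start", "end")])
  lvl <- lvl[order(lvl$start), ]
  gaps <- c(lvl$start[1], lvl$start[-1] - lvl$end[-nrow(lvl)],
            nchar(cap) - lvl$end[nrow(lvl)])
  expect_true(all(gaps >= 0 & gaps < 5000))
})

test_that("consensus derivation recovers the planted monomer", {
  cons <- pcht_consensus()
  d0 <- derive_consensus(rep(cons, 5))
  expect_identical(d0$consensus, cons)
  expect_true(all(apply(d0$profile, 2, max) == 1))
  expect_equal(colSums(d0$profile), rep(1, 32), ignore_attr = TRUE)

  set.seed(15)
  noisy <- replicate(3000, {
    x <- strsplit(cons, "")[[1]]
    hit <- which(runif(32) < 0.05)
    if (length(hit)) x[hit] <- sample(c("A", "C", "G", "T"), length(hit),
                                      replace = TRUE)
    paste(x, collapse = "")
  })
  dn <- derive_consensus(noisy)
  expect_identical(dn$consensus, cons)
  expect_equal(ncol(dn$profile), 32)
})
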