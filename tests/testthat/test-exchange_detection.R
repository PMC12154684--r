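random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_pct <- function(seq, p, seed) {
  set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < p)
  x[hit] <- vapply(x[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(x, collapse = "")
}

test_that("identical caps give one full-length block at identity 1", {
  s <- random_seq(120000, 1)
  bl <- anchor_chain_align(setNames(s, "x"), setNames(s, "y"))
  main <- bl[which.max(bl$length), ]
  expect_equal(main$identity, 1)
  expect_gte(main$length, nchar(s) - 110)  # edges limited by k + stride
  expect_equal(main$query_start, main$target_start)
})

test_that("unrelated random sequences give no blocks", {
  a <- random_seq(300000, 2)
  b <- random_seq(300000, 3)
  bl <- anchor_chain_align(setNames(a, "a"), setNames(b, "b"))
  expect_equal(nrow(bl), 0)
})

test_that("block identity tracks the planted divergence", {
  a <- random_seq(100000, 4)
  b <- mutate_pct(a, 0.05, 5)
  bl <- anchor_chain_align(setNames(a, "a"), setNames(b, "b"))
  w <- windowed_identity(bl, nchar(a))
  expect_equal(w$weighted_identity, 0.95, tolerance = 0.005 / 0.95)
  # full-alignment oracle on a 10 kbp sample
  sub_a <- substr(a, 40001, 50000)
  sub_b <- substr(b, 40001, 50000)
  ora <- Biostrings::pairwiseAlignment(Biostrings::DNAString(sub_a),
                                       Biostrings::DNAString(sub_b),
                                       type = "global")
  oid <- Biostrings::nmatch(ora) / 10000
  expect_equal(w$weighted_identity, oid, tolerance = 0.005)
})

test_that("windowed identity and the high-identity pair rule behave", {
  s <- random_seq(200000, 6)
  bl <- anchor_chain_align(setNames(s, "x"), setNames(s, "y"))
  w <- windowed_identity(bl, nchar(s), window = 50000)
  expect_true(all(w$windows$identity == 1))
  expect_gte(w$coverage, 0.99)
  expect_true(high_identity_pair(bl, nchar(s)))

  # 10% divergence: mean window identity ~0.90 and the rule rejects
  d <- mutate_pct(s, 0.10, 7)
  bl2 <- anchor_chain_align(setNames(s, "x"), setNames(d, "y"))
  expect_false(high_identity_pair(bl2, nchar(s)))
})

test_that("a planted exchange is recovered with breakpoints within 2 kbp", {
  cfg <- cap_config(n_arrays = 6, array_len_mean = 25000,
                    array_len_sd = 8000, spacer_len = 6000, cap_count = 2,
                    seed = 11)
  cs <- plant_exchange(simulate_cap_set(cfg), "cap01", "cap02",
                       spacer_from = 2, spacer_to = 4)
  ex <- cs$truth$exchanges
  bl <- anchor_chain_align(cs$caps["cap02"], cs$caps["cap01"])
  sp <- cs$truth$spacers
  cand <- detect_exchange_candidates(bl, cs$caps[["cap02"]],
                                     cs$caps[["cap01"]],
                                     spacers = sp[sp$seq_id == "cap02", ],
                                     min_len = 50000)
  expect_equal(nrow(cand), 1)
  expect_gte(cand$identity, 0.995)
  expect_lte(abs(cand$bp1 - ex$acc_start), 2000)
  expect_lte(abs(cand$bp2 - ex$acc_end), 2000)
  expect_equal(cand$bp1_spacer_dist, 0)
  expect_equal(cand$bp2_spacer_dist, 0)

  # threshold semantics: candidate count is non-increasing in min_identity
  n995 <- nrow(detect_exchange_candidates(bl, min_identity = 0.995,
                                          min_len = 50000))
  n998 <- nrow(detect_exchange_candidates(bl, min_identity = 0.998,
                                          min_len = 50000))
  n1 <- nrow(detect_exchange_candidates(bl, min_identity = 0.9999,
                                        min_len = 50000))
  expect_true(n998 <= n995 && n1 <= n998)
})

test_that("divergent allelic caps produce no exchange candidates", {
  cfg <- cap_config(n_arrays = 5, array_len_mean = 20000,
                    array_len_sd = 5000, spacer_len = 5000, cap_count = 1,
                    seed = 15)
  cs <- simulate_cap_set(cfg)
  h1 <- mutate_pct(cs$caps[[1]], 0.045, 16)
  h2 <- mutate_pct(cs$caps[[1]], 0.045, 17)   # ~9% apart
  bl <- anchor_chain_align(setNames(h1, "h1"), setNames(h2, "h2"))
  cand <- detect_exchange_candidates(bl, min_len = 50000)
  expect_equal(nrow(cand), 0)
})

test_that("alignment is symmetric under swapping the pair", {
  cfg <- cap_config(n_arrays = 3, array_len_mean = 15000,
                    array_len_sd = 3000, spacer_len = 4000, cap_count = 2,
                    seed = 19)
  cs <- plant_exchange(simulate_cap_set(cfg), "cap01", "cap02",
                       spacer_from = 1, spacer_to = 2)
  ab <- anchor_chain_align(cs$caps["cap01"], cs$caps["cap02"])
  ba <- anchor_chain_align(cs$caps["cap02"], cs$caps["cap01"])
  a_main <- ab[which.max(ab$length), ]
  b_main <- ba[which.max(ba$length), ]
  expect_equal(a_main$query_start, b_main$target_start)
  expect_equal(a_main$target_start, b_main$query_start)
  expect_equal(a_main$identity, b_main$identity, tolerance = 1e-6)
})

test_that("nearest spacer distance agrees with the exhaustive oracle", {
  sp <- intervals("c", c(100, 500, 900), c(200, 600, 950))
  expect_equal(nearest_spacer_distance(150, sp), 0)
  expect_equal(nearest_spacer_distance(210, sp), 10)
  # 10 kbp right of a spacer end with the next spacer 40 kbp away
  sp2 <- intervals("c", c(0, 60000), c(10000, 70000))
  expect_equal(nearest_spacer_distance(20000, sp2), 10000)

  set.seed(21)
  for (i in 1:20) {
    st <- sort(sample.int(10000, 5))
    spr <- intervals("c", st, st + sample.int(300, 5))
    pos <- sample.int(11000, 50) - 1
    expect_equal(nearest_spacer_distance(pos, spr), oracle_nearest(pos, spr))
  }
})
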