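test_that("pairwise distances match closed forms and metric axioms", {
  expect_equal(as.numeric(compute_distances(c(a = "ACGT", b = "ACGT"), "p")),
               0)
  d <- compute_distances(c(a = "AAAA", b = "AAAT"), "JC")
  expect_equal(as.numeric(d), -0.75 * log(1 - 4 * 0.25 / 3),
               tolerance = 1e-9)
  # pairwise deletion: gap/N columns dropped per pair
  dp <- compute_distances(c(a = "AC-TN", b = "ACGTA"), "p")
  expect_equal(as.numeric(dp), 0)

  set.seed(2)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:10)
  D <- as.matrix(compute_distances(seqs, "p"))
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))

  expect_error(compute_distances(c(a = "AAAA", b = "TTTT"), "JC"),
               "p >= 0.75")
  expect_error(compute_distances(c(a = "--", b = "AA"), "p"),
               "no comparable sites")
})

test_that("neighbor-joining is exact on additive distances", {
  # 3 taxa: branch lengths solve the three-point formulas
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- build_nj_tree(D)
  expect_equal(sort(setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])[letters[1:3]]),
               sort(c(a = 1, b = 2, c = 3)), ignore_attr = TRUE)

  set.seed(4)
  for (i in 1:20) {
    t0 <- ape::rtree(sample(4:15, 1), br = function(n) runif(n, 0.1, 1))
    rec <- build_nj_tree(ape::cophenetic.phylo(t0))
    expect_equal(rf_distance(rec, t0), 0)
    expect_equal(max(abs(sort(ape::cophenetic.phylo(rec)[t0$tip.label, t0$tip.label] -
                                ape::cophenetic.phylo(t0)))), 0,
                 tolerance = 1e-8)
  }

  # all-equal distances: star-like resolution, zero internal branches
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  ts <- build_nj_tree(De)
  internal <- ts$edge[, 2] > length(ts$tip.label)
  expect_true(all(ts$edge.length[internal] < 1e-9))
  expect_true(all(ts$edge.length >= 0))
})

test_that("RF distance matches a brute-force bipartition oracle", {
  t4a <- ape::read.tree(text = "((a,b),(c,d));")
  t4b <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t4a, t4a), 0)
  expect_equal(rf_distance(t4a, t4b), 2)
  expect_equal(rf_distance(t4a, t4b, normalized = TRUE), 1)

  set.seed(6)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    t1 <- ape::rtopology(n, rooted = FALSE)
    t2 <- ape::rtopology(n, rooted = FALSE)
    t2$tip.label <- sample(t1$tip.label)
    expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2))
  }
  expect_error(rf_distance(t4a, ape::read.tree(text = "((a,b),(c,e));")),
               "different tip sets")
})

test_that("bootstrap consensus honours the replicate count and flags strong signal", {
  tr <- random_clock_tree(8, depth = 10, seed = 3)
  sim <- simulate_spacer_evolution(tr, rate = 0.005, length = 20000, seed = 3)
  bc <- bootstrap_consensus(sim$seqs, n_boot = 25, seed = 1)
  expect_length(bc$replicates, 25)
  sup <- suppressWarnings(as.numeric(bc$consensus$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  expect_equal(rf_distance(bc$consensus, tr), 0)
})

test_that("bootstrap support increases with planted branch length", {
  base <- "(((a:1,b:1):%s,c:%s):1,d:2);"
  sup_at <- function(inner) {
    tr <- ape::read.tree(text = sprintf(base, inner, 1 + as.numeric(inner)))
    mean(replicate(8, {
      sim <- simulate_spacer_evolution(tr, rate = 0.01, length = 300,
                                       seed = sample.int(1e6, 1))
      bc <- bootstrap_consensus(sim$seqs, n_boot = 50,
                                seed = sample.int(1e6, 1))
      keys <- lapply(bc$replicates, subtercap:::tree_bipartitions)
      mean(vapply(keys, function(k) "c|d" %in% k, logical(1)))
    }))
  }
  set.seed(12)
  sups <- c(sup_at("0.02"), sup_at("0.3"), sup_at("3"))
  expect_true(sups[1] < sups[3])
  expect_true(sups[2] <= sups[3] + 0.05)
})

test_that("clock calibration rescales heights to ages", {
  # ultrametric tree, single calibration: exact scaling
  iso <- ape::read.tree(text = "((a:2,b:2):3,c:5);")
  c1 <- calibrate_tree(iso, "c", list(list(tips = c("a", "b"), age = 10)))
  expect_equal(c1$ages$age[c1$ages$members == "a|b"], 10)
  expect_equal(c1$ages$age[c1$ages$members == "a|b|c"], 25)

  # two mutually consistent calibrations give the same rate as either alone
  two <- calibrate_tree(iso, "c", list(list(tips = c("a", "b"), age = 10),
                                       list(tips = c("a", "c"), age = 25)))
  expect_equal(two$rate, c1$rate, tolerance = 1e-12)

  # invariance to uniform rescaling of branch lengths
  iso2 <- iso
  iso2$edge.length <- iso$edge.length * 7
  c2 <- calibrate_tree(iso2, "c", list(list(tips = c("a", "b"), age = 10)))
  expect_equal(c2$ages$age, c1$ages$age, tolerance = 1e-12)

  expect_error(calibrate_tree(iso, "c", list(list(tips = c("a", "z"),
                                                  age = 1))),
               "calibration node not present")
})

test_that("calibration recovers simulated divergence times", {
  tt <- ape::read.tree(
    text = "((((A:5.1,B:5.1):2.4,C:7.5):7.7,D:15.2):4.3,E:19.5);")
  set.seed(20)
  errs <- replicate(5, {
    sim <- simulate_spacer_evolution(tt, rate = 0.002, length = 30000,
                                     seed = sample.int(1e6, 1))
    nj <- build_nj_tree(compute_distances(sim$seqs, "JC"))
    cal <- calibrate_tree(nj, "E",
                          list(list(tips = c("A", "D"), age = 15.2),
                               list(tips = c("A", "E"), age = 19.5)))
    ages <- setNames(cal$ages$age, cal$ages$members)
    c(abs(ages[["A|B"]] - 5.1), abs(ages[["A|B|C"]] - 7.5))
  })
  expect_lt(mean(errs), 0.8)
})

test_that("terminal branch mean averages tip edges", {
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  expect_equal(terminal_branch_mean(tr), 1)
  expect_equal(terminal_branch_mean(tr, "a"), 1)
  set.seed(30)
  t2 <- ape::rtree(12)
  tips <- sample(t2$tip.label, 5)
  direct <- mean(t2$edge.length[match(match(tips, t2$tip.label),
                                      t2$edge[, 2])])
  expect_equal(terminal_branch_mean(t2, tips), direct)
})
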