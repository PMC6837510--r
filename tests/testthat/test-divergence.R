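test_that("p-distance counts differences with pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT")$p, 0)
  expect_equal(p_distance("ACGT", "ACGA")$p, 0.25)
  est <- p_distance("ACGN", "ACTA")
  expect_equal(est$sites_compared, 3L)
  expect_equal(est$differences, 1L)
  expect_equal(est$p, 1 / 3)
  expect_error(p_distance("ACG", "ACGT"), "unequal")
  expect_error(p_distance("NNNN", "ACGT"), "no comparable")
})

test_that("p-distance matches a position-by-position oracle on random pairs", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    a <- paste(sample(c("A", "C", "G", "T", "N", "-"), n, replace = TRUE,
                      prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N", "-"), n, replace = TRUE,
                      prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = "")
    expected <- oracle_p_distance(a, b)
    if (expected$sites_compared == 0) {
      expect_error(p_distance(a, b))
    } else {
      got <- p_distance(a, b)
      expect_equal(got$differences, expected$differences)
      expect_equal(got$sites_compared, expected$sites_compared)
      expect_equal(got$p, expected$p)
    }
  }
})

test_that("group mean averages per-pair p over all pairs", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AAAT")
  # pairs: (a,b) 0.25, (a,c) 0.25, (b,c) 0
  gm <- group_mean_p(aln)
  expect_equal(gm$n_pairs, 3L)
  expect_equal(gm$p, (0.25 + 0.25 + 0) / 3)
  expect_equal(group_mean_p(aln, c("a", "b"))$p, p_distance("AAAA", "AAAT")$p)
  expect_equal(group_mean_p(c(x = "ACGT", y = "ACGT", z = "ACGT"))$p, 0)
  expect_error(group_mean_p(c(a = "NNNN", b = "ACGT", c = "ACGT")),
               "pair \\(a, b\\)")
})

test_that("sliding windows follow the step rule with the half-window tail cut", {
  set.seed(3)
  aln <- c(a = paste(sample(c("A", "C"), 1000, TRUE), collapse = ""),
           b = paste(sample(c("A", "C"), 1000, TRUE), collapse = ""))
  prof <- window_profile(aln, window = 500, overlap = 100)
  expect_equal(prof$start, c(0, 400))
  expect_equal(prof$end, c(500, 900))
  # a 1100-column alignment keeps the 300-long tail (>= 250)
  aln2 <- c(a = strrep("A", 1100), b = strrep("A", 1100))
  prof2 <- window_profile(aln2, window = 500, overlap = 100)
  expect_equal(prof2$start, c(0, 400, 800))
  expect_equal(prof2$end, c(500, 900, 1100))
  expect_true(all(prof2$p == 0))
  expect_error(window_profile(aln, window = 100, overlap = 100), "overlap")
})

test_that("two groups give independent profiles over identical windows", {
  set.seed(8)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  aln <- c(in1 = mk(), in2 = mk(), out1 = mk(), out2 = mk())
  prof <- window_profile(aln, groups = list(ingroup = c("in1", "in2"),
                                            comparator = c("out1", "out2")))
  ing <- prof[prof$group == "ingroup", ]
  cmp <- prof[prof$group == "comparator", ]
  expect_equal(ing$start, cmp$start)
  expect_equal(ing$end, cmp$end)
  for (i in seq_len(nrow(ing))) {
    sub <- substr(aln[c("in1", "in2")], ing$start[i] + 1, ing$end[i])
    expect_equal(ing$p[i], p_distance(sub[1], sub[2])$p)
  }
})

test_that("whole-alignment mean equals the weighted window combination when windows tile", {
  set.seed(12)
  aln <- c(a = paste(sample(c("A", "G"), 800, TRUE), collapse = ""),
           b = paste(sample(c("A", "G"), 800, TRUE), collapse = ""),
           c = paste(sample(c("A", "G"), 800, TRUE), collapse = ""))
  prof <- window_profile(aln, window = 200, overlap = 0)
  whole <- group_mean_p(aln)$p
  expect_equal(sum(prof$p * 200) / 800, whole, tolerance = 1e-12)
})

test_that("pairwise matrices are symmetric with zero diagonal", {
  aln <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGAACGT")
  d <- pairwise_matrix(aln)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1 / 8)
  expect_equal(d["b", "c"], 1 / 8)
})

test_that("sister tips are equidistant from an outgroup on average", {
  # matrix of simulator output is ultrametric in expectation
  diffs <- vapply(1:20, function(r) {
    cfg <- mini_config(seed = 700 + r)
    tr <- ape::read.tree(text = "((A:2e5,B:2e5):3e5,C:5e5);")
    sim <- evolve_clade(build_ancestor(cfg), tr, mini_config(seed = 900 + r))
    d <- pairwise_matrix(tip_sequences(sim))
    d["A", "C"] - d["B", "C"]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 1e-9)
})

test_that("group divergence rises with chronogram depth", {
  depths <- c(0.5, 1, 2, 4, 8) * 1e5
  ps <- vapply(seq_along(depths), function(i) {
    cfg <- mini_config(seed = 40)
    sim <- evolve_clade(build_ancestor(cfg), two_tip_tree(depths[i]),
                        mini_config(seed = 50 + i))
    group_mean_p(tip_sequences(sim))$p
  }, numeric(1))
  expect_gt(stats::cor(depths, ps, method = "spearman"), 0)
  expect_equal(order(ps), seq_along(depths))
})

test_that("site classification matches the column oracle and the class definitions", {
  m <- rbind(a = c("T", "T", "A", "A"),
             b = c("T", "T", "A", "C"),
             c = c("A", "T", "A", "G"),
             d = c("A", "T", "N", "T"))
  # col1 TTAA informative, col2 conserved, col3 has N, col4 all-different
  cls <- classify_sites(m)
  expect_equal(cls$parsimony_informative, 1L)
  expect_equal(cls$conserved, 1L)
  expect_equal(cls$unclassified, 1L)
  expect_equal(cls$other_variable, 1L)
  expect_equal(cls$total, 4L)
  sing <- classify_sites(rbind(a = "T", b = "T", c = "T", d = "A"))
  expect_equal(sing$singleton, 1L)
  set.seed(77)
  for (i in 1:100) {
    nr <- sample(4:7, 1)
    nc <- sample(5:30, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), nr * nc, TRUE,
                       prob = c(rep(0.23, 4), 0.04, 0.04)), nrow = nr)
    rownames(m) <- paste0("t", 1:nr)
    got <- classify_sites(m)
    expected <- table(factor(apply(m, 2, oracle_classify_column),
                             levels = c("conserved", "parsimony_informative",
                                        "singleton", "other_variable",
                                        "unclassified")))
    expect_equal(got$conserved, unname(expected[["conserved"]]))
    expect_equal(got$parsimony_informative,
                 unname(expected[["parsimony_informative"]]))
    expect_equal(got$singleton, unname(expected[["singleton"]]))
    expect_equal(got$other_variable, unname(expected[["other_variable"]]))
    expect_equal(got$unclassified, unname(expected[["unclassified"]]))
    expect_equal(got$conserved + got$parsimony_informative + got$singleton +
                   got$other_variable + got$unclassified, got$total)
  }
})
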