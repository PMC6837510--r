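test_that("Jukes-Cantor correction matches its closed form and domain", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jc_correct(0.1), 0.10732, tolerance = 1e-4)
  expect_true(all(jc_correct(c(0.05, 0.2, 0.5)) >= c(0.05, 0.2, 0.5)))
  expect_error(jc_correct(0.75), "saturation")
  expect_error(jc_correct(-0.1), "non-negative")
})

test_that("neighbor joining recovers additive topologies and roots on the outgroup", {
  # additive 4-taxon matrix generated from ((A,B),(C,D)) with internal branch 3
  tip <- c(A = 1, B = 2, C = 1.5, D = 2.5)
  d <- matrix(0, 4, 4, dimnames = list(names(tip), names(tip)))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    cross <- (i <= 2) != (j <= 2)
    d[i, j] <- tip[i] + tip[j] + if (cross) 3 else 0
  }
  tr <- nj_topology(d, outgroup = "D")
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  # two taxa: a single cherry
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- nj_topology(d2)
  expect_setequal(tr2$tip.label, c("x", "y"))
  expect_equal(tr2$edge.length, c(0.2, 0.2))
  dbad <- d
  dbad[1, 2] <- 99
  expect_error(nj_topology(dbad), "symmetric")
})

test_that("the two-taxon clock age is d/(2*mu) to machine precision", {
  d <- matrix(c(0, 0.062, 0.062, 0), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  topo <- ape::read.tree(text = "(a:1,b:1);")
  fit <- strict_clock_fit(topo, d, rate = 6.2e-7)
  expect_equal(unname(fit$ages[["3"]]), 0.062 / (2 * 6.2e-7),
               tolerance = 1e-15)
  expect_equal(unname(fit$ages[["3"]]), 50000)
  expect_equal(fit$residual_ss, 0)
})

test_that("perfectly clocklike distances are reproduced exactly and the fit is a fixed point", {
  topo <- ape::read.tree(text = "((a:1,b:1):2,(c:2.5,d:2.5):0.5);")
  mu <- 6.2e-7
  ages_true <- c(a = 0, b = 0, c = 0, d = 0)
  # distances implied by ages: d_ij = 2 mu t_mrca
  tmrca <- matrix(3e6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tmrca["a", "b"] <- tmrca["b", "a"] <- 1e6
  tmrca["c", "d"] <- tmrca["d", "c"] <- 2.5e6
  diag(tmrca) <- 0
  d <- 2 * mu * tmrca
  fit <- strict_clock_fit(topo, d, rate = mu)
  expect_equal(fit$residual_ss, 0, tolerance = 1e-18)
  expect_equal(unname(fit$ages[["5"]]), 3e6)
  expect_equal(unname(fit$ages[["6"]]), 1e6)
  expect_equal(unname(fit$ages[["7"]]), 2.5e6)
  expect_true(ape::is.ultrametric(fit$chronogram, tol = 1e-6))
  # re-derive distances from the fitted chronogram and refit: fixed point
  ct <- ape::cophenetic.phylo(fit$chronogram)[letters[1:4], letters[1:4]]
  fit2 <- strict_clock_fit(topo, mu * ct, rate = mu)
  expect_equal(fit2$ages, fit$ages, tolerance = 1e-9)
})

test_that("fitted ages scale linearly with the distances", {
  set.seed(2)
  topo <- ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);")
  base <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  base["a", "b"] <- 0.02; base["c", "d"] <- 0.05
  base["a", "c"] <- base["a", "d"] <- base["b", "c"] <- base["b", "d"] <- 0.09
  base <- base + t(base)
  f1 <- strict_clock_fit(topo, base, rate = 1e-8)
  f3 <- strict_clock_fit(topo, 3 * base, rate = 1e-8)
  expect_equal(f3$ages, 3 * f1$ages, tolerance = 1e-9)
  expect_true(all(diff(sort(f1$ages[5:7])) >= 0))
})

test_that("calibrated and uncalibrated fits agree when the calibration equals the free root age", {
  topo <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- 0.01
  d["a", "c"] <- d["b", "c"] <- 0.04
  d <- d + t(d)
  mu <- 6.2e-7
  free <- strict_clock_fit(topo, d, rate = mu)
  root_age <- unname(free$ages[["4"]])
  cal <- strict_clock_fit(topo, d, rate = mu, root_calibration_age = root_age)
  expect_equal(cal$ages, free$ages, tolerance = 1e-9)
  expect_equal(cal$rate_used, mu, tolerance = 1e-12)
  # a different calibration rescales ages and re-estimates the rate
  cal2 <- strict_clock_fit(topo, d, rate = mu,
                           root_calibration_age = 11.3e6)
  expect_equal(unname(cal2$ages[["4"]]), 11.3e6)
  expect_equal(cal2$rate_used * 11.3e6, mu * root_age, tolerance = 1e-9)
})

test_that("monotonicity violations are pooled rather than inverted", {
  # child raw age above parent raw age must collapse to a common age
  topo <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- 0.06                      # cherry looks older ...
  d["a", "c"] <- d["b", "c"] <- 0.03       # ... than the root
  d <- d + t(d)
  fit <- strict_clock_fit(topo, d, rate = 1e-7)
  expect_lte(unname(fit$ages[["5"]]), unname(fit$ages[["4"]]) + 1e-9)
  expect_true(ape::is.ultrametric(fit$chronogram, tol = 1e-6))
  # pooled value is the weighted mean of the raw node estimates
  expect_equal(unname(fit$ages[["4"]]),
               mean(c(0.06 / 2, 0.03 / 2, 0.03 / 2)) / 1e-7)
})

test_that("saturated distances abort dating with the offending pairs named", {
  topo <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- 0.01
  d["a", "c"] <- d["b", "c"] <- NA
  d <- matrix(pmax(d, t(d), na.rm = FALSE), 3, dimnames = dimnames(d))
  d["b", "a"] <- 0.01
  expect_error(strict_clock_fit(topo, d, rate = 1e-7), "a-c")
})
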