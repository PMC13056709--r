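test_that("size factors are depth over median depth, NA for empty cells", {
  m <- matrix(0L, nrow = 2, ncol = 3,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  m[1, ] <- c(100L, 200L, 400L)
  expect_equal(unname(size_factors(m)), c(0.5, 1, 2))

  m2 <- cbind(m, c4 = c(0L, 0L))
  rownames(m2) <- c("g1", "g2")
  expect_equal(unname(size_factors(m2)), c(0.5, 1, 2, NA))

  all_same <- matrix(5L, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_equal(unname(size_factors(all_same)), c(1, 1, 1))
  # overall scaling leaves the factors unchanged
  expect_equal(size_factors(m * 3L), size_factors(m))
  zeros <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(zeros), "zero depth")
})

test_that("the expression floor keeps mean >= threshold and matches dense row means", {
  withr::local_seed(19)
  m <- matrix(rpois(100 * 50, 0.9), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:50)))
  mask <- filter_low_expression(m, 1)
  expect_identical(unname(mask), unname(rowMeans(m) >= 1))

  g <- matrix(0L, 1, 100, dimnames = list("g", sprintf("c%03d", 1:100)))
  g[1, 1:99] <- 1L
  expect_false(filter_low_expression(g, 1)[["g"]])  # mean 0.99 drops
  g[1, 100] <- 1L
  expect_true(filter_low_expression(g, 1)[["g"]])   # mean 1.00 keeps
})

test_that("moment dispersion is 0 for constant genes and recovers Poisson and NB truth", {
  m <- matrix(3L, nrow = 2, ncol = 40,
              dimnames = list(c("g1", "g2"), sprintf("c%02d", 1:40)))
  grp <- rep(c("a", "b"), each = 20)
  expect_equal(unname(estimate_dispersion(m, grp, shrinkage_weight = 0)),
               c(0, 0))

  withr::local_seed(20)
  pois <- matrix(rpois(2000 * 200, 5), nrow = 2000,
                 dimnames = list(sprintf("g%04d", 1:2000),
                                 sprintf("c%03d", 1:200)))
  grp <- rep(c("a", "b"), each = 100)
  phi <- estimate_dispersion(pois, grp)
  expect_lte(median(phi), 0.05)

  nb <- matrix(rnbinom(2000 * 200, mu = 5, size = 2), nrow = 2000,
               dimnames = dimnames(pois))
  phi_nb <- estimate_dispersion(nb, grp)
  expect_gte(mean(phi_nb), 0.35)
  expect_lte(mean(phi_nb), 0.65)

  expect_error(estimate_dispersion(pois[, 1:3], c("a", "a", "b")),
               "two cells")
})

test_that("the exact NB test matches brute-force conditional enumeration to 1e-9", {
  for (phi in c(0, 0.5)) {
    for (total in 0:12) {
      for (a in 0:total) {
        expect_equal(
          exact_nb_test(a, total - a, 1, 1, phi),
          oracle_exact_nb_p(a, total, 1, 1, phi),
          tolerance = 1e-9,
          label = sprintf("a=%d T=%d phi=%.1f", a, total, phi))
      }
    }
  }
  # unequal masses and larger totals, spot grid
  for (phi in c(0, 0.3, 1.2)) {
    for (case in list(c(17, 40), c(0, 25), c(55, 60))) {
      expect_equal(
        exact_nb_test(case[1], case[2] - case[1], 1.7, 0.6, phi),
        oracle_exact_nb_p(case[1], case[2], 1.7, 0.6, phi),
        tolerance = 1e-9)
    }
  }
})

test_that("the Poisson equal-mass case reduces to the exact binomial test", {
  expect_equal(exact_nb_test(8, 2, 1, 1, 0), 112 / 1024, tolerance = 1e-12)
  # symmetric observation is never evidence: p = 1
  expect_equal(exact_nb_test(5, 5, 1, 1, 0.7), 1)
  expect_equal(exact_nb_test(0, 0, 1, 1, 0.5), 1)
})

test_that("the exact test is symmetric under group relabelling", {
  withr::local_seed(22)
  for (i in 1:20) {
    total <- sample(0:200, 1)
    a <- sample(0:total, 1)
    nA <- runif(1, 0.5, 2); nB <- runif(1, 0.5, 2)
    phi <- runif(1, 0, 1.5)
    expect_equal(exact_nb_test(a, total - a, nA, nB, phi),
                 exact_nb_test(total - a, a, nB, nA, phi),
                 tolerance = 1e-12)
  }
})

test_that("log2 fold changes are pseudocounted and finite", {
  expect_equal(log2_fold_change(3, 3), 0)
  expect_equal(log2_fold_change(3, 1, 1), 1)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_true(is.finite(log2_fold_change(1e6, 0)))
  expect_error(log2_fold_change(-1, 1), ">= 0")
})

test_that("BH adjustment matches an independent step-up reference", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::local_seed(23)
  for (i in 1:25) {
    p <- runif(sample(1:400, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("run_de recovers planted markers and is symmetric and order-invariant", {
  exp <- tiny_experiment(seed = 24)
  labels <- exp$truth$cell_labels_day0
  type <- "Neuron"
  target <- names(labels)[labels == type]
  baseline <- names(labels)[labels != type]
  de <- run_de(exp$counts_day0, target, baseline)

  markers <- exp$truth$marker_assignment
  mg <- names(markers)[!is.na(markers) & markers == type]
  mg <- intersect(mg, de$gene_id)
  hit <- de$significant[match(mg, de$gene_id)] &
    de$log2fc[match(mg, de$gene_id)] > 0
  expect_gte(mean(hit), 0.9)

  # swap: log2fc negates, p_raw unchanged
  swapped <- run_de(exp$counts_day0, baseline, target)
  expect_equal(swapped$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(swapped$p_raw, de$p_raw, tolerance = 1e-12)

  # cell order is irrelevant
  perm <- sample(ncol(exp$counts_day0))
  de2 <- run_de(exp$counts_day0[, perm], sample(target), sample(baseline))
  expect_equal(de2, de)

  expect_error(run_de(exp$counts_day0, target, c(baseline, target[1])),
               "overlap")
  expect_error(run_de(exp$counts_day0, character(0), baseline), "non-empty")
})

test_that("null comparisons give calibrated sub-uniform p-values", {
  withr::local_seed(25)
  m <- matrix(rnbinom(2000 * 300, mu = 2, size = 2), nrow = 2000,
              dimnames = list(sprintf("g%04d", 1:2000),
                              sprintf("c%03d", 1:300)))
  de <- run_de(m, colnames(m)[1:150], colnames(m)[151:300])
  frac <- mean(de$p_raw < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
  # one-sided KS-style check: the p-value cdf never exceeds uniform by much
  grid <- seq(0.01, 1, by = 0.01)
  excess <- max(vapply(grid, function(t) mean(de$p_raw <= t) - t, numeric(1)))
  expect_lte(excess, 0.03)
})
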