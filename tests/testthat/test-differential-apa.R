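# TSI, exact usage-shift testing, BH-FDR, classification, expression
# coupling and overlap statistics.

test_that("TSI equals the distal usage change for two-site genes", {
  d <- c(100, 600)
  expect_equal(tsi(d, c(50, 50), c(50, 50)), 0)
  expect_equal(tsi(d, c(100, 0), c(0, 100)), 1)
  expect_equal(tsi(d, c(0, 100), c(100, 0)), -1)
  expect_equal(tsi(d, c(80, 20), c(40, 60)), 0.40)
})

test_that("TSI is antisymmetric and bounded in [-1, 1]", {
  set.seed(41)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    d <- sort(sample(50:2000, k))
    a <- rmultinom(1, sample(20:400, 1), runif(k))[, 1]
    b <- rmultinom(1, sample(20:400, 1), runif(k))[, 1]
    if (sum(a) == 0 || sum(b) == 0) next
    t_ab <- tsi(d, a, b)
    expect_equal(t_ab, -tsi(d, b, a), tolerance = 1e-12)
    expect_true(t_ab >= -1 && t_ab <= 1)
  }
})

test_that("single-site genes yield missing TSI", {
  expect_true(is.na(tsi(200, 50, 80)))
  expect_true(is.na(tsi(c(100, 500), c(0, 0), c(10, 10))))
})

test_that("usage-shift test matches hypergeometric enumeration on examples", {
  expect_equal(tsi_test(c(10, 10), c(10, 10)), 1.0)
  expect_equal(tsi_test(c(5, 0), c(0, 5)), 2 / 252, tolerance = 1e-12)
  expect_equal(tsi_test(c(5, 0), c(0, 5)), enum_fisher_p(5, 0, 0, 5),
               tolerance = 1e-12)
})

test_that("zero-margin tables carry no information (p = 1)", {
  expect_equal(tsi_test(c(0, 0), c(5, 7)), 1.0)
  expect_equal(tsi_test(c(5, 0), c(7, 0)), 1.0)
})

test_that("doubling the counts of an unbalanced table strengthens the evidence", {
  p1 <- tsi_test(c(20, 10), c(10, 20))
  p2 <- tsi_test(c(40, 20), c(20, 40))
  expect_lt(p2, p1)
})

test_that("usage-shift p-values equal brute-force enumeration on random tables", {
  set.seed(42)
  for (i in 1:150) {
    tab <- as.vector(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    p_impl <- tsi_test(c(tab[1], tab[2]), c(tab[3], tab[4]))
    margin0 <- (tab[1] + tab[2] == 0) || (tab[3] + tab[4] == 0) ||
      (tab[1] + tab[3] == 0) || (tab[2] + tab[4] == 0)
    p_oracle <- if (margin0) 1.0 else
      enum_fisher_p(tab[1], tab[3], tab[2], tab[4])
    expect_equal(p_impl, p_oracle, tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(43)
  for (n in c(3, 17, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_fdr(p), hand_bh(p), tolerance = 1e-12)
  }
  # NA p-values propagate without affecting the others' n
  p <- c(0.01, NA, 0.04)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], hand_bh(p[c(1, 3)]))
})

test_that("calls follow the FDR-and-sign rule", {
  expect_equal(classify_tsi(0.3, 0.01), "lengthened")
  expect_equal(classify_tsi(-0.3, 0.01), "shortened")
  expect_equal(classify_tsi(0.5, 0.2), "unchanged")
  expect_equal(classify_tsi(0, 0.001), "unchanged")
  expect_true(is.na(classify_tsi(NA, 0.01)))
})

test_that("tsi_table pools replicates, drops single-site genes and classifies", {
  prof <- make_profiles(rep(c("g1", "g2", "g3"), c(2, 2, 1)),
                        distance = c(100, 600, 150, 700, 300),
                        counts = list(a1 = c(80, 20, 50, 50, 30),
                                      a2 = c(82, 18, 52, 48, 30),
                                      b1 = c(20, 80, 49, 51, 30),
                                      b2 = c(20, 80, 51, 49, 30)),
                        samples = c("a1", "a2", "b1", "b2"))
  expect_message(
    tab <- tsi_table(prof, c("a1", "a2"), c("b1", "b2")),
    "single-site")
  expect_setequal(tab$gene_id, c("g1", "g2"))
  g1 <- tab[tab$gene_id == "g1", ]
  expect_equal(g1$proximal_a, 162)
  expect_equal(g1$distal_a, 38)
  expect_equal(g1$tsi, 160 / 200 - 38 / 200, tolerance = 1e-12)
  expect_equal(g1$call, "lengthened")
  expect_equal(tab$call[tab$gene_id == "g2"], "unchanged")
})

test_that("length-change counts respect cut-off nesting", {
  expect_equal(count_length_changes(100, 125, 0.2)$n_lengthened, 1)
  expect_equal(count_length_changes(100, 110, 0.2)$n_lengthened, 0)
  expect_equal(count_length_changes(100, 110, 0.2)$n_shortened, 0)
  set.seed(44)
  la <- runif(300, 100, 2000)
  lb <- la * exp(rnorm(300, 0, 0.2))
  cc <- count_length_changes(la, lb, c(0.05, 0.1, 0.2))
  expect_true(all(diff(cc$n_lengthened) <= 0))
  expect_true(all(diff(cc$n_shortened) <= 0))
  # genes with zero or missing baseline are excluded
  expect_equal(count_length_changes(c(0, 100), c(50, 130), 0.2)$n_evaluated, 1)
})

test_that("expression filter applies the FPKM floor and inclusive fold-change", {
  expect_equal(expression_filter(2.0, 3.0), "up")      # exactly 1.5x
  expect_equal(expression_filter(0.5, 100), "excluded")
  expect_equal(expression_filter(3.0, 2.0), "down")
  expect_equal(expression_filter(2.0, 2.5), "neither")
  expect_equal(expression_filter(c(2, 0.5), c(3, 100)),
               c("up", "excluded"))
})

test_that("binomial trend test is exact and two-sided", {
  expect_equal(binomial_trend_test(5, 5)$p_value, 1.0)
  expect_equal(binomial_trend_test(10, 0)$p_value, 0.001953125,
               tolerance = 1e-12)
  expect_equal(binomial_trend_test(10, 0)$p_value, enum_binom_p(10, 10),
               tolerance = 1e-12)
  expect_equal(binomial_trend_test(13, 4)$p_value, enum_binom_p(13, 17),
               tolerance = 1e-12)
  expect_equal(binomial_trend_test(12, 3)$direction, "down")
  expect_error(binomial_trend_test(0, 0), "no classified genes")
})

test_that("overlap test gives calibrated hypergeometric tails", {
  universe <- sprintf("g%04d", 1:1000)
  # disjoint small sets: no enrichment signal
  r <- overlap_test(universe[1:20], universe[101:120], 1000)
  expect_equal(r$overlap, 0)
  expect_gt(r$p_value, 0.6)
  # identical sets: overwhelming enrichment
  r2 <- overlap_test(universe[1:20], universe[1:20], 1000)
  expect_equal(r2$overlap, 20)
  expect_lt(r2$p_value, 1e-20)
  # overlap at expectation sits in the mid/upper tail band
  r3 <- overlap_test(universe[1:100], universe[c(1:10, 501:590)], 1000)
  expect_equal(r3$overlap, 10)
  expect_equal(r3$expected, 10)
  expect_equal(r3$p_value, 0.5550192, tolerance = 1e-6)
  expect_error(overlap_test(universe, universe[1:5], 500), "universe")
})
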