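# NSAF quantitation and share aggregation.

test_that("NSAF matches the hand SAF oracle and normalizes to 1", {
  sc <- spectral_counts("s1", c("p1", "p2"), "MAG_1", c(10, 10),
                        c(100, 200))
  out <- nsaf(sc)
  expect_equal(out$nsaf, c(2 / 3, 1 / 3))  # SAF 0.1 vs 0.05
  one <- nsaf(spectral_counts("s1", "p1", "MAG_1", 5, 300))
  expect_equal(one$nsaf, 1)
  trio <- nsaf(spectral_counts("s1", c("a", "b", "c"), "MAG_1",
                               rep(7, 3), rep(400, 3)))
  expect_equal(trio$nsaf, rep(1 / 3, 3))
})

test_that("NSAF sums to 1 for arbitrary count tables, zeros get 0", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    sc <- spectral_counts("s", sprintf("p%03d", 1:n),
                          sample(c("A", "B", "contaminant"), n, TRUE),
                          c(1, rnbinom(n - 1, mu = 8, size = 1)),
                          round(runif(n, 50, 2000)))
    out <- nsaf(sc)
    expect_equal(sum(out$nsaf), 1, tolerance = 1e-12)
    expect_true(all(out$nsaf[sc$spectral_count == 0] == 0))
  }
  zeros <- spectral_counts("s", c("p1", "p2"), "A", c(0, 0), c(100, 100))
  expect_error(nsaf(zeros), "undefined")
})

test_that("spectral-count validation rejects bad records", {
  expect_error(spectral_counts("s", "p", "A", -1, 100), "non-negative")
  expect_error(spectral_counts("s", "p", "A", 1.5, 100), "integral")
  expect_error(spectral_counts("s", "p", "A", 1, 0), "positive")
  expect_error(spectral_counts("s", c("p", "p"), "A", c(1, 2),
                               c(10, 10)), "duplicated")
})

test_that("bin shares partition to 100% and respect exclusions", {
  sc <- spectral_counts("s", sprintf("p%d", 1:6),
                        c("A", "A", "B", "B", "contaminant", "B"),
                        c(5, 10, 4, 8, 20, 3),
                        c(100, 120, 500, 900, 80, 100))
  tab <- nsaf(sc)
  bins <- unique(tab$bin)
  shares <- vapply(bins, function(b) bin_share(tab, b), numeric(1))
  expect_equal(sum(shares), 100, tolerance = 1e-10)
  expect_true(all(shares >= 0 & shares <= 100))
  one_bin <- nsaf(spectral_counts("s", c("x", "y"), "A", c(1, 2),
                                  c(10, 10)))
  expect_equal(bin_share(one_bin, "A"), 100)
  expect_error(bin_share(tab, "nope"), "unknown bin")
  expect_equal(bin_share(tab, "nope", allow_missing = TRUE), 0)
  # excluding the contaminant bin renormalizes the base
  excl <- bin_share(tab, "A", exclude_bins = "contaminant")
  keep <- tab$bin != "contaminant"
  expect_equal(excl, 100 * sum(tab$nsaf[tab$bin == "A"]) /
                 sum(tab$nsaf[keep]))
  expect_gt(excl, bin_share(tab, "A"))
})

test_that("protein-set shares support sample and within-bin bases", {
  sc <- spectral_counts("s", sprintf("p%d", 1:5),
                        c("A", "A", "A", "B", "B"),
                        c(2, 3, 5, 10, 10),
                        c(100, 100, 100, 100, 100))
  tab <- nsaf(sc)
  expect_equal(protein_set_share(tab, sprintf("p%d", 1:5)), 100)
  expect_equal(protein_set_share(tab, character(0)), 0)
  # within-bin renormalization: p1+p2 hold 5/10 of bin A's counts
  expect_equal(protein_set_share(tab, c("p1", "p2"), base = "bin",
                                 bin = "A"), 50)
  expect_error(protein_set_share(tab, c("p1", "p4"), base = "bin",
                                 bin = "A"), "not contained")
  expect_error(protein_set_share(tab, "ghost"), "unknown protein")
})

test_that("replicate averaging is the mean of per-sample NSAF", {
  sc <- spectral_counts(rep(c("s1", "s2"), each = 2),
                        c("p1", "p2", "p1", "p2"),
                        "A", c(10, 10, 30, 10), c(100, 100, 100, 100))
  per <- nsaf_by_sample(sc)
  expect_equal(sum(per$nsaf[per$sample == "s1"]), 1)
  expect_equal(sum(per$nsaf[per$sample == "s2"]), 1)
  m <- nsaf_mean(sc)
  expect_equal(m$mean_nsaf[m$protein == "p1"], mean(c(0.5, 0.75)))
  expect_equal(sum(m$mean_nsaf), 1, tolerance = 1e-12)
})
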