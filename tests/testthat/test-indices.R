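test_that("the tabulated thalidomide partition yields the six worked-example values", {
  p <- thalidomide_partition()
  expect_equal(round(abc_r(p)$value, 4), 5.9115)
  expect_equal(round(ga_index(p)$value, 4), 20.3429)
  expect_equal(round(sdd_index(p)$value, 4), 48.3333)
  expect_equal(round(ga_pi(p)$value, 3), 570.213)
  expect_identical(e_pi1(p)$ln, 104)          # via sum over edges of ds+dt
  expect_identical(e_pi2(p)$ln, 127)
  expect_equal(format(e_pi1(p)), "1.46766e45")
  expect_equal(format(e_pi2(p)), "1.43020e55")
})

test_that("two-vertex and path graphs give the closed-form index values", {
  k2 <- make_k2()
  ix <- compute_indices(k2)
  expect_equal(ix$ABC_R$value, -1)            # (sqrt(0) - 1)/sqrt(1)
  expect_equal(ix$GA$value, 1)
  expect_equal(ix$SDD$value, 2)
  expect_equal(ix$GAPi$value, 1)
  expect_identical(ix$EPi1$ln, 2)
  expect_identical(ix$EPi2$ln, 1)

  p3 <- path_graph(3)
  expect_identical(e_pi2(p3)$ln, 4)           # two edges of class (1,2)
  expect_equal(ga_pi(p3, method = "edgewise")$value, 8 / 9)

  # every edge term of GA is 1 on a regular graph, so GA equals |E|
  c6 <- cycle_graph(6)
  expect_equal(ga_index(c6)$value, 6)
})

test_that("fixture drugs reproduce the hand-verifiable tabulated values", {
  drugs <- drug_records()
  expect_equal(round(abc_r(drugs[["Metformin"]]$graph)$value, 4), 2.1268)
  expect_equal(round(abc_r(drugs[["Minocycline"]]$graph)$value, 4), 11.6827)
  expect_equal(sdd_index(drugs[["Minocycline"]]$graph)$value, 99.75)
  expect_equal(sdd_index(drugs[["Valproic Acid"]]$graph)$value, 22)
  expect_identical(e_pi1(drugs[["Valproic Acid"]]$graph)$ln, 38)
  expect_equal(round(ga_pi(drugs[["Valproic Acid"]]$graph)$value, 2), 12.80)
})

test_that("class-wise GAPi follows the 4-decimal contribution convention", {
  p <- thalidomide_partition()
  # contributions 3.4641 x 4 x 5.8788 x 7 under the tabulation convention
  expect_equal(ga_pi(p, contribution_digits = 4)$value,
               3.4641 * 4 * 5.8788 * 7)
  # full-precision product is slightly lower
  full <- ga_pi(p, contribution_digits = NULL)$value
  expect_equal(full, 570.2111, tolerance = 1e-6)
  # single-class graph reduces to frequency x term under either convention
  expect_equal(ga_pi(cycle_graph(5))$value, 5)
})

test_that("class-wise evaluation equals brute-force per-edge sums", {
  set.seed(101)
  for (i in 1:40) {
    g <- random_molecular_graph(sample(5:40, 1))
    bf <- brute_force_indices(g)
    p <- edge_partition(g)
    expect_equal(abc_r(p)$value, bf$abc_r, tolerance = 1e-12)
    expect_equal(ga_index(p)$value, bf$ga, tolerance = 1e-12)
    expect_equal(sdd_index(p)$value, bf$sdd, tolerance = 1e-12)
    expect_identical(e_pi1(p)$ln, as.numeric(bf$ln_epi1))
    expect_identical(e_pi2(p)$ln, as.numeric(bf$ln_epi2))
    expect_equal(ga_pi(p, method = "edgewise")$value, bf$ga_pi_edgewise,
                 tolerance = 1e-12)
  }
})

test_that("index bounds hold on fixtures and random graphs", {
  graphs <- c(lapply(drug_records(), `[[`, "graph"),
              local({
                set.seed(5)
                lapply(1:20, function(i) random_molecular_graph(sample(5:30, 1)))
              }))
  for (g in graphs) {
    m <- nrow(g$edges)
    ga <- ga_index(g)$value
    expect_gt(ga, 0)
    expect_lte(ga / m, 1)
    expect_gte(sdd_index(g)$value, 2 * m)
    ew <- ga_pi(g, method = "edgewise")$value
    expect_gt(ew, 0)
    expect_lte(ew, 1)
  }
})

test_that("all indices are invariant under vertex relabelling", {
  set.seed(13)
  for (i in 1:25) {
    g <- random_molecular_graph(sample(5:30, 1))
    h <- relabel(g, random_permutation(g))
    a <- as.data.frame(compute_indices(g))
    b <- as.data.frame(compute_indices(h))
    expect_equal(a, b)
  }
})

test_that("log-domain values render consistently and round-trip", {
  ix <- e_pi1(thalidomide_partition())
  expect_equal(ix$value, exp(ix$ln), tolerance = 1e-12)
  # mantissa x 10^exponent reproduces the linear scale to 6 significant digits
  expect_equal(ix$mantissa * 10^ix$exponent, ix$value, tolerance = 1e-5)
  # a value too large for double precision lives in log domain only
  big <- topo_index("EPi2", ln = 1000)
  expect_true(is.na(big$value))
  expect_equal(big$exponent, 434L)
  expect_error(topo_index("GA", value = 2, ln = 1), regexp = "disagree")
})
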