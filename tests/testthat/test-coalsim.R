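test_that("prior draws respect bounds and the time-order constraint", {
  pr <- tiny_priors()
  sc <- polyploid_scenario("allopolyploid", "tetrasomic", "bidirectional_AB")
  set.seed(10)
  draws <- replicate(5000, {
    p <- sample_prior(pr, sc)
    c(p$T_split, p$T_WGD, p$N_dip, p$m_dip_to_A, p$m_A_to_dip)
  })
  expect_true(all(draws[2, ] <= draws[1, ]))
  expect_true(all(draws[1, ] >= 1e3 & draws[1, ] <= 1e6))
  expect_true(all(draws[3, ] >= 1e3 & draws[3, ] <= 1e5))
  expect_true(all(draws[4, ] >= 0 & draws[4, ] < 1e-4))
  # marginal of T_split is uniform over its prior
  ks <- ks.test(draws[1, ], "punif", 1e3, 1e6)
  expect_gt(ks$p.value, 0.01)
  # closed migration routes stay closed
  sc0 <- polyploid_scenario("autopolyploid", "tetrasomic", "none")
  set.seed(11)
  p0 <- sample_prior(pr, sc0)
  expect_equal(p0$m_dip_to_A + p0$m_dip_to_B + p0$m_A_to_dip + p0$m_B_to_dip, 0)
})

test_that("datasets are reproducible and respect locus structure", {
  sc <- polyploid_scenario("autopolyploid", "tetrasomic",
                           "unidirectional_dip_to_AB")
  par <- scenario_parameters(m_dip_to_A = 1e-5, m_dip_to_B = 1e-5)
  a <- simulate_dataset(sc, par, n_loci = 5, seed = 3)
  b <- simulate_dataset(sc, par, n_loci = 5, seed = 3)
  expect_identical(lapply(a$loci, `[[`, "mat"), lapply(b$loci, `[[`, "mat"))
  expect_length(a$loci, 5L)
  expect_true(all(a$clock_rates > 0))
  expect_true(all(vapply(a$loci, function(l) all(l$mat %in% 0:1), NA)))
  # vanishing clock rate: no segregating sites
  z <- simulate_dataset(sc, par, n_loci = 3, clock_rates = 1e-20, seed = 4)
  expect_true(all(vapply(z$loci, function(l) ncol(l$mat), 0L) == 0L))
  # clock truncation: all redrawn rates positive even with huge SD
  set.seed(5)
  w <- simulate_dataset(sc, par, n_loci = 200, clock_mean = 1e-10,
                        clock_sd = 5e-10, seed = 6)
  expect_true(all(w$clock_rates > 0))
})

test_that("heterosomic datasets record their disomic locus assignment", {
  sc <- polyploid_scenario("autopolyploid", "heterosomic", "none")
  par <- scenario_parameters(n_disomic_loci = 7L)
  ds <- simulate_dataset(sc, par, n_loci = 20, seed = 9)
  expect_length(ds$disomic_loci, 7L)
  inh <- vapply(ds$loci, `[[`, "", "inheritance")
  expect_equal(which(inh == "disomic"), ds$disomic_loci)
  expect_equal(sum(inh == "tetrasomic"), 13L)
  expect_error(
    simulate_dataset(polyploid_scenario("autopolyploid", "tetrasomic", "none"),
                     par, n_loci = 5),
    "tetrasomic")
})

test_that("deep isolation drives FST toward one", {
  sc <- polyploid_scenario("autopolyploid", "tetrasomic", "none")
  par <- scenario_parameters(T_split = 5e7, T_WGD = 4.9e7, N_dip = 5e4,
                             N_ext = 5e4, N_tet = 5e4, N_anc = 5e4)
  set.seed(12)
  fst <- replicate(300, {
    l <- simulate_locus(sc, par, 2000, 8.62e-10,
                        list(diploid = 6L, tetA = 3L, tetB = 3L))
    locus_stats(l$mat, ifelse(l$pop == "diploid", "A", "B"),
                length = l$length)["FST"]
  })
  expect_gt(mean(fst, na.rm = TRUE), 0.8)
})

test_that("disomic and tetrasomic coincide when the WGD is at the present", {
  par <- scenario_parameters(T_split = 4e5, T_WGD = 0, N_ext = 1e5)
  dxy_of <- function(inh) {
    sc <- polyploid_scenario("autopolyploid", inh, "none")
    replicate(800, {
      l <- simulate_locus(sc, par, 1000, 1e-8,
                          list(diploid = 2L, tetA = 3L, tetB = 3L))
      A <- l$mat[l$pop == "tetA", , drop = FALSE]
      B <- l$mat[l$pop == "tetB", , drop = FALSE]
      if (ncol(l$mat) == 0) return(0)
      pA <- colMeans(A); pB <- colMeans(B)
      sum(pA * (1 - pB) + pB * (1 - pA)) / l$length
    })
  }
  set.seed(13)
  d_dis <- dxy_of("disomic")
  d_tet <- dxy_of("tetrasomic")
  se <- sqrt(var(d_dis) / length(d_dis) + var(d_tet) / length(d_tet))
  expect_lt(abs(mean(d_dis) - mean(d_tet)), 3 * se)
})

test_that("infinite inter-subgenome exchange recovers the tetrasomic model", {
  # consistency knob: disomic demes with massive exchange behave as one
  # panmictic deme of size N_tet
  par <- scenario_parameters(T_split = 2e6, T_WGD = 1.9e6, N_tet = 1e5)
  sfs_mass <- function(inh, xm) {
    sc <- polyploid_scenario("autopolyploid", inh, "none")
    set.seed(14)
    tot <- numeric(4)
    for (i in 1:600) {
      l <- simulate_locus(sc, par, 1000, 1e-8,
                          list(diploid = 2L, tetA = 4L, tetB = 4L),
                          inter_subgenome_m = xm)
      tet <- l$mat[l$pop != "diploid", , drop = FALSE]
      s <- folded_sfs(tet)
      tot <- tot + s$counts
    }
    tot / sum(tot)
  }
  m_tet <- sfs_mass("tetrasomic", 0)
  m_mix <- sfs_mass("disomic", 0.4)
  expect_lt(total_variation_test_helper(m_tet, m_mix), 0.05)
})

test_that("ms-style output round-trips block structure", {
  sc <- polyploid_scenario()
  ds <- simulate_dataset(sc, scenario_parameters(), n_loci = 3, seed = 2,
                         sample_sizes = list(diploid = 4L, tetA = 2L,
                                             tetB = 2L))
  path <- tempfile(fileext = ".ms")
  write_ms(ds, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "//"), 3L)
  seg <- as.integer(sub("segsites: ", "", grep("^segsites", lines, value = TRUE)))
  expect_equal(seg, vapply(ds$loci, function(l) ncol(l$mat), 0L))
})
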