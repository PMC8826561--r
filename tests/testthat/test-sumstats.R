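test_that("locus statistics handle fixed and invariant edge cases", {
  # one site, A fixed 0, B fixed 1
  mat <- matrix(c(0, 0, 1, 1), ncol = 1)
  st <- locus_stats(mat, c("A", "A", "B", "B"), length = 1)
  expect_equal(unname(st[c("sf", "ss", "sxA", "sxB")]), c(1, 0, 0, 0))
  expect_equal(unname(st["FST"]), 1)
  expect_equal(unname(st["Dxy"]), 1)
  # no variation anywhere
  st0 <- locus_stats(matrix(0, 4, 3), c("A", "A", "B", "B"), length = 10)
  expect_true(all(st0[c("pi_A", "pi_B", "Dxy", "S_A", "S_B")] == 0))
  expect_true(is.na(st0["FST"]))
  expect_error(locus_stats(mat, c("A", "B", "B", "B"), length = 1),
               "at least 2")
})

test_that("diversity matches brute-force pairwise enumeration", {
  set.seed(4)
  for (rep in 1:10) {
    mat <- matrix(rbinom(4 * 10, 1, 0.4), 4, 10)
    st <- locus_stats(mat, c("A", "A", "B", "B"), length = 10)
    expect_equal(unname(st["pi_A"]), oracle_pi(mat[1:2, , drop = FALSE], 10))
    expect_equal(unname(st["pi_B"]), oracle_pi(mat[3:4, , drop = FALSE], 10))
    # FST from the independent within/total decomposition
    pw <- (oracle_pi(mat[1:2, , drop = FALSE], 10) +
             oracle_pi(mat[3:4, , drop = FALSE], 10)) / 2
    pt <- oracle_pi(mat, 10)
    if (pt > 0)
      expect_equal(unname(st["FST"]), 1 - pw / pt)
    # Dxy by direct between-population averaging
    dxy <- mean(c(sum(mat[1, ] != mat[3, ]), sum(mat[1, ] != mat[4, ]),
                  sum(mat[2, ] != mat[3, ]), sum(mat[2, ] != mat[4, ]))) / 10
    expect_equal(unname(st["Dxy"]), dxy)
    # polymorphism categories always partition the biallelic sites
    expect_equal(unname(st["sf"] + st["ss"] + st["sxA"] + st["sxB"]),
                 unname(st["bialsites"]))
  }
})

test_that("polymorphism categories partition sites on larger samples", {
  set.seed(5)
  for (rep in 1:10) {
    mat <- matrix(rbinom(12 * 30, 1, runif(1, 0.1, 0.5)), 12, 30)
    pop <- rep(c("A", "B"), each = 6)
    st <- locus_stats(mat, pop, length = 30)
    expect_equal(unname(st["sf"] + st["ss"] + st["sxA"] + st["sxB"]),
                 unname(st["bialsites"]))
  }
})

test_that("nucleotide and binary paths agree on complete data", {
  set.seed(6)
  bin <- matrix(rbinom(6 * 20, 1, 0.3), 6, 20)
  nuc <- matrix("A", 6, 20)
  nuc[bin == 1] <- "G"
  pop <- rep(c("A", "B"), each = 3)
  st_b <- locus_stats(bin, pop, length = 20)
  st_n <- locus_stats(nuc, pop)
  expect_equal(st_b, st_n)
})

test_that("stat vectors aggregate with population SD and NA bookkeeping", {
  row <- locus_stats(matrix(c(0, 1, 0, 1), 4), c("A", "A", "B", "B"),
                     length = 1)
  sv1 <- dataset_stat_vector(rbind(row, row, row))
  expect_true(all(sv1$sd[!is.na(sv1$sd)] == 0))
  expect_equal(sv1$mean, row[names(sv1$mean)])
  sv2 <- dataset_stat_vector(rbind(row))
  expect_true(all(sv2$sd[!is.na(sv2$sd)] == 0))
  # independent recomputation on a random table
  set.seed(7)
  tab <- matrix(rnorm(20 * 16), 20, 16,
                dimnames = list(NULL, names(row)))
  tab[sample(length(tab), 10)] <- NA
  sv3 <- dataset_stat_vector(tab)
  for (cn in colnames(tab)) {
    x <- tab[, cn]; x <- x[!is.na(x)]
    expect_equal(unname(sv3$mean[cn]), mean(x))
    expect_equal(unname(sv3$sd[cn]), sqrt(mean((x - mean(x))^2)))
  }
  expect_equal(unname(sv3$n_undefined), colSums(is.na(tab)), ignore_attr = TRUE)
})

test_that("neutral panmictic Tajima's D centers on zero", {
  sc <- polyploid_scenario("autopolyploid", "tetrasomic", "none")
  par <- scenario_parameters(T_split = 0, T_WGD = 0, N_anc = 2e5)
  set.seed(8)
  tajd <- replicate(2000, {
    l <- simulate_locus(sc, par, 1500, 5e-9,
                        list(diploid = 8L, tetA = 1L, tetB = 1L))
    m <- l$mat[l$pop == "diploid", , drop = FALSE]
    S <- sum(colSums(m) > 0 & colSums(m) < nrow(m))
    if (S == 0) return(NA_real_)
    locus_stats(l$mat, ifelse(l$pop == "diploid", "A", "B"),
                length = l$length)["TajD_A"]
  })
  tajd <- tajd[!is.na(tajd)]
  se <- sd(tajd) / sqrt(length(tajd))
  expect_lt(abs(mean(tajd)), 3 * se + 0.05)
})

test_that("folded spectra count minor alleles and the 50% mass", {
  mat <- matrix(0, 8, 1); mat[1:4, 1] <- 1
  s <- folded_sfs(mat)
  expect_equal(s$mass_at_half, 1)
  expect_equal(s$n_snps, 1L)
  expect_equal(sum(s$mass), 1)
  s0 <- folded_sfs(matrix(0, 8, 5))
  expect_equal(s0$n_snps, 0L)
  expect_equal(s0$mass_at_half, 0)
  # odd sample size: mass at half undefined
  expect_true(is.na(folded_sfs(matrix(c(0, 1, 0), 3, 1))$mass_at_half))
})

test_that("the k-locus randomization test flags constructed outliers", {
  set.seed(9)
  base <- matrix(rnorm(40 * 16, 0, 1), 40, 16,
                 dimnames = list(NULL, c("S_A", "S_B", "pi_A", "pi_B",
                                         "thetaW_A", "thetaW_B", "TajD_A",
                                         "TajD_B", "Dxy", "Da", "FST", "sf",
                                         "ss", "sxA", "sxB", "bialsites")))
  r1 <- randomization_test_loci(base, observed_loci = 1:10, n_reps = 200,
                                seed = 1)
  r2 <- randomization_test_loci(base, observed_loci = 1:10, n_reps = 200,
                                seed = 1)
  expect_identical(r1, r2)
  # k = all loci: the null is degenerate at the observed value
  rall <- randomization_test_loci(base, observed_loci = 1:40, n_reps = 50,
                                  seed = 2)
  expect_false(any(rall$outside))
  # inflate pi_A in a designated subset
  infl <- base
  infl[1:10, "pi_A"] <- infl[1:10, "pi_A"] + 50
  rinf <- randomization_test_loci(infl, observed_loci = 1:10, n_reps = 300,
                                  seed = 3)
  expect_true(rinf$outside[rinf$statistic == "mean_pi_A"])
  expect_error(randomization_test_loci(base, 1:50), "exceeds")
})
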