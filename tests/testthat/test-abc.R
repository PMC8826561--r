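# toy reference table with Gaussian statistic clouds per model
toy_table <- function(n_per_model, means, sd = 1, p = 8, seed = 1) {
  set.seed(seed)
  stats <- do.call(rbind, lapply(means, function(mu)
    matrix(rnorm(n_per_model * p, mu, sd), n_per_model, p)))
  colnames(stats) <- paste0("stat", seq_len(p))
  list(model = rep(names(means), each = n_per_model), stats = stats)
}

test_that("lnML-to-probability conversion is a stable softmax", {
  expect_equal(unname(model_probabilities_from_lnml(c(a = -10, b = -10,
                                                      c = -10, d = -10))),
               rep(0.25, 4))
  p1 <- model_probabilities_from_lnml(c(a = -117000, b = -117002.5))
  p2 <- model_probabilities_from_lnml(c(a = 0, b = -2.5))
  expect_equal(p1, p2)  # shift invariance
  withNA <- model_probabilities_from_lnml(c(a = -1, b = NA, c = -2))
  expect_length(withNA, 2L)
  expect_equal(sum(withNA), 1)
  expect_error(model_probabilities_from_lnml(c(a = -1, b = NA)), "two models")
  expect_error(model_probabilities_from_lnml(c(a = Inf, b = 0)), "finite")
})

test_that("rejection step retains the nearest rows with kernel weights", {
  tab <- toy_table(250, list(m1 = 0, m2 = 3), seed = 2)
  obs <- setNames(rep(0, 8), colnames(tab$stats))
  all_in <- abc_reject(obs, tab$stats, tolerance = 1)
  expect_length(all_in$idx, 500L)
  # observed equal to a table row: that row is retained with weight 1
  obs_row <- tab$stats[42, ]
  r <- abc_reject(obs_row, tab$stats, tolerance = 0.02)
  expect_equal(r$idx[1], 42L)
  expect_equal(r$weights[1], 1)
  expect_equal(r$dist[1], 0)
  # equals brute-force k-nearest on MAD-scaled Euclidean distance
  sc <- apply(tab$stats, 2, mad)
  d <- sqrt(colSums((t(tab$stats) / sc - obs / sc)^2))
  k <- ceiling(0.05 * 500)
  expect_setequal(abc_reject(obs, tab$stats, tolerance = 0.05)$idx,
                  order(d)[1:k])
  expect_error(abc_reject(obs, tab$stats, tolerance = 0), "tolerance")
  expect_error(abc_reject(obs[-1], tab$stats[, -1], tolerance = 0.1), NA)
})

test_that("model choice is symmetric for identical generators", {
  obs <- setNames(rep(0, 8), paste0("stat", 1:8))
  # fresh table per repetition: the symmetry claim is about the procedure,
  # including the table randomness, not one fixed table
  probs <- vapply(1:20, function(s) {
    tab <- toy_table(600, list(m1 = 0, m2 = 0), seed = 100 + s)
    suppressWarnings(
      abc_model_choice(obs, tab, tolerance = 0.25, n_nets = 10,
                       n_hidden = 4, seed = s)$prob["m1"])
  }, 0)
  expect_lt(abs(mean(probs) - 0.5), 0.1)
  # rejection fallback equals the weighted label frequency
  tab <- toy_table(600, list(m1 = 0, m2 = 0), seed = 3)
  mc <- abc_model_choice(obs, tab, tolerance = 0.1, seed = 1,
                         method = "rejection")
  rej <- abc_reject(obs, tab$stats, tolerance = 0.1)
  labs <- tab$model[rej$idx]
  expect_equal(unname(mc$prob["m1"]),
               sum(rej$weights[labs == "m1"]) / sum(rej$weights))
  expect_equal(sum(mc$prob), 1)
})

test_that("parameter posterior recovers an identifiable toy parameter", {
  # single statistic = parameter + small noise
  set.seed(11)
  n <- 3000
  theta <- runif(n, 0, 10)
  stats <- cbind(s1 = theta + rnorm(n, 0, 0.1))
  tab <- list(stats = stats, params = cbind(theta = theta))
  obs <- c(s1 = 4)
  pp <- abc_parameter_posterior(obs, tab, bounds = list(theta = c(0, 10)),
                                n_keep = 500, n_nets = 10, n_hidden = 4,
                                seed = 2)
  expect_true(all(pp$samples >= 0 & pp$samples <= 10))
  expect_lt(abs(pp$pdv["theta"] - 4) / 4, 0.05)
  expect_lte(pp$ci["q05", "theta"], pp$ci["q95", "theta"])
  expect_gte(pp$pdv["theta"], pp$ci["q05", "theta"])
  expect_lte(pp$pdv["theta"], pp$ci["q95", "theta"])

  # PDV/CI match a brute-force weighted density/quantile oracle
  rej <- abc_reject(obs, tab$stats, n_keep = 500)
  raw <- abc_parameter_posterior(obs, tab, bounds = list(theta = c(0, 10)),
                                 n_keep = 500, adjust = FALSE)
  w <- rej$weights / sum(rej$weights)
  x <- tab$params[rej$idx, "theta"]
  dens <- density(x, weights = w, bw = "nrd0")
  expect_equal(unname(raw$pdv["theta"]), dens$x[which.max(dens$y)],
               tolerance = 1e-6)
  expect_equal(unname(raw$ci["q05", "theta"]),
               oracle_wq_step(x, w, 0.05), tolerance = 0.1)
})

test_that("robustness arithmetic and the symmetric-model baseline", {
  expect_equal(robustness_statistic(0.8, 0.2), 0.8)
  expect_equal(robustness_statistic(0.5, 0.5), 0.5)
  # identical scenarios on both sides: R near 0.5 (scaled n_pseudo)
  sc <- polyploid_scenario("autopolyploid", "tetrasomic", "none")
  pr <- tiny_priors()
  models <- list(m1 = sc, m2 = sc)
  set.seed(4)
  tab <- build_reference_table(models, pr, n_sims = 150, n_loci = 4,
                               locus_length = 500,
                               sample_sizes = list(diploid = 4L, tetA = 2L,
                                                   tetB = 2L), seed = 5)
  rb <- robustness_assessment(models, pr, tab, n_pseudo = 40,
                              tolerance = 0.1, method = "rejection",
                              n_loci = 4, locus_length = 500,
                              sample_sizes = list(diploid = 4L, tetA = 2L,
                                                  tetB = 2L), seed = 6)
  expect_true(all(abs(rowSums(rb$P) - 1) < 1e-9))
  expect_lt(abs(rb$robustness - 0.5), 0.12)
})

test_that("published descendance lnMLs load with expected shape", {
  tab <- migrate_lnml_table()
  expect_equal(nrow(tab), 12L)
  expect_named(tab, c("model", "NE", "MW", "SW"))
  expect_equal(sum(is.na(tab$NE)), 4L)
  expect_equal(sum(is.na(tab$MW)), 3L)
})
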