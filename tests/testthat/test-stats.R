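test_that("spearman correlation handles monotone and antitone relations", {
  x <- 1:10
  expect_equal(spearman_cor(x, 2 * x)$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  expect_lt(spearman_cor(x, -x^3)$p, 1e-6)
  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("spearman null distribution is honest at moderate n", {
  set.seed(53)
  reps <- 300
  rhos <- replicate(reps, spearman_cor(runif(500), runif(500))$rho)
  expect_gte(mean(abs(rhos) < 0.12), 0.99)
  # p-values roughly uniform: ~5% below 0.05
  ps <- replicate(200, spearman_cor(rnorm(40), rnorm(40))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
})

test_that("exact p-values are used for small tie-free samples", {
  set.seed(59)
  x <- rnorm(8); y <- rnorm(8)
  got <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$p, ref$p.value)
  expect_equal(got$rho, unname(ref$estimate))
})

test_that("bonferroni caps at 1 and scales by the family size", {
  expect_equal(bonferroni(0.01, m = 41), 0.41)
  expect_equal(bonferroni(1e-16, m = 8), 8e-16)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

simulate_null_obs <- function(n, b_size = 0, sd_eps = 1) {
  comp <- matrix(stats::rgamma(4 * n, 10), ncol = 4)
  comp <- comp / rowSums(comp)
  colnames(comp) <- c("A", "C", "G", "T")
  S <- stats::rnorm(n, 10, 2)
  D <- 50 * comp[, "C"] + b_size * S + stats::rnorm(n, sd = sd_eps)
  data.frame(D = D, A = comp[, "A"], C = comp[, "C"], G = comp[, "G"],
             T = comp[, "T"], S = S)
}

test_that("nested model recovers a perfect composition fit", {
  set.seed(61)
  obs <- simulate_null_obs(300, sd_eps = 0)   # D exactly linear in C
  # summary.lm warns about the (deliberately) perfect fit
  nm <- suppressWarnings(nested_size_model(obs))
  expect_equal(nm$r2_B, 1, tolerance = 1e-9)
  expect_equal(nm$delta_r2, 0, tolerance = 1e-9)
  expect_error(nested_size_model(obs[1:5, ]), "at least 8")
  bad <- obs; bad$G <- bad$A                  # collinear after the T drop
  expect_error(nested_size_model(bad), "collinear")
})

test_that("nested-model size term is well calibrated under the null", {
  set.seed(67)
  reps <- 200
  res <- t(replicate(reps, {
    nm <- nested_size_model(simulate_null_obs(300))
    c(p = nm$p_size, d = nm$delta_r2)
  }))
  rate <- mean(res[, "p"] < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci + 0.02)
  expect_lt(abs(median(res[, "d"])), 0.02)
})

test_that("nested model detects a planted genome-size effect", {
  set.seed(71)
  reps <- 100
  # standardised size effect ~ -0.3 given sd(50C) ~ 3.4, sd(eps) = 2
  res <- t(replicate(reps, {
    nm <- nested_size_model(simulate_null_obs(300, b_size = -0.62,
                                              sd_eps = 2))
    c(p = nm$p_size, d = nm$delta_r2)
  }))
  expect_gte(mean(res[, "p"] < 0.01 & res[, "d"] > 0.05), 0.95)
})

test_that("adding an irrelevant covariate does not raise adjusted R2 on average", {
  set.seed(73)
  deltas <- replicate(200, nested_size_model(simulate_null_obs(120))$delta_r2)
  expect_lte(mean(deltas), 0)
})

test_that("rank response is invariant to monotone transforms of disorder", {
  set.seed(79)
  obs <- simulate_null_obs(200)
  obs$D <- obs$D - min(obs$D) + 1
  a <- nested_size_model(obs, response = "rank")
  obs2 <- obs; obs2$D <- log(obs$D)^3 + 5 * log(obs$D)
  b <- nested_size_model(obs2, response = "rank")
  expect_equal(a$r2_B, b$r2_B)
  expect_equal(a$p_size, b$p_size)
})

make_family_obs <- function(means, n_per = 50, sd_D = 1) {
  do.call(rbind, lapply(seq_along(means), function(i) {
    o <- simulate_null_obs(n_per)
    o$D <- stats::rnorm(n_per, means[i], sd_D)
    o$family <- sprintf("Fam%d", i)
    o$baltimore_type <- c("ssDNA", "dsDNA")[1 + i %% 2]
    o$host_category <- "Plants"
    o$accession <- sprintf("F%dG%03d", i, seq_len(n_per))
    o
  }))
}

test_that("group summaries recover planted family means and conserve N", {
  set.seed(83)
  obs <- make_family_obs(c(5, 15, 25))
  gs <- group_summaries(obs, "family")
  expect_equal(gs$mean_D, c(5, 15, 25), tolerance = 1)
  expect_equal(sum(gs$N), nrow(obs))
  expect_equal(gs$range_D, gs$max_D - gs$min_D)
  # Bonferroni across the table's own rows
  expect_equal(gs$spearman_p_corrected,
               pmin(1, nrow(gs) * gs$spearman_p))
})

test_that("a single all-encompassing group equals the direct nested fit", {
  set.seed(89)
  obs <- make_family_obs(10)[, ]
  gs <- group_summaries(obs, "family")
  nm <- nested_size_model(obs)
  expect_equal(gs$r2_B, nm$r2_B)
  expect_equal(gs$r2_BS, nm$r2_BS)
  expect_equal(gs$p_size, nm$p_size)
  sp <- spearman_cor(obs$S, obs$D)
  expect_equal(gs$spearman_rho, sp$rho)
})

test_that("host summaries join the external host disorder table", {
  set.seed(97)
  obs <- make_family_obs(c(8, 20))
  obs$host_category <- rep(c("Plants", "Bacteria"), each = 50)
  ht <- data.frame(host_category = c("Plants", "Bacteria"),
                   host_mean = c(20.1, 7.4), host_min = c(11.5, 2.3),
                   host_max = c(28.9, 19.5))
  gs <- group_summaries(obs, "host_category", host_table = ht)
  expect_equal(gs$host_mean[gs$group == "Plants"], 20.1)
  expect_equal(gs$range_D, gs$max_D - gs$min_D)
})

test_that("variance attribution ranks a purely family-driven signal first", {
  set.seed(101)
  obs <- make_family_obs(c(3, 10, 17, 24, 31), n_per = 40)
  va <- variance_attribution(obs)
  r2 <- setNames(va$adj_r2, va$spec_name)
  expect_gt(r2[["family"]], r2[["bases"]])
  expect_gt(r2[["family"]], r2[["size"]])
  # intercept-only model explains nothing
  va0 <- variance_attribution(obs, specs = list(null = character(0)))
  expect_equal(va0$adj_r2, 0, tolerance = 1e-12)
  expect_error(variance_attribution(obs, specs = list(x = "nope")),
               "unknown")
})

test_that("bases+size minus bases equals the nested-model delta", {
  set.seed(103)
  obs <- make_family_obs(c(5, 12), n_per = 60)
  va <- variance_attribution(obs, specs = list(bases = c("A", "C", "G"),
                                               bases_size = c("A", "C", "G", "S")))
  nm <- nested_size_model(obs)
  d <- va$adj_r2[va$spec_name == "bases_size"] -
    va$adj_r2[va$spec_name == "bases"]
  expect_equal(d, nm$delta_r2, tolerance = 1e-12)
})

test_that("composition-disorder table has 8 rows and finds a perfect driver", {
  set.seed(107)
  obs <- simulate_null_obs(100)
  obs$A4 <- obs$A; obs$C4 <- obs$C; obs$G4 <- obs$G; obs$T4 <- obs$T
  obs$D <- 100 * obs$C                    # perfect monotone function of C
  tab <- composition_disorder_correlations(obs)
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$rho[tab$base == "C" & tab$site_class == "all"], 1)
  # shuffled disorder kills every correlation
  obs$D <- sample(obs$D)
  tab2 <- composition_disorder_correlations(obs)
  expect_true(all(abs(tab2$rho) < 0.3))
})
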