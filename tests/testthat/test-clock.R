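test_that("LG transition matrices are stochastic and detailed-balanced", {
  pi <- unname(lg_frequencies())
  for (t in c(0.01, 0.1, 0.5, 2)) {
    P <- lg_transition(t)
    expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-10)
    # detailed balance: pi_i P_ij = pi_j P_ji
    flux <- pi * P
    expect_equal(flux, t(flux), tolerance = 1e-10, ignore_attr = TRUE)
  }
  # scaled to one expected substitution per site per unit time
  Q <- smtphylo:::lg_eigen()$Q
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
})

test_that("gamma category rates average one and collapse as shape grows", {
  for (shape in c(0.2, 0.8, 3)) {
    r <- gamma_category_rates(shape, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(gamma_category_rates(1e6, 4), rep(1, 4), tolerance = 1e-3)
  expect_error(gamma_category_rates(-1), "positive")
})

test_that("pruning likelihood equals exhaustive state enumeration", {
  tr <- parse_newick("((A:0.1,B:0.25):0.15,C:0.4);")
  # make it a dated tree: ages 0.4 (root), 0.25 (inner); unit rates
  set.seed(8)
  aln <- sim_rates_and_alignment(
    parse_newick("((A:0.25,B:0.25):0.15,C:0.4);"), 0, 2, seed = 8
  )$alignment
  model <- clock_model(parse_newick("((A:0.25,B:0.25):0.15,C:0.4);"),
                       aln, n_gamma_categories = 1)
  ages <- c(0.4, 0.25)
  rates <- rep(1, nrow(model$edges))
  got <- site_likelihood(model, ages, rates, gamma_shape = 1)
  # oracle: brute-force sum over all 20^2 internal assignments
  codes <- matrix(match(aln, smtphylo:::.LG_AA),
                  nrow = nrow(aln))[match(model$topology$tip.label,
                                          rownames(aln)), , drop = FALSE]
  blen_by_node <- rep(NA_real_, 5)
  all_ages <- c(0, 0, 0, ages)
  for (i in seq_len(nrow(model$topology$edge))) {
    v <- model$topology$edge[i, 2]
    blen_by_node[v] <- all_ages[model$topology$edge[i, 1]] - all_ages[v]
  }
  want <- oracle_loglik_enum(model$topology, codes, blen_by_node)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("likelihood limits: zero time gives equilibrium, large shape gives one rate", {
  aln <- as_alignment(c(A = "W", B = "W"))
  tr <- parse_newick("(A:1,B:1);")
  model <- clock_model(tr, aln, n_gamma_categories = 1)
  ll <- site_likelihood(model, ages = 1e-12,
                        rates = rep(1, 2), gamma_shape = 1)
  expect_equal(ll, log(lg_frequencies()[["W"]]), tolerance = 1e-6)
  # gamma_shape -> infinity approaches the single-rate likelihood
  set.seed(12)
  tr4 <- sim_species_tree(4, 1, seed = 12)
  aln4 <- sim_rates_and_alignment(tr4, 0, 40, seed = 13)$alignment
  m4 <- clock_model(tr4, aln4, n_gamma_categories = 4)
  m1 <- clock_model(tr4, aln4, n_gamma_categories = 1)
  ages <- node_ages(tr4)[5:7]
  rates <- rep(1, 6)
  expect_equal(site_likelihood(m4, ages, rates, gamma_shape = 1e7),
               site_likelihood(m1, ages, rates, gamma_shape = 1),
               tolerance = 1e-5)
})

test_that("likelihood is invariant to column permutation and additive in columns", {
  set.seed(21)
  tr <- sim_species_tree(5, 1, seed = 21)
  aln <- sim_rates_and_alignment(tr, 0.3, 30, seed = 22)$alignment
  ages <- node_ages(tr)[6:9]
  rates <- runif(nrow(tr$edge), 0.5, 2)
  m <- clock_model(tr, aln, n_gamma_categories = 4)
  perm <- aln[, sample(ncol(aln)), drop = FALSE]
  mp <- clock_model(tr, perm, n_gamma_categories = 4)
  dbl <- cbind(aln, aln)
  md <- clock_model(tr, dbl, n_gamma_categories = 4)
  l0 <- site_likelihood(m, ages, rates, 0.7)
  expect_equal(site_likelihood(mp, ages, rates, 0.7), l0,
               tolerance = 1e-10)
  expect_equal(site_likelihood(md, ages, rates, 0.7), 2 * l0,
               tolerance = 1e-10)
})

test_that("pruning agrees with an independent LG+Gamma implementation", {
  library(phangorn)
  set.seed(31)
  tr <- sim_species_tree(6, 1, seed = 31)
  aln <- sim_rates_and_alignment(tr, 0, 60, seed = 32)$alignment
  ages <- node_ages(tr)[7:11]
  m <- clock_model(tr, aln, n_gamma_categories = 4)
  ll <- site_likelihood(m, ages, rep(1, nrow(m$edges)), gamma_shape = 0.6)
  fit <- phangorn::pml(tr, phangorn::phyDat(aln, type = "AA"),
                       model = "LG", k = 4, shape = 0.6)
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
})

test_that("the Yule prior has the documented scaling and n = 2 limits", {
  ages <- c(3, 1.2, 0.5)
  lam <- 0.8
  base <- yule_log_prior(ages, lam)
  # scaling ages by c and the rate by 1/c shifts log-density by
  # -(n_internal) log c
  cc <- 2.5
  expect_equal(yule_log_prior(ages * cc, lam / cc),
               base - length(ages) * log(cc), tolerance = 1e-12)
  # 2-taxon tree: exponential density in the root age
  expect_equal(yule_log_prior(2, lam), log(lam) - 2 * lam * 2)
  expect_error(yule_log_prior(ages, 0), "positive")
})

test_that("rate and calibration priors match their closed forms", {
  sig <- 0.4
  rates <- c(0.5, 1, 2)
  expect_equal(rates_log_prior(rates, sig),
               sum(dlnorm(rates, -sig^2 / 2, sig, log = TRUE)))
  # the mean-1 constraint: density maximal at the lognormal mode
  mode_rate <- exp(-sig^2 / 2 - sig^2)
  grid <- seq(0.2, 2, by = 0.001)
  dens <- vapply(grid, function(r) rates_log_prior(r, sig), numeric(1))
  expect_equal(grid[which.max(dens)], mode_rate, tolerance = 2e-3)
  cal <- calibration(c("A", "B"), offset = 10, log_mean = 1, log_sd = 0.5)
  expect_identical(calibration_log_density(10, cal), -Inf)
  expect_equal(calibration_log_density(10 + exp(1), cal),
               dlnorm(exp(1), 1, 0.5, log = TRUE))
})

test_that("mcmc is deterministic per seed and sized by the sampling interval", {
  set.seed(41)
  tr <- sim_species_tree(5, 1, seed = 41)
  aln <- sim_rates_and_alignment(tr, 0, 30, seed = 42)$alignment
  m <- clock_model(tr, aln)
  a <- mcmc(m, 400, sample_every = 50, seed = 9)
  b <- mcmc(m, 400, sample_every = 50, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 400 %/% 50 + 1)
  c2 <- mcmc(m, 400, sample_every = 50, seed = 10)
  expect_false(identical(a$log_posterior, c2$log_posterior))
})

test_that("prior-only sampling matches quadrature on a 3-taxon tree", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  aln <- as_alignment(c(A = "AR", B = "AR", C = "AR"))
  cal <- calibration(c("A", "B", "C"), offset = 1, log_mean = 0,
                     log_sd = 0.5)
  m <- clock_model(tr, aln, list(cal))
  init <- smtphylo:::.clock_init_state(m)
  init$ages <- c(2, 1)
  init$birth_rate <- 1
  tra <- mcmc(m, 40000, sample_every = 10, seed = 5,
              move_weights = c(node_age = 1, root_age = 1,
                               branch_rate = 0, gamma_shape = 0,
                               rate_log_sd = 0, birth_rate = 0),
              use_likelihood = FALSE, init = init)
  keep <- tra[-(1:1000), ]
  # quadrature oracle: density over the root age after integrating the
  # inner node age analytically (Yule: exp(-t_i) on (0, t_r))
  f <- function(tr_) exp(-2 * tr_) * (1 - exp(-tr_)) *
    dlnorm(tr_ - 1, 0, 0.5)
  zz <- integrate(f, 1, 30)$value
  want <- integrate(function(x) x * f(x), 1, 30)$value / zz
  got <- mean(keep$age_4)
  nb <- 10
  m <- (nrow(keep) %/% nb) * nb
  bm <- tapply(keep$age_4[1:m], rep(seq_len(nb), each = m / nb), mean)
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(got - want), 3 * se + 1e-3)
})

test_that("trace summaries use 25% burn-in, medians and HPD intervals", {
  fake <- data.frame(gen = 1:100, age_5 = as.numeric(1:100))
  s <- summarize_trace(fake, 0.25)
  expect_equal(s$median_age, median(26:100))
  const <- data.frame(gen = 1:20, age_5 = rep(4.2, 20))
  s2 <- summarize_trace(const)
  expect_equal(s2$median_age, 4.2)
  expect_equal(s2$hpd_upper - s2$hpd_lower, 0)
  expect_error(summarize_trace(fake, 1), "burn-in")
  # HPD of a normal sample approximates +/- 1.96 sd
  set.seed(3)
  x <- rnorm(20000)
  h <- hpd_interval(x)
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)
})

test_that("calibration files round-trip and unresolvable clades error", {
  cals <- list(calibration(c("A", "B"), 5, 0.2, 0.5),
               calibration(c("C", "D", "E"), 1, 0, 0.3))
  f <- tempfile(fileext = ".tsv")
  write_calibrations(cals, f)
  back <- read_calibrations(f)
  expect_equal(back[[1]]$clade, c("A", "B"))
  expect_equal(back[[2]]$offset, 1)
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  aln <- as_alignment(c(A = "AR", B = "AR", C = "AR"))
  expect_error(
    clock_model(tr, aln, list(calibration(c("A", "Z"), 1, 0, 0.5))),
    "unresolvable"
  )
})
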