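test_that("simulation is deterministic given the seed", {
  p <- sim_params(seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_cohort(p, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("parameter validation rejects malformed settings", {
  expect_error(sim_params(family_size_probs = c(`10` = 0.5)), "sum to 1")
  expect_error(sim_params(allele_freq = c(a = 1.2, b = 0.2)))
  expect_error(sim_params(within_family_sharing = 2))
  expect_error(sim_params(betas = 1:3))
})

test_that("the replication preset matches the study scale", {
  coh <- simulate_cohort(sim_params(), seed = 1)
  expect_equal(length(unique(coh$family_id)), 76L)
  expect_gt(nrow(coh), 850)       # 76 families averaging ~12.5 members
  expect_lt(nrow(coh), 1050)
  car1 <- mean(dominant_code(coh$rs4242382, "A"))
  car2 <- mean(dominant_code(coh$rs10486567, "A"))
  expect_equal(car1, 0.397, tolerance = 0.15)  # 1-(1-0.223)^2
  expect_equal(car2, 0.436, tolerance = 0.15)
  expect_true(all(coh$age >= 40))
  expect_true(all(!coh$aggressive | coh$affected))
})

test_that("carrier frequency converges to the Hardy-Weinberg value", {
  q <- 0.223
  p_car <- 1 - (1 - q)^2
  coh <- simulate_cohort(sim_params(n_families = 1000,
                                    within_family_sharing = 0), seed = 2)
  n <- nrow(coh)
  obs <- mean(dominant_code(coh$rs4242382, "A"))
  se <- sqrt(p_car * (1 - p_car) / n)
  expect_lt(abs(obs - p_car), 2 * se)
})

test_that("without sharing, genotypes are independent within families", {
  coh <- simulate_cohort(sim_params(n_families = 1500,
                                    within_family_sharing = 0), seed = 3)
  first2 <- do.call(rbind, lapply(split(seq_len(nrow(coh)),
                                        coh$family_id), utils::head, 2))
  g <- matrix(dominant_code(coh$rs4242382, "A")[t(first2)],
              ncol = 2, byrow = TRUE)
  ht <- suppressWarnings(chisq.test(table(g[, 1], g[, 2]),
                                    correct = FALSE))
  expect_gt(ht$p.value, 0.01)
})

test_that("sharing raises within-family genotype correlation", {
  corr_of <- function(sharing, seed) {
    coh <- simulate_cohort(sim_params(n_families = 800,
                                      within_family_sharing = sharing),
                           seed = seed)
    first2 <- do.call(rbind, lapply(split(seq_len(nrow(coh)),
                                          coh$family_id),
                                    utils::head, 2))
    g <- matrix(dominant_code(coh$rs4242382, "A")[t(first2)],
                ncol = 2, byrow = TRUE)
    cor(g[, 1], g[, 2])
  }
  expect_gt(corr_of(0.8, 4), corr_of(0, 4) + 0.1)
})

test_that("infeasible rates trigger a truncation warning", {
  p <- sim_params(betas = c(3, 0, 0, 0))  # exp(3) ~ 20 cases expected
  expect_warning(simulate_cohort(p, seed = 5), "truncated")
})

test_that("the contingency fixture is deterministic and strict-valid", {
  a <- fixture_table1()
  b <- fixture_table1()
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 947L)
  expect_equal(length(unique(a$family_id)), 76L)
  # per-family case counts follow the published distribution
  fc <- family_case_counts(a)
  expect_equal(as.integer(table(fc$n_affected)), c(30L, 26L, 12L, 6L, 2L))
  expect_equal(mean(a$age[!a$affected]), 61.5)
  expect_equal(mean(a$age[a$affected]), 65.0)
})
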