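test_that("the homozygote-deficiency Poisson tail matches the published headline numbers", {
  d <- deficiency_test(3, 72)
  expect_equal(signif(d$p_value, 2), 3.5e-27)
  expect_equal(round(100 * d$deficit), 96)
  # O = E gives no deficit and a comfortable p
  d0 <- deficiency_test(10, 10)
  expect_equal(d0$deficit, 0)
  expect_gt(d0$p_value, 0.5)
})

test_that("the Poisson lower tail equals independent log-space summation and is monotone in E", {
  withr::with_seed(201, {
    for (i in 1:50) {
      O <- sample(0:30, 1)
      E <- runif(1, 0.5, 200)
      d <- deficiency_test(O, E)
      expect_equal(d$p_value, poisson_tail_oracle(O, E),
                   tolerance = 1e-9)
    }
  })
  p_seq <- vapply(seq(10, 100, by = 10),
                  function(E) deficiency_test(3, E)$p_value, numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("the binomial deficiency model gives the exact lower tail", {
  d <- deficiency_test(3, model = "binomial", n_trials = 2952,
                       p_hom = 72 / 2952)
  expect_equal(d$p_value, pbinom(3, 2952, 72 / 2952))
  expect_equal(d$expected, 72)
  expect_error(deficiency_test(3, 0), "expected")
})

test_that("Fisher two-sided p matches exhaustive hypergeometric enumeration", {
  # all tables with small totals
  for (N in 2:10) {
    combos <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    combos <- combos[rowSums(combos) <= N, ]
    for (j in seq_len(nrow(combos))) {
      m <- matrix(c(combos$a[j], combos$b[j], combos$c[j],
                    N - combos$a[j] - combos$b[j] - combos$c[j]), 2,
                  byrow = TRUE)
      p <- fisher_exact_2x2(m)
      expect_equal(p, fisher_enum_oracle(m), tolerance = 1e-7)
      expect_true(p > 0 && p <= 1)
    }
  }
  # random tables up to the N = 40 envelope
  withr::with_seed(202, {
    for (i in 1:150) {
      m <- matrix(rmultinom(1, sample(10:40, 1), runif(4, 0.05, 1)), 2)
      expect_equal(fisher_exact_2x2(m), fisher_enum_oracle(m),
                   tolerance = 1e-7)
    }
  })
})

test_that("the cohort association table is overwhelmingly significant without the homozygote", {
  tab <- matrix(c(2540, 3, 9, 399), 2, byrow = TRUE)
  expect_lt(fisher_exact_2x2(tab), 1e-4)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)), "negative|non-negative")
})

test_that("HWE chi-square reproduces the at-risk-mating and cohort results", {
  h <- hwe_chisq(c(5, 6, 5))
  expect_equal(h$q_hat, 0.5)
  expect_equal(h$expected, c(4, 8, 4))
  expect_equal(h$chi2, 1)
  expect_equal(round(h$p_value, 3), 0.317)

  cohort <- hwe_chisq(c(2543, 408, 1))
  expect_lt(cohort$p_value, 0.001)

  perfect <- hwe_chisq(c(25, 50, 25))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)
})

test_that("HWE handles degenerate inputs and keeps expected counts summing to n", {
  expect_error(hwe_chisq(c(0, 0, 0)), "n = 0")
  expect_warning(mono <- hwe_chisq(c(10, 0, 0)), "monomorphic")
  expect_equal(mono$p_value, 1)
  withr::with_seed(203, {
    for (i in 1:20) {
      counts <- rmultinom(1, sample(10:500, 1), runif(3))[, 1]
      if (sum(counts) == 0 || counts[1] == sum(counts) ||
          counts[3] == sum(counts)) next
      h <- suppressWarnings(hwe_chisq(counts))
      expect_equal(sum(h$expected), h$n)
      expect_gte(h$chi2, 0)
    }
  })
})

test_that("allele and carrier frequencies follow the counting definitions", {
  af <- allele_frequency(c(2543, 408, 1))
  expect_equal(af$q_hat, 410 / 5904)
  expect_equal(af$q_percent, 7)
  expect_equal(allele_frequency(c(50, 0, 0))$q_hat, 0)
  # carrier frequency on the Swiss Lacaune diversity-panel counts
  swiss <- allele_frequency(c(27, 10, 0))
  expect_equal(swiss$carrier_freq, 10 / 37)
})

test_that("rates round half-up to the printed percent", {
  expect_equal(rate(11, 17)$percent, 65)
  expect_equal(rate(0, 10)$percent, 0)
  expect_equal(rate(1, 8)$percent, 13)  # 12.5 rounds up
  expect_error(rate(1, 0), "trials")
  expect_error(rate(5, 3), "between")
})

test_that("segregation of 16 lambs from carrier x carrier matings matches 1:2:1", {
  withr::with_seed(204, {
    genos <- c(rep("hom_ref", 5), rep("het", 6), rep("hom_alt", 5))
    m <- tibble::tibble(
      mating_id = sprintf("M%02d", sample(rep(1:11, length.out = 16))),
      sire_genotype = "het", dam_genotype = "het",
      genotype = sample(genos)
    )
  })
  s <- segregation_test(m)
  expect_equal(unname(s$observed), c(5, 6, 5))
  expect_equal(unname(s$expected), c(4, 8, 4))
  expect_equal(s$chi2, 1)
  expect_equal(s$df, 2L)
  s1 <- segregation_test(m, df = "one")
  expect_equal(round(s1$p_value, 3), 0.317)
})

test_that("mating-type expectations and Mendelian-error exclusion are correct", {
  m <- tibble::tibble(
    mating_id = c("A", "A"), sire_genotype = "het",
    dam_genotype = "hom_ref", genotype = c("het", "hom_ref")
  )
  s <- segregation_test(m)
  expect_equal(unname(s$expected), c(1, 1, 0))

  bad <- dplyr::bind_rows(m, tibble::tibble(
    mating_id = "B", sire_genotype = "het", dam_genotype = "hom_ref",
    genotype = "hom_alt"
  ))
  expect_warning(s2 <- segregation_test(bad), "incompatible")
  expect_equal(nrow(s2$mendelian_errors), 1)
  expect_equal(s2$n_offspring, 2)
})

test_that("segregation ratios converge on simulated matings", {
  cfg <- sim_config(seed = 11, n_matings_at_risk = 4000L,
                    ai_success_rate = 1)
  m <- simulate_matings(cfg)
  s <- segregation_test(m)
  n <- s$n_offspring
  for (cls in c("hom_ref", "het", "hom_alt")) {
    p0 <- c(hom_ref = 0.25, het = 0.5, hom_alt = 0.25)[[cls]]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(s$observed[[cls]] / n - p0), 3 * se)
  }
})

test_that("exact rank-sum p-values match full enumeration, with and without ties", {
  expect_equal(wilcoxon_exact(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(wilcoxon_exact(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  withr::with_seed(205, {
    for (i in 1:30) {
      n_a <- sample(2:5, 1)
      n_b <- sample(2:6, 1)
      a <- sample(1:6, n_a, replace = TRUE)   # small pool forces ties
      b <- sample(1:6, n_b, replace = TRUE)
      expect_equal(wilcoxon_exact(a, b)$p_value,
                   wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
    }
    # untied samples agree with the classical exact test
    for (i in 1:10) {
      vals <- sample(1:1000, 10)
      a <- vals[1:4]
      b <- vals[5:10]
      expect_equal(wilcoxon_exact(a, b)$p_value,
                   wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
  expect_error(wilcoxon_exact(numeric(0), 1:3), "non-empty")
  expect_error(wilcoxon_exact(1:20, 1:20), "25")
})

test_that("attributable mortality follows q^2/m with round-figure rendering", {
  am <- attributable_mortality(0.06, 0.15)
  expect_equal(am$fraction_of_deaths, 0.024)
  expect_equal(am$as_percent, 2)
  expect_equal(am$as_one_in_n, 50)
  expect_equal(attributable_mortality(0.1, 0.2)$fraction_of_deaths, 0.05)
  expect_equal(attributable_mortality(0.001, 0.15)$as_percent, 0)
  expect_error(attributable_mortality(0.5, 0.1), "q\\^2 > m")
})

test_that("the concordance audit finds the twelve discordant cohort members", {
  cohort <- ldhh6_cohort_counts(as_cohort = TRUE)
  a <- concordance_audit(cohort)
  expect_equal(a$n_discordant, 12)
  bd <- tidy(a)
  expect_equal(bd$n_samples[bd$haplotype_status == "non_carrier" &
                              bd$genotype == "het"], 9)
  expect_equal(bd$n_samples[bd$haplotype_status == "carrier_het" &
                              bd$genotype == "hom_ref"], 3)

  perfect <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    haplotype_status = c("non_carrier", "carrier_het", "carrier_hom"),
    genotype = c("hom_ref", "het", "hom_alt")
  )
  expect_equal(concordance_audit(perfect)$n_discordant, 0)
})

test_that("unknown statuses and missing genotypes are counted separately, not as discordance", {
  cohort <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    haplotype_status = c("unknown", "non_carrier", "carrier_het", "non_carrier"),
    genotype = c("het", "missing", "het", "het")
  )
  a <- concordance_audit(cohort)
  expect_equal(a$n_missing, 2)
  expect_equal(a$n_discordant, 1)
  expect_error(concordance_audit(dplyr::mutate(cohort, genotype = "G/G")),
               "invalid")
})
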