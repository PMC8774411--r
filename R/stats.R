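#' Homozygote-deficiency test
#'
#' Tests whether the number of homozygous carriers observed in a genotyped
#' cohort falls short of the number expected from the haplotype frequency.
#' Under the Poisson model the p-value is the lower tail
#' `P(X <= O)` for `X ~ Poisson(E)`; the binomial variant uses the exact
#' lower tail of `Binomial(n_trials, p_hom)`. The deficit is
#' `D = (E - O) / E`.
#'
#' @param observed Observed count of homozygotes (`O >= 0`).
#' @param expected Expected count `E > 0` (ignored by the binomial model,
#'   where `E = n_trials * p_hom`).
#' @param model `"poisson"` (default) or `"binomial"`.
#' @param n_trials,p_hom Binomial-model parameters.
#' @return An object of class `deficiency_result` with fields `observed`,
#'   `expected`, `deficit`, `p_value`, `model`. `tidy()` returns them as a
#'   one-row tibble.
#' @examples
#' deficiency_test(3, 72)   # 96% deficit, p ~ 3.5e-27
#' @export
deficiency_test <- function(observed, expected = NULL,
                            model = c("poisson", "binomial"),
                            n_trials = NULL, p_hom = NULL) {
  model <- match.arg(model)
  if (observed < 0) abort("observed must be >= 0")
  if (model == "poisson") {
    if (is.null(expected) || expected <= 0) abort("expected must be > 0")
    p <- ppois(observed, lambda = expected)
  } else {
    if (is.null(n_trials) || is.null(p_hom)) {
      abort("binomial model needs n_trials and p_hom")
    }
    expected <- n_trials * p_hom
    if (expected <= 0) abort("expected must be > 0")
    p <- pbinom(observed, size = n_trials, prob = p_hom)
  }
  structure(
    list(observed = observed, expected = expected,
         deficit = (expected - observed) / expected, p_value = p,
         model = model),
    class = "deficiency_result"
  )
}

#' @export
print.deficiency_result <- function(x, ...) {
  cat(sprintf(
    "Homozygote-deficiency test (%s): O = %d, E = %.3g, deficit = %.1f%%, p = %.3g\n",
    x$model, x$observed, x$expected, 100 * x$deficit, x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact test of association for a 2x2 contingency table under the
#' probability-mass rule: the two-sided p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.
#'
#' @param table A 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts.
#' @return The two-sided p-value (in `(0, 1]`).
#' @examples
#' fisher_exact_2x2(matrix(c(2540, 9, 3, 399), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) abort("table must be 2x2")
  if (any(m < 0)) abort("cell counts must be non-negative")
  # the tie tolerance in the summation can push p a hair above 1
  min(1, fisher.test(m)$p.value)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square comparison of observed genotype counts against the
#' Hardy-Weinberg expectations `n(1-q)^2, 2nq(1-q), nq^2` computed from the
#' allele frequency estimated on the same counts; 1 degree of freedom, no
#' continuity correction.
#'
#' @param counts Numeric vector `(n_AA, n_Aa, n_aa)` of genotype counts
#'   (major homozygote, heterozygote, minor homozygote).
#' @return An object of class `hwe_result` with `n`, `observed`,
#'   `expected`, `q_hat`, `chi2`, `df`, `p_value`.
#' @examples
#' hwe_chisq(c(5, 6, 5))        # p = 0.317
#' hwe_chisq(c(2543, 408, 1))   # strong departure, p < 0.001
#' @export
hwe_chisq <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3)
  if (any(counts < 0)) abort("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) abort("no individuals (n = 0)")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (q %in% c(0, 1)) {
    warn("monomorphic sample: HWE chi-square degenerate")
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(n = n, observed = counts, expected = expected, q_hat = q,
         chi2 = chi2, df = 1L, p_value = p),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf(
    "HWE chi-square: n = %d, q = %.4f, observed (%s) vs expected (%s), chi2 = %.3g, p = %.3g\n",
    x$n, x$q_hat, paste(x$observed, collapse = ", "),
    paste(signif(x$expected, 4), collapse = ", "), x$chi2, x$p_value))
  invisible(x)
}

#' Allele and carrier frequency from genotype counts
#'
#' @param counts Numeric vector `(n_AA, n_Aa, n_aa)`.
#' @return A one-row tibble: `n`, `q_hat` (minor/alternate allele
#'   frequency `(n_Aa + 2 n_aa) / 2n`), `carrier_freq`
#'   (`(n_Aa + n_aa) / n`), and their nearest-percent renderings.
#' @examples
#' allele_frequency(c(2543, 408, 1))  # q ~ 7%
#' @export
allele_frequency <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3)
  n <- sum(counts)
  if (n == 0) abort("no individuals (n = 0)")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  carrier <- (counts[2] + counts[3]) / n
  tibble(n = n, q_hat = q, carrier_freq = carrier,
         q_percent = round_half_up(100 * q),
         carrier_percent = round_half_up(100 * carrier))
}

round_half_up <- function(x) floor(x + 0.5)

#' Proportion with half-up percent rounding
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials > 0`.
#' @return A one-row tibble: `successes`, `trials`, `proportion`,
#'   `percent` (nearest integer, half rounded up).
#' @examples
#' rate(11, 17)  # 65%
#' @export
rate <- function(successes, trials) {
  if (trials <= 0) abort("trials must be > 0")
  if (successes < 0 || successes > trials) {
    abort("successes must be between 0 and trials")
  }
  p <- successes / trials
  tibble(successes = successes, trials = trials, proportion = p,
         percent = round_half_up(100 * p))
}

#' Mendelian segregation test on mating records
#'
#' Pools offspring genotype counts over matings, computes the Mendelian
#' expected counts per mating type (het x het gives 1:2:1, het x hom_ref
#' gives 1:1:0, ...), and compares observed to expected with a Pearson
#' chi-square. Offspring genotypes impossible given the parents (e.g.
#' `hom_alt` from `hom_ref x het`) are flagged as Mendelian errors and
#' excluded, with their rows recorded in the result.
#'
#' @param matings A mating tibble (see [read_matings()]): one row per lamb
#'   with `mating_id`, `sire_genotype`, `dam_genotype`, `genotype`.
#' @param df `"classes"` (default; degrees of freedom = number of
#'   non-empty expected classes minus 1) or `"one"` (df = 1, the
#'   HWE-style convention).
#' @return An object of class `segregation_result` with `observed`,
#'   `expected` (named counts over hom_ref/het/hom_alt), `chi2`, `df`,
#'   `p_value`, and `mendelian_errors` (excluded rows).
#' @export
segregation_test <- function(matings, df = c("classes", "one")) {
  df <- match.arg(df)
  x <- as_tibble(matings) |>
    filter(!is.na(.data$genotype))
  if (nrow(x) == 0) abort("no genotyped offspring")
  probs <- purrr::map2(x$sire_genotype, x$dam_genotype, mendelian_probs)
  possible <- purrr::map2_lgl(probs, x$genotype, function(p, g) p[[g]] > 0)
  errors <- x[!possible, , drop = FALSE]
  if (nrow(errors) > 0) {
    warn(paste0(nrow(errors),
                " offspring with genotypes incompatible with parents excluded"))
  }
  x <- x[possible, , drop = FALSE]
  probs <- probs[possible]
  classes <- c("hom_ref", "het", "hom_alt")
  expected <- purrr::reduce(probs, `+`)
  observed <- setNames(vapply(classes, function(g) sum(x$genotype == g),
                              numeric(1)), classes)
  nz <- expected > 0
  chi2 <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  dfree <- if (df == "one") 1L else sum(nz) - 1L
  p <- pchisq(chi2, df = dfree, lower.tail = FALSE)
  structure(
    list(observed = observed, expected = expected, chi2 = chi2, df = dfree,
         p_value = p, n_offspring = nrow(x), mendelian_errors = errors),
    class = "segregation_result"
  )
}

mendelian_probs <- function(sire, dam) {
  allele_p <- function(g) switch(g, hom_ref = 0, het = 0.5, hom_alt = 1,
                                 abort(paste0("unknown parental genotype ", g)))
  ps <- allele_p(sire)
  pd <- allele_p(dam)
  c(hom_ref = (1 - ps) * (1 - pd), het = ps * (1 - pd) + pd * (1 - ps),
    hom_alt = ps * pd)
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "Segregation test: observed (%s) vs expected (%s), chi2 = %.3g, df = %d, p = %.3g\n",
    paste(x$observed, collapse = ", "),
    paste(signif(x$expected, 4), collapse = ", "), x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Exact two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided rank-sum test for small samples, suitable for the
#' growth comparisons of at-risk-mating offspring where group sizes are a
#' handful of lambs. Ties receive midranks, and the exact permutation
#' distribution of the rank sum of the first group is computed by dynamic
#' programming over all `choose(n_a + n_b, n_a)` group assignments, so the
#' p-value is exact even with ties (unlike the normal approximation).
#' The two-sided p-value is `2 * min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param group_a,group_b Numeric vectors (combined length at most 25 for
#'   exact mode).
#' @return A one-row tibble: `n_a`, `n_b`, `rank_sum_a`, `p_value`.
#' @examples
#' wilcoxon_exact(c(1, 2), c(3, 4))  # p = 1/3
#' @export
wilcoxon_exact <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a + n_b > 25) {
    abort("exact mode supports at most 25 observations in total")
  }
  r <- rank(c(group_a, group_b))      # midranks for ties
  w_obs <- sum(r[seq_len(n_a)])
  dist <- rank_sum_distribution(r, n_a)
  p_le <- sum(dist$prob[dist$sum <= w_obs + 1e-9])
  p_ge <- sum(dist$prob[dist$sum >= w_obs - 1e-9])
  p <- min(1, 2 * min(p_le, p_ge))
  tibble(n_a = n_a, n_b = n_b, rank_sum_a = w_obs, p_value = p)
}

## exact distribution of the size-k subset rank sum; ranks doubled so
## midranks become integers, DP over (subset size, doubled sum)
rank_sum_distribution <- function(ranks, k) {
  r2 <- as.integer(round(2 * ranks))
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(k)])
  ## counts[size + 1, sum + 1]
  counts <- matrix(0, nrow = k + 1, ncol = max_sum + 1)
  counts[1, 1] <- 1
  for (ri in r2) {
    for (sz in rev(seq_len(k))) {
      reach <- which(counts[sz, ] > 0)
      reach <- reach[reach + ri <= max_sum + 1]
      if (length(reach) > 0) {
        counts[sz + 1, reach + ri] <- counts[sz + 1, reach + ri] +
          counts[sz, reach]
      }
    }
  }
  sums2 <- which(counts[k + 1, ] > 0) - 1
  n_subsets <- choose(length(ranks), k)
  tibble(sum = sums2 / 2, prob = counts[k + 1, sums2 + 1] / n_subsets)
}

#' Mortality fraction attributable to a recessive lethal allele
#'
#' Under Hardy-Weinberg conception frequencies and full juvenile lethality
#' of homozygotes, a recessive lethal allele at frequency `q` accounts for
#' a fraction `q^2 / m` of all juvenile deaths when the overall juvenile
#' mortality rate is `m`.
#'
#' @param q Allele frequency, in `(0, 1)`.
#' @param m Overall juvenile mortality rate, in `(0, 1]`; must satisfy
#'   `q^2 <= m`.
#' @param denominators Candidate round denominators for the "one in N"
#'   rendering.
#' @return A one-row tibble: `q`, `m`, `fraction_of_deaths`, `as_percent`
#'   (nearest integer), `as_one_in_n` (nearest round denominator).
#' @examples
#' attributable_mortality(0.06, 0.15)  # 2% of deaths, about 1 in 50
#' @export
attributable_mortality <- function(q, m,
                                   denominators = c(10, 20, 25, 50, 100)) {
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)")
  if (m <= 0 || m > 1) abort("m must be in (0, 1]")
  if (q^2 > m) abort("q^2 > m: homozygote conceptions exceed total mortality")
  fraction <- q^2 / m
  one_in <- denominators[which.min(abs(denominators - 1 / fraction))]
  tibble(q = q, m = m, fraction_of_deaths = fraction,
         as_percent = round_half_up(100 * fraction), as_one_in_n = one_in)
}

#' Audit concordance between haplotype status and variant genotype
#'
#' A causal variant in complete linkage disequilibrium with a haplotype
#' implies the mapping non-carrier/hom_ref, heterozygous carrier/het,
#' homozygous carrier/hom_alt. This audit counts cohort members violating
#' that mapping and breaks them down into the two informative discordance
#' classes: status non-carrier but genotype carries the variant
#' (recombination-shortened haplotypes), and status carrier but genotype
#' homozygous reference (haplotype genotyping/phasing error).
#'
#' @param cohort Tibble with columns `sample_id`, `haplotype_status`
#'   (levels of [read_status_table()]) and `genotype` (`hom_ref`, `het`,
#'   `hom_alt`, `missing`).
#' @return An object of class `concordance_audit` with `n`,
#'   `n_discordant`, `breakdown` (tibble of discordant status x genotype
#'   combinations), `n_missing` (samples with unknown status or missing
#'   genotype, counted separately).
#' @export
concordance_audit <- function(cohort) {
  x <- as_tibble(cohort)
  stopifnot(all(c("haplotype_status", "genotype") %in% names(x)))
  bad_s <- setdiff(unique(x$haplotype_status), status_levels())
  bad_g <- setdiff(unique(x$genotype), gt_states())
  if (length(bad_s) > 0 || length(bad_g) > 0) {
    abort(paste0("invalid status/genotype labels: ",
                 paste(c(bad_s, bad_g), collapse = ", ")))
  }
  expected_geno <- c(non_carrier = "hom_ref", carrier_het = "het",
                     carrier_hom = "hom_alt")
  assessable <- x$haplotype_status != "unknown" & x$genotype != "missing"
  xx <- x[assessable, , drop = FALSE]
  disc <- xx[expected_geno[xx$haplotype_status] != xx$genotype, , drop = FALSE]
  breakdown <- disc |>
    count(.data$haplotype_status, .data$genotype, name = "n_samples")
  structure(
    list(n = nrow(x), n_discordant = nrow(disc), breakdown = breakdown,
         n_missing = sum(!assessable), discordant = disc),
    class = "concordance_audit"
  )
}

#' @export
print.concordance_audit <- function(x, ...) {
  cat(sprintf("Concordance audit: %d of %d discordant (%d not assessable)\n",
              x$n_discordant, x$n, x$n_missing))
  if (nrow(x$breakdown) > 0) print(x$breakdown)
  invisible(x)
}

#' Cross-tabulate haplotype status against variant genotype
#'
#' @param cohort As in [concordance_audit()].
#' @return A genotype x status contingency table (matrix) with genotype
#'   rows `hom_ref`, `het`, `hom_alt` and status columns `non_carrier`,
#'   `carrier_het`, `carrier_hom`.
#' @export
status_genotype_table <- function(cohort) {
  x <- as_tibble(cohort) |>
    filter(.data$haplotype_status != "unknown", .data$genotype != "missing")
  table(factor(x$genotype, levels = c("hom_ref", "het", "hom_alt")),
        factor(x$haplotype_status,
               levels = c("non_carrier", "carrier_het", "carrier_hom")))
}
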