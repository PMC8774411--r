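#' Simulation configuration
#'
#' Parameters of the synthetic carrier-screening study. Defaults emulate
#' the Lacaune LDHH6/CCDC65 study conditions: a genotyped cohort of 2952
#' lambs, causal allele frequency 0.06 (about 12% heterozygous carriers), a
#' 27-marker haplotype whose rare recombination-shortened versions make
#' some variant carriers look like haplotype non-carriers, occasional
#' haplotype-call errors in the other direction, survival of homozygotes
#' to genotyping age calibrated at 3/72, 17 at-risk matings with an AI
#' success rate of 0.65, and birthweights of 4.9 +/- 1.0 kg (males) /
#' 3.9 +/- 0.6 kg (females).
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param n_cohort Number of conceived cohort members (the emitted cohort
#'   is slightly smaller after juvenile deaths of homozygotes).
#' @param q_causal Causal allele frequency at conception.
#' @param n_markers_haplotype Number of array markers in the haplotype
#'   (documentation only: the simulator tracks haplotype state, not the
#'   individual marker alleles).
#' @param p_recomb_short_haplotype Probability that a variant-carrying
#'   chromosome carries a recombination-shortened haplotype and is missed
#'   by haplotype calling (drives `non_carrier`-status x `het`-genotype
#'   discordance).
#' @param genotyping_error_rate Probability that a true non-carrier is
#'   wrongly called a haplotype carrier (drives `carrier_het`-status x
#'   `hom_ref`-genotype discordance).
#' @param n_sequenced_carriers,n_sequenced_noncarriers Composition of the
#'   sequenced panel emulated by [sequenced_panel_fixture()].
#' @param lethality_survival Probability a homozygote survives to
#'   genotyping age (default 3/72, the observed-over-expected calibration).
#' @param n_matings_at_risk Number of carrier x carrier matings.
#' @param ai_success_rate Probability an inseminated ewe is pregnant.
#' @param twin_prob Probability a pregnancy carries twins.
#' @param adg_mean,adg_sd Average daily gain distribution, g/day, days
#'   0-15.
#' @param adg_effect Mean ADG reduction (g/day) in homozygous carriers.
#' @param hom_survival_juvenile Probability a homozygous lamb from an
#'   at-risk mating survives the juvenile period.
#' @param birthweight Named list of `c(mean, sd)` in kg for sexes `M`, `F`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cohort = 2952L,
                       q_causal = 0.06,
                       n_markers_haplotype = 27L,
                       p_recomb_short_haplotype = 0.022,
                       genotyping_error_rate = 0.0012,
                       n_sequenced_carriers = 2L,
                       n_sequenced_noncarriers = 86L,
                       lethality_survival = 3 / 72,
                       n_matings_at_risk = 17L,
                       ai_success_rate = 0.65,
                       twin_prob = 0.45,
                       adg_mean = 260,
                       adg_sd = 60,
                       adg_effect = 120,
                       hom_survival_juvenile = 0.2,
                       birthweight = list(M = c(4.9, 1.0), F = c(3.9, 0.6))) {
  cfg <- list(seed = as.integer(seed), n_cohort = as.integer(n_cohort),
              q_causal = q_causal,
              n_markers_haplotype = as.integer(n_markers_haplotype),
              p_recomb_short_haplotype = p_recomb_short_haplotype,
              genotyping_error_rate = genotyping_error_rate,
              n_sequenced_carriers = as.integer(n_sequenced_carriers),
              n_sequenced_noncarriers = as.integer(n_sequenced_noncarriers),
              lethality_survival = lethality_survival,
              n_matings_at_risk = as.integer(n_matings_at_risk),
              ai_success_rate = ai_success_rate, twin_prob = twin_prob,
              adg_mean = adg_mean, adg_sd = adg_sd, adg_effect = adg_effect,
              hom_survival_juvenile = hom_survival_juvenile,
              birthweight = birthweight)
  probs <- c(cfg$q_causal, cfg$p_recomb_short_haplotype,
             cfg$genotyping_error_rate, cfg$lethality_survival,
             cfg$ai_success_rate, cfg$twin_prob, cfg$hom_survival_juvenile)
  if (any(probs < 0 | probs > 1)) {
    abort("all probability parameters must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

causal_variant_site <- function() {
  list(chrom = "NC_040254.1", pos = 147207999, ref = "C", alt = "A",
       qual = 506.7)
}

#' Simulate a genotyped screening cohort
#'
#' Draws `n_cohort` conceptions with causal genotypes at Hardy-Weinberg
#' proportions for allele frequency `q_causal`, removes homozygotes that
#' die before genotyping age (each survives with probability
#' `lethality_survival`), derives the haplotype status from the true
#' genotype, and then injects the two discordance mechanisms: carriers of
#' recombination-shortened haplotypes called `non_carrier`
#' (`p_recomb_short_haplotype` per heterozygote) and haplotype-call errors
#' labelling true non-carriers as `carrier_het` (`genotyping_error_rate`).
#' The variant assay itself is taken as accurate, so discordance arises
#' only on the haplotype side, as validated assays behave.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; if given, the cohort VCF
#'   (`cohort.vcf`), status TSV (`cohort_status.tsv`) and ground-truth TSV
#'   (`cohort_truth.tsv`) are written there.
#' @return A list with `calls` (single-variant [geno_tbl][as_geno_tbl] of
#'   the emitted cohort), `status` (status tibble) and `truth` (one row
#'   per *conceived* individual: `sample_id`, `true_genotype`, `survived`,
#'   `haplotype_status`, `discord_class`). Emitted samples map 1:1 onto
#'   `truth` rows with `survived == TRUE`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_cohort
    q <- cfg$q_causal
    geno <- sample(c("hom_ref", "het", "hom_alt"), n, replace = TRUE,
                   prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    survived <- ifelse(geno == "hom_alt",
                       runif(n) < cfg$lethality_survival, TRUE)
    status <- c(hom_ref = "non_carrier", het = "carrier_het",
                hom_alt = "carrier_hom")[geno]
    discord <- rep("none", n)
    recomb <- geno == "het" & runif(n) < cfg$p_recomb_short_haplotype
    status[recomb] <- "non_carrier"
    discord[recomb] <- "recombinant_haplotype"
    err <- geno == "hom_ref" & runif(n) < cfg$genotyping_error_rate
    status[err] <- "carrier_het"
    discord[err] <- "status_error"

    truth <- tibble(
      sample_id = sprintf("SIM_%05d", seq_len(n)),
      true_genotype = geno, survived = survived,
      haplotype_status = status, discord_class = discord
    )
    emitted <- filter(truth, .data$survived)
    site <- causal_variant_site()
    calls <- as_geno_tbl(tibble(
      chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      qual = site$qual, sample_id = emitted$sample_id,
      gt = emitted$true_genotype
    ))
    status_tbl <- tibble(
      sample_id = emitted$sample_id, breed = "Lacaune",
      haplotype_status = emitted$haplotype_status, sequenced = FALSE,
      cohort_year = 2021L
    )
    out <- list(calls = calls, status = status_tbl, truth = truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(out$calls, file.path(dir, "cohort.vcf"))
    write_status_table(out$status, file.path(dir, "cohort_status.tsv"))
    readr::write_tsv(out$truth, file.path(dir, "cohort_truth.tsv"),
                     progress = FALSE)
  }
  out
}

#' Simulate at-risk carrier-by-carrier matings
#'
#' Heterozygous ewes are inseminated with semen from heterozygous rams;
#' each mating is pregnant with probability `ai_success_rate`, litters are
#' singletons or twins (`twin_prob`), offspring genotypes segregate
#' 1:2:1, birthweights are drawn per sex, ADG (days 0-15) is normal with a
#' mean reduction of `adg_effect` g/day in homozygotes, and homozygous
#' lambs die in the juvenile period (days 15-25) unless they survive with
#' probability `hom_survival_juvenile`; other lambs are censored alive at
#' day 180.
#'
#' @param cfg A [sim_config()].
#' @param n_matings Number of matings (defaults to `cfg$n_matings_at_risk`).
#' @param dir Optional directory; if given, a `matings.tsv` is written.
#' @return A mating tibble, one row per lamb (non-pregnant matings keep one
#'   row with empty lamb fields); see [read_matings()] for columns.
#' @export
simulate_matings <- function(cfg = sim_config(),
                             n_matings = cfg$n_matings_at_risk, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- withr::with_seed(cfg$seed + 1L, {
    pregnant <- runif(n_matings) < cfg$ai_success_rate
    n_lambs <- ifelse(pregnant, 1L + rbinom(n_matings, 1, cfg$twin_prob), 0L)
    matings <- tibble(
      mating_id = sprintf("MATE_%02d", seq_len(n_matings)),
      sire_genotype = "het", dam_genotype = "het",
      inseminated = TRUE, pregnant = pregnant, n_lambs = n_lambs
    )
    lambs <- matings[rep(seq_len(n_matings), n_lambs), ] |>
      group_by(.data$mating_id) |>
      mutate(lamb_no = row_number()) |>
      ungroup()
    nl <- nrow(lambs)
    geno <- sample(c("hom_ref", "het", "hom_alt"), nl, replace = TRUE,
                   prob = c(0.25, 0.5, 0.25))
    sex <- sample(c("M", "F"), nl, replace = TRUE)
    bw_mean <- ifelse(sex == "M", cfg$birthweight$M[1], cfg$birthweight$F[1])
    bw_sd <- ifelse(sex == "M", cfg$birthweight$M[2], cfg$birthweight$F[2])
    bw <- pmax(0.5, rnorm(nl, bw_mean, bw_sd))
    adg <- rnorm(nl, cfg$adg_mean - (geno == "hom_alt") * cfg$adg_effect,
                 cfg$adg_sd)
    dies <- geno == "hom_alt" & runif(nl) > cfg$hom_survival_juvenile
    lambs <- lambs |>
      mutate(lamb_id = sprintf("LAMB_%s_%d",
                               sub("MATE_", "", .data$mating_id),
                               .data$lamb_no),
             sex = sex, genotype = geno, birthweight = round(bw, 2),
             weight_d15 = round(bw + adg * 15 / 1000, 2),
             survival_days = ifelse(dies, sample(15:25, nl, replace = TRUE),
                                    180),
             censored = !dies) |>
      select(-"lamb_no")
    empties <- matings |>
      filter(!.data$pregnant) |>
      mutate(lamb_id = NA_character_, sex = NA_character_,
             genotype = NA_character_, birthweight = NA_real_,
             weight_d15 = NA_real_, survival_days = NA_real_,
             censored = NA)
    bind_rows(lambs, empties) |>
      arrange(.data$mating_id, .data$lamb_id) |>
      select(-"n_lambs")
  })
  out <- mutate(out,
                adg_0_15 = (.data$weight_d15 - .data$birthweight) / 15 * 1000)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_matings(out, file.path(dir, "matings.tsv"))
  }
  out
}

#' Packaged sequenced-panel fixture for the prioritization screen
#'
#' Builds the deterministic whole-genome-sequencing panel the
#' prioritization screen runs on: 88 samples (2 Lacaune haplotype
#' carriers, 22 Lacaune non-carriers, 64 animals of other breeds) with the
#' eleven published candidate variants ([ldhh6_candidate_variants()])
#' heterozygous in both carriers and homozygous reference everywhere else,
#' plus `decoys` generated decoy variants that each violate exactly one
#' filter condition: outside the screening region, quality at most 30, not
#' heterozygous in one carrier, or heterozygous in some non-carrier.
#'
#' @param decoys Number of decoy variants (default 30).
#' @param seed Seed for the decoy draw.
#' @param dir Optional directory; if given, `panel.vcf`,
#'   `panel_status.tsv` and `panel_annotations.tsv` are written there.
#' @return A list with `calls` (a [geno_tbl][as_geno_tbl]), `status`,
#'   `annotations` (with `impact`), and `decoy_truth` (tibble `pos`, `alt`,
#'   `violates` naming each decoy's designated failing condition).
#' @export
sequenced_panel_fixture <- function(decoys = 30L, seed = 1L, dir = NULL) {
  stopifnot(decoys >= 0)
  carriers <- c("LAC_C01", "LAC_C02")
  lacaune <- sprintf("LAC_%02d", 3:24)
  other_breeds <- c("Romane", "Texel", "Charollais", "Suffolk",
                    "Ile de France", "Corse", "Romanov", "Manech tete rousse")
  others <- sprintf("OTH_%02d", 1:64)
  samples <- c(carriers, lacaune, others)
  breeds <- c(rep("Lacaune", 24), rep(other_breeds, length.out = 64))

  real <- ldhh6_candidate_variants()
  rg <- parse_region(ldhh6_region())

  panel_calls <- function(site_gt) {
    # site_gt: named list pos/ref/alt/qual + per-sample gt vector
    tibble(chrom = "NC_040254.1", pos = site_gt$pos, ref = site_gt$ref,
           alt = site_gt$alt, qual = site_gt$qual, sample_id = samples,
           gt = site_gt$gt)
  }

  base_gt <- function() {
    gt <- rep("hom_ref", length(samples))
    names(gt) <- samples
    gt
  }

  out <- withr::with_seed(seed, {
    sites <- purrr::pmap(real, function(chrom, pos, ref, alt, qual, ...) {
      gt <- base_gt()
      gt[carriers] <- "het"
      list(pos = pos, ref = ref, alt = alt, qual = qual, gt = gt)
    })
    decoy_truth <- tibble(pos = numeric(), alt = character(),
                          violates = character())
    if (decoys > 0) {
      classes <- rep(c("region", "qual", "carrier", "noncarrier"),
                     length.out = decoys)
      used_pos <- real$pos
      for (cl in classes) {
        repeat {
          pos <- if (cl == "region") {
            round(runif(1, 1e8, 1.2e8))  # > 2 Mb clear of region + flank
          } else {
            round(runif(1, rg$start, rg$end))
          }
          if (!pos %in% used_pos) break
        }
        used_pos <- c(used_pos, pos)
        ref <- sample(c("A", "C", "G", "T"), 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        qual <- if (cl == "qual") round(runif(1, 5, 30), 1) else
          round(runif(1, 50, 900), 1)
        gt <- base_gt()
        gt[carriers] <- "het"
        if (cl == "carrier") gt[sample(carriers, 1)] <- "hom_ref"
        if (cl == "noncarrier") {
          gt[sample(setdiff(samples, carriers), sample(1:3, 1))] <- "het"
        }
        sites[[length(sites) + 1]] <- list(pos = pos, ref = ref, alt = alt,
                                           qual = qual, gt = gt)
        decoy_truth <- bind_rows(decoy_truth,
                                 tibble(pos = pos, alt = alt, violates = cl))
      }
    }
    calls <- bind_rows(purrr::map(sites, panel_calls)) |>
      arrange(.data$pos, .data$alt, match(.data$sample_id, samples))
    annotations <- bind_rows(
      select(real, "chrom", "pos", "alt", "impact"),
      tibble(chrom = "NC_040254.1", pos = decoy_truth$pos,
             alt = decoy_truth$alt, impact = "Modifier")
    )
    status <- tibble(
      sample_id = samples, breed = breeds,
      haplotype_status = ifelse(samples %in% carriers, "carrier_het",
                                "non_carrier"),
      sequenced = TRUE
    )
    list(calls = as_geno_tbl(calls), status = status,
         annotations = annotations, decoy_truth = decoy_truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(out$calls, file.path(dir, "panel.vcf"), samples = samples)
    write_status_table(out$status, file.path(dir, "panel_status.tsv"))
    readr::write_tsv(out$annotations, file.path(dir, "panel_annotations.tsv"),
                     progress = FALSE)
  }
  out
}

#' Packaged CCDC65-like gene-model fixture
#'
#' A deterministic minus-strand transcript model mimicking the geometry of
#' ovine CCDC65: a 190-nt 5'UTR, a 1497-nt CDS encoding 498 residues plus
#' the stop, a GAA (Glu) codon at transcript positions 521-523, and three
#' exons whose genomic coordinates place that codon's first base at
#' NC_040254.1:147,207,999 with forward-strand alleles C (reference) and A
#' (variant). The 5'UTR length of 190 nt is a reconciling assumption that
#' makes transcript-dialect coordinate 521 land on codon 111; it is not an
#' annotated UTR length. Filler sequence is generated from a fixed
#' internal seed, so the fixture is identical across calls.
#'
#' @return A list with `model` (a [transcript_model()]), `variant`
#'   (one-row tibble for the stop-gain SNV), and `domains`
#'   ([ccdc65_domains()]).
#' @export
gene_model_fixture <- function() {
  u <- 190L
  n_res <- 498L
  utr3 <- 150L
  site <- causal_variant_site()

  seq <- withr::with_seed(20211224L, {
    bases <- c("A", "C", "G", "T")
    sense_codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                          collapse = "")
    sense_codons <- setdiff(sense_codons, c("TAA", "TAG", "TGA"))
    utr5 <- paste(sample(bases, u, replace = TRUE), collapse = "")
    codons <- sample(sense_codons, n_res, replace = TRUE)
    codons[1] <- "ATG"
    codons[111] <- "GAA"
    # guard the frame: mutating codon 111 G>T must be the FIRST new stop
    cds <- paste(c(codons, "TAA"), collapse = "")
    utr3seq <- paste(sample(bases, utr3, replace = TRUE), collapse = "")
    paste0(utr5, cds, utr3seq)
  })

  ## exon lengths in transcript order; the variant base (tx 521) sits in
  ## the third exon, offset 70 from its transcript-first (genomic-last) base
  ex_len <- c(250L, 200L, nchar(seq) - 450L)
  end3 <- site$pos + 70
  start3 <- end3 - (ex_len[3] - 1)
  start2 <- end3 + 501
  end2 <- start2 + (ex_len[2] - 1)
  start1 <- end2 + 501
  end1 <- start1 + (ex_len[1] - 1)
  exons <- tibble(start = c(start1, start2, start3),
                  end = c(end1, end2, end3))

  model <- transcript_model(
    transcript_id = "TX_CCDC65_SYN", chrom = site$chrom, strand = "-",
    exons = exons, cds_start_tx = u + 1L, sequence = seq
  )
  stopifnot(model$ref_protein_len == n_res,
            genomic_to_transcript(model, site$pos)$tx_pos == 521L)
  list(
    model = model,
    variant = tibble(chrom = site$chrom, pos = site$pos, ref = site$ref,
                     alt = site$alt, qual = site$qual),
    domains = ccdc65_domains()
  )
}
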