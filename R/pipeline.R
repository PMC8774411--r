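#' Run the screening-and-validation pipeline end to end
#'
#' Orchestrates the stages in fixed order: ingest (or simulate) ->
#' prioritize -> consequence -> validation statistics -> report. Any stage
#' failure aborts with a stage-tagged error. Sections whose inputs are
#' absent (no gene model, no cohort, ...) are skipped with a recorded
#' reason rather than failing.
#'
#' The configuration is a named list (or a YAML file read into one) with
#' components:
#'
#' * `simulate` — optional list passed to [sim_config()]; when present the
#'   sequenced panel, genotyped cohort and at-risk matings are generated
#'   in memory instead of read from files.
#' * `vcf`, `status`, `annotations` — paths for the sequenced-panel VCF,
#'   sample-status TSV and per-variant impact TSV.
#' * `gene_model`, `fasta` — gene-model TSV + transcript FASTA for the
#'   consequence stage (`dialect` selects the `c.` numbering, see
#'   [call_consequence()]).
#' * `cohort` — path to a TSV with `sample_id`, `haplotype_status`,
#'   `genotype` for the genotyped validation cohort.
#' * `matings` — path to a mating TSV (see [read_matings()]).
#' * `region` (default [ldhh6_region()]), `flank_bp`, `min_qual`,
#'   `require_impact` — prioritization parameters.
#' * `deficiency` — optional list `(observed, expected)`; when absent and
#'   a cohort is present, the expectation is derived from the cohort's
#'   heterozygote count under Hardy-Weinberg.
#' * `mortality` — optional list `(q, m)`; `q` defaults to the cohort
#'   allele frequency, `m` to 0.15.
#'
#' @param config Named list, or path to a YAML file.
#' @param out Optional directory; if given, [write_report()] is called.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("recleth")),
      config_hash = rlang::hash(config),
      seed = config$simulate$seed %||% NA,
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    skipped = list()
  )
  skip <- function(section, reason) {
    report$skipped[[section]] <<- reason
    NULL
  }

  ## -- ingest / simulate ------------------------------------------------
  sim <- NULL
  inputs <- stage("ingest", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config, config$simulate)
      sim <- list(
        panel = sequenced_panel_fixture(seed = cfg$seed),
        cohort = simulate_cohort(cfg),
        matings = simulate_matings(cfg)
      )
      cohort_tbl <- left_join(
        select(sim$cohort$status, "sample_id", "haplotype_status"),
        select(sim$cohort$calls, "sample_id", genotype = "gt"),
        by = "sample_id"
      )
      list(calls = sim$panel$calls, status = sim$panel$status,
           annotations = sim$panel$annotations, cohort = cohort_tbl,
           matings = sim$matings)
    } else {
      list(
        calls = if (!is.null(config$vcf)) read_vcf(config$vcf),
        status = if (!is.null(config$status)) read_status_table(config$status),
        annotations = if (!is.null(config$annotations)) {
          readr::read_tsv(config$annotations,
                          col_types = readr::cols(pos = "d", .default = "c"),
                          progress = FALSE)
        },
        cohort = if (!is.null(config$cohort)) {
          readr::read_tsv(config$cohort,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
        },
        matings = if (!is.null(config$matings)) read_matings(config$matings)
      )
    }
  })

  ## -- prioritize -------------------------------------------------------
  high_candidates <- NULL
  if (is.null(inputs$calls) || nrow(inputs$calls) == 0) {
    skip("prioritize", "no variant calls supplied")
  } else {
    report$filter <- stage("prioritize", {
      carriers <- inputs$status$sample_id[
        inputs$status$haplotype_status %in% c("carrier_het", "carrier_hom")]
      fc <- filter_config(
        region = config$region %||% ldhh6_region(),
        carrier_ids = carriers,
        flank_bp = config$flank_bp %||% 0,
        min_qual = config$min_qual %||% 30,
        require_impact = config$require_impact %||% "HIGH"
      )
      rep0 <- concordance_filter(inputs$calls, fc)
      if (!is.null(inputs$annotations)) {
        rep0 <- impact_filter(rep0, inputs$annotations)
      }
      rep0
    })
    high_candidates <- report$filter$surviving
  }

  ## -- consequence ------------------------------------------------------
  model <- NULL
  if (!is.null(config$gene_model)) {
    model <- stage("consequence", read_gene_model(config$gene_model,
                                                  config$fasta))
  } else if (!is.null(sim)) {
    model <- gene_model_fixture()$model
  }
  if (is.null(model)) {
    skip("consequence", "no gene model supplied")
  } else if (is.null(high_candidates) || nrow(high_candidates) == 0) {
    skip("consequence", "no surviving candidate variant")
  } else {
    report$consequence <- stage("consequence", {
      dialect <- config$dialect %||% "transcript"
      purrr::pmap(high_candidates,
                  function(chrom, pos, ref, alt, ...) {
                    call_consequence(model,
                                     list(chrom = chrom, pos = pos,
                                          ref = ref, alt = alt),
                                     dialect = dialect)
                  }) |>
        bind_rows()
    })
  }

  ## -- validation statistics -------------------------------------------
  if (is.null(inputs$cohort)) {
    skip("cohort_stats", "no genotyped cohort supplied")
  } else {
    report <- stage("cohort_stats", {
      tab <- status_genotype_table(inputs$cohort)
      geno_counts <- rowSums(tab)
      report$allele_frequency <- allele_frequency(geno_counts)
      report$hwe <- hwe_chisq(geno_counts)
      report$association <- list(
        table = tab[c("hom_ref", "het"), c("non_carrier", "carrier_het")],
        p_value = fisher_exact_2x2(
          tab[c("hom_ref", "het"), c("non_carrier", "carrier_het")])
      )
      report$audit <- concordance_audit(inputs$cohort)
      defi <- config$deficiency
      if (is.null(defi)) {
        n <- sum(geno_counts)
        q_het <- geno_counts[["het"]] / (2 * n)
        defi <- list(observed = geno_counts[["hom_alt"]],
                     expected = n * q_het^2)
      }
      report$deficiency <- deficiency_test(defi$observed, defi$expected)
      mort <- config$mortality %||% list()
      report$mortality <- attributable_mortality(
        q = mort$q %||% report$allele_frequency$q_hat,
        m = mort$m %||% 0.15
      )
      report
    })
  }

  if (is.null(inputs$matings)) {
    report$skipped[["mating_stats"]] <- "no mating records supplied"
  } else {
    report <- stage("mating_stats", {
      m <- inputs$matings
      per_mating <- distinct(m, .data$mating_id, .data$pregnant)
      report$ai_success <- rate(sum(per_mating$pregnant),
                                nrow(per_mating))
      lambs <- filter(m, !is.na(.data$genotype))
      if (nrow(lambs) > 0) {
        report$segregation <- segregation_test(m)
        hom <- filter(lambs, .data$genotype == "hom_alt")
        oth <- filter(lambs, .data$genotype != "hom_alt")
        if (nrow(hom) > 0 && nrow(oth) > 0 &&
            nrow(hom) + nrow(oth) <= 25) {
          report$adg_test <- wilcoxon_exact(hom$adg_0_15, oth$adg_0_15)
        }
      }
      report
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$filter)) {
    cat(sprintf("  candidates: %d concordant, %s at required impact\n",
                x$filter$counts[["n_concordant"]],
                x$filter$counts[["n_impact"]]))
  }
  if (!is.null(x$consequence)) {
    cat(sprintf("  consequence: %s (%s, %s)\n", x$consequence$hgvs_p[1],
                x$consequence$consequence_term[1], x$consequence$hgvs_c[1]))
  }
  if (!is.null(x$allele_frequency)) {
    cat(sprintf("  allele frequency: %.4f (%d%%)\n",
                x$allele_frequency$q_hat, x$allele_frequency$q_percent))
  }
  if (!is.null(x$deficiency)) cat("  ", format_line(x$deficiency), "\n")
  if (!is.null(x$audit)) {
    cat(sprintf("  discordant cohort members: %d of %d\n",
                x$audit$n_discordant, x$audit$n))
  }
  if (length(x$skipped) > 0) {
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

format_line <- function(x) {
  sprintf("deficiency: O = %d, E = %.3g, deficit %.0f%%, p = %.2g",
          x$observed, x$expected, 100 * x$deficit, x$p_value)
}

report_to_list <- function(x) {
  out <- list(
    schema_version = "1.0",
    provenance = x$provenance,
    skipped = x$skipped
  )
  if (!is.null(x$filter)) {
    out$filter <- list(counts = as.list(x$filter$counts),
                       surviving = x$filter$surviving,
                       fail_reasons = x$filter$fail_reasons)
  }
  if (!is.null(x$consequence)) out$consequence <- x$consequence
  for (nm in c("allele_frequency", "mortality", "ai_success", "adg_test")) {
    if (!is.null(x[[nm]])) out[[nm]] <- x[[nm]]
  }
  for (nm in c("deficiency", "hwe", "segregation", "audit")) {
    if (!is.null(x[[nm]])) {
      out[[nm]] <- c(as.list(glance(x[[nm]])),
                     list(detail = tidy(x[[nm]])))
    }
  }
  if (!is.null(x$association)) {
    out$association <- list(table = as.data.frame.matrix(x$association$table),
                            p_value = x$association$p_value)
  }
  out
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (full nested report, schema-versioned) and
#' `report.tsv` (flat key/value pairs of the scalar results) into `dir`.
#' The JSON is written atomically (temp file + rename).
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lst <- report_to_list(report)
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  jsonlite::write_json(lst, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  file.rename(tmp, file.path(dir, "report.json"))

  flat <- unlist(lst[setdiff(names(lst), c("filter", "consequence"))])
  flat_tbl <- tibble(key = names(flat), value = as.character(flat))
  readr::write_tsv(flat_tbl, file.path(dir, "report.tsv"), progress = FALSE)
  invisible(dir)
}
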