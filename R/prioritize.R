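#' Configuration for candidate-variant prioritization
#'
#' Bundles the parameters of the carrier-concordance screen: the haplotype
#' region (extended by a flank on each side), the variant quality cutoff,
#' and the carrier / non-carrier sample sets.
#'
#' @param region Region string `chrom:start-end` (1-based inclusive)
#'   delimiting the haplotype under investigation.
#' @param carrier_ids Character vector of samples known to carry the
#'   haplotype heterozygously (must be non-empty).
#' @param noncarrier_ids Samples required to be homozygous reference.
#'   `NULL` (default) means every sample not in `carrier_ids`, matching the
#'   screen's use of all non-carrier animals of the same breed plus
#'   unrelated breeds.
#' @param flank_bp Flank added to each side of `region`, in bp
#'   (default 1e6).
#' @param min_qual Variants must have quality strictly greater than this
#'   (default 30).
#' @param require_impact Impact class retained by [impact_filter()]
#'   (default `"HIGH"`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(region, carrier_ids, noncarrier_ids = NULL,
                          flank_bp = 1e6, min_qual = 30,
                          require_impact = "HIGH") {
  if (length(carrier_ids) == 0) abort("carrier_ids must be non-empty")
  if (!is.null(noncarrier_ids)) {
    overlap <- intersect(carrier_ids, noncarrier_ids)
    if (length(overlap) > 0) {
      abort(paste0("carrier and non-carrier sets overlap: ",
                   paste(overlap, collapse = ", ")))
    }
  }
  if (flank_bp < 0) abort("flank_bp must be >= 0")
  structure(
    list(region = parse_region(region), flank_bp = flank_bp,
         min_qual = min_qual, carrier_ids = carrier_ids,
         noncarrier_ids = noncarrier_ids, require_impact = require_impact),
    class = "filter_config"
  )
}

## first-fail reasons in their fixed reporting order
fail_reason_levels <- function() {
  c("outside_region", "low_qual", "carrier_not_het", "carrier_missing",
    "noncarrier_not_hom_ref", "noncarrier_missing", "impact_mismatch",
    "unannotated")
}

new_filter_report <- function(counts, surviving, fail_reasons, config) {
  structure(list(counts = counts, surviving = surviving,
                 fail_reasons = fail_reasons, config = config),
            class = "filter_report")
}

#' Three-condition carrier-concordance variant filter
#'
#' Screens variant calls for candidates fully concordant with a
#' homozygote-deficient haplotype: a surviving variant must (after region
#' and quality restriction) (i) differ from the reference allele, (ii) be
#' called heterozygous in *every* haplotype-carrier sample and (iii) be
#' called homozygous reference in *every* non-carrier sample. A missing
#' call at any required sample fails the variant (conservative), with a
#' distinct fail reason. Each failing variant is assigned the first failing
#' condition in the fixed order region, quality, carrier concordance,
#' non-carrier concordance, so reports are reproducible.
#'
#' @param calls A [geno_tbl][as_geno_tbl] of variant calls.
#' @param config A [filter_config()].
#' @return A `filter_report`: list with `counts` (named integers `n_input`,
#'   `n_region`, `n_qual`, `n_concordant`, `n_impact`), `surviving` (tibble
#'   of surviving variant sites) and `fail_reasons` (tibble with one row and
#'   one first-fail reason per non-surviving variant). Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @seealso [impact_filter()] for the subsequent impact-class restriction.
#' @export
concordance_filter <- function(calls, config) {
  calls <- as_geno_tbl(calls)
  samples <- sample_ids(calls)
  carriers <- config$carrier_ids
  noncarriers <- config$noncarrier_ids %||% setdiff(samples, carriers)
  missing_ids <- setdiff(c(carriers, noncarriers), samples)
  if (length(missing_ids) > 0) {
    abort(paste0("sample id(s) absent from calls: ",
                 paste(missing_ids, collapse = ", ")))
  }

  sites <- variant_sites(calls)
  rg <- config$region
  lo <- rg$start - config$flank_bp
  hi <- rg$end + config$flank_bp

  per_carrier <- calls |>
    filter(.data$sample_id %in% carriers) |>
    group_by(.data$chrom, .data$pos, .data$alt) |>
    summarise(carrier_missing = any(.data$gt == "missing"),
              carrier_all_het = all(.data$gt == "het"), .groups = "drop")
  per_noncar <- calls |>
    filter(.data$sample_id %in% noncarriers) |>
    group_by(.data$chrom, .data$pos, .data$alt) |>
    summarise(noncar_missing = any(.data$gt == "missing"),
              noncar_all_ref = all(.data$gt == "hom_ref"), .groups = "drop")

  ev <- sites |>
    left_join(per_carrier, by = c("chrom", "pos", "alt")) |>
    left_join(per_noncar, by = c("chrom", "pos", "alt")) |>
    mutate(
      in_region = .data$chrom == rg$chrom & .data$pos >= lo & .data$pos <= hi,
      qual_ok = .data$qual > config$min_qual,
      reason = dplyr::case_when(
        !in_region ~ "outside_region",
        !qual_ok ~ "low_qual",
        carrier_missing ~ "carrier_missing",
        !carrier_all_het ~ "carrier_not_het",
        noncar_missing ~ "noncarrier_missing",
        !noncar_all_ref ~ "noncarrier_not_hom_ref",
        TRUE ~ NA_character_
      )
    )

  counts <- c(
    n_input = nrow(ev),
    n_region = sum(ev$in_region),
    n_qual = sum(ev$in_region & ev$qual_ok),
    n_concordant = sum(is.na(ev$reason)),
    n_impact = NA_integer_
  )
  surviving <- ev |>
    filter(is.na(.data$reason)) |>
    select("chrom", "pos", "ref", "alt", "qual")
  fail_reasons <- ev |>
    filter(!is.na(.data$reason)) |>
    select("chrom", "pos", "ref", "alt", "reason")
  new_filter_report(counts, surviving, fail_reasons, config)
}

#' Normalise an impact-class label
#'
#' Annotation tools print impact in varying styles (`"Modifier"`,
#' `"High, stop-gain (p.Glu111*)"`); this keeps the leading word,
#' uppercased, and validates it against `HIGH`, `MODERATE`, `LOW`,
#' `MODIFIER`.
#'
#' @param impact Character vector of raw impact labels.
#' @return Character vector of canonical impact classes.
#' @export
normalize_impact <- function(impact) {
  out <- toupper(stringr::str_extract(impact, "^[A-Za-z]+"))
  bad <- !out %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (any(bad)) {
    abort(paste0("unrecognised impact label(s): ",
                 paste(unique(impact[bad]), collapse = ", ")))
  }
  out
}

#' Restrict surviving variants to a predicted-impact class
#'
#' Applies the final prioritization step: among concordance-filter
#' survivors, keep only variants whose annotated impact equals the
#' configured class (typically `HIGH`, isolating protein-truncating
#' candidates). Every surviving variant must be annotated; an unannotated
#' survivor is an error because annotation must run first.
#'
#' @param report A `filter_report` from [concordance_filter()].
#' @param annotations Tibble with columns `chrom`, `pos`, `alt` (or
#'   `chrom`, `pos`) and `impact` (raw labels accepted, see
#'   [normalize_impact()]).
#' @param require_impact Impact class to keep; defaults to the value in the
#'   report's config.
#' @return An updated `filter_report` with `n_impact` set.
#' @export
impact_filter <- function(report, annotations, require_impact = NULL) {
  stopifnot(inherits(report, "filter_report"))
  require_impact <- require_impact %||% report$config$require_impact
  ann <- as_tibble(annotations)
  ann$impact <- normalize_impact(ann$impact)
  by_cols <- intersect(c("chrom", "pos", "alt"), names(ann))
  ev <- left_join(report$surviving, ann[, c(by_cols, "impact")], by = by_cols)
  if (anyNA(ev$impact)) {
    miss <- ev |> filter(is.na(.data$impact))
    abort(paste0("surviving variant(s) without impact annotation at: ",
                 paste(miss$pos, collapse = ", "),
                 " (run annotation before impact_filter)"))
  }
  keep <- ev$impact == require_impact
  counts <- report$counts
  counts["n_impact"] <- sum(keep)
  fail <- ev |>
    filter(!keep) |>
    mutate(reason = "impact_mismatch") |>
    select("chrom", "pos", "ref", "alt", "reason")
  new_filter_report(
    counts,
    ev |> filter(keep) |> select(-dplyr::any_of("impact")),
    bind_rows(report$fail_reasons, fail),
    report$config
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cts <- x$counts
  labs <- c(n_input = "input variants", n_region = "in region",
            n_qual = "pass quality", n_concordant = "carrier-concordant",
            n_impact = "required impact")
  for (nm in names(cts)) {
    if (!is.na(cts[[nm]])) cat(sprintf("  %-20s %d\n", labs[[nm]], cts[[nm]]))
  }
  invisible(x)
}
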