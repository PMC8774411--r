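#' Genotype call tables
#'
#' The pipeline represents a set of diploid genotype calls as a long tibble
#' (class `geno_tbl`) with one row per variant x sample combination:
#'
#' * `chrom`, `pos` — sequence name and 1-based genomic position,
#' * `ref`, `alt` — uppercase reference/alternate alleles (biallelic),
#' * `qual` — non-negative variant quality score,
#' * `sample_id` — sample identifier,
#' * `gt` — one of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#'
#' Sample order (the VCF column order) is the order of first appearance of
#' `sample_id`; variant order is `(chrom, pos, alt)`.
#'
#' @param x A data frame with the columns above.
#' @return `as_geno_tbl()` returns the validated tibble with class
#'   `geno_tbl` prepended.
#' @export
as_geno_tbl <- function(x) {
  x <- as_tibble(x)
  needed <- c("chrom", "pos", "ref", "alt", "qual", "sample_id", "gt")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_gt <- setdiff(unique(x$gt), gt_states())
  if (length(bad_gt) > 0) {
    abort(paste0("invalid genotype state(s): ", paste(bad_gt, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$pos < 1)) abort("positions must be >= 1")
    if (any(x$qual < 0, na.rm = TRUE)) abort("quality scores must be >= 0")
    if (any(x$ref == x$alt)) abort("ref and alt alleles must differ")
  }
  class(x) <- unique(c("geno_tbl", class(x)))
  x
}

gt_states <- function() c("hom_ref", "het", "hom_alt", "missing")

status_levels <- function() c("carrier_het", "carrier_hom", "non_carrier", "unknown")

#' @rdname as_geno_tbl
#' @export
variant_sites <- function(x) {
  distinct(as_tibble(x), .data$chrom, .data$pos, .data$ref, .data$alt,
           .data$qual) |>
    arrange(.data$chrom, .data$pos, .data$alt)
}

#' @rdname as_geno_tbl
#' @export
sample_ids <- function(x) unique(x$sample_id)

#' Parse a genomic region string
#'
#' Regions are written `chrom:start-end`, 1-based inclusive; thousands
#' separators (commas) in the coordinates are ignored.
#'
#' @param region A single string such as `"NC_040254.1:145,243,481-148,946,399"`.
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1)
  m <- stringr::str_match(region, "^(.+):([0-9,]+)-([0-9,]+)$")
  if (is.na(m[1, 1])) {
    abort(paste0("malformed region '", region, "'; expected chrom:start-end"))
  }
  start <- as.numeric(gsub(",", "", m[1, 3]))
  end <- as.numeric(gsub(",", "", m[1, 4]))
  if (start > end) abort("region start must be <= end")
  list(chrom = m[1, 2], start = start, end = end)
}

## GT string ("0/1", "0|1", "./.", ...) -> call state for ALT allele `allele`
gt_string_to_state <- function(gt, allele = 1L) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  vapply(strsplit(gt, "/", fixed = TRUE), function(a) {
    if (length(a) == 0 || any(is.na(a)) || any(a == ".")) return("missing")
    hits <- sum(a == as.character(allele))
    if (hits == 2) "hom_alt" else if (hits == 1) "het" else "hom_ref"
  }, character(1), USE.NAMES = FALSE)
}

state_to_gt_string <- function(state) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[state]
}

#' Read genotype calls from a VCF file
#'
#' Reads a VCF v4.2 file (GT field only) into a long genotype table (see
#' [as_geno_tbl()]). Only biallelic records are kept by default; multi-allelic
#' records are either rejected (with their reason recorded in the
#' `"rejected"` attribute) or split into one biallelic record per alternate
#' allele. Phased separators (`|`) are treated as unphased: the analysis
#' never uses phase.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param region Optional `chrom:start-end` region (1-based inclusive); only
#'   records with `start <= pos <= end` on `chrom` are returned. A region on
#'   a chromosome absent from the file yields an empty table with a warning.
#' @param split_multiallelic If `TRUE`, split multi-allelic records into
#'   biallelic ones (genotypes are recoded per alternate allele); if `FALSE`
#'   (default) such records are rejected and logged.
#' @return A `geno_tbl`. The attribute `"rejected"` holds a tibble
#'   (`chrom`, `pos`, `ref`, `alt`, `reason`) of records that were dropped,
#'   so that `n_input = n_returned_sites + n_rejected`.
#' @export
read_vcf <- function(path, region = NULL, split_multiallelic = FALSE) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  samples <- colnames(vcf@gt)
  samples <- samples[samples != "FORMAT"]
  if (length(samples) == 0) abort("VCF header declares no samples")

  fix <- vcf@fix
  n_rec <- nrow(fix)
  rejected <- tibble(chrom = character(), pos = numeric(), ref = character(),
                     alt = character(), reason = character())
  empty <- as_geno_tbl(tibble(chrom = character(), pos = numeric(),
                              ref = character(), alt = character(),
                              qual = numeric(), sample_id = character(),
                              gt = character()))
  if (is.null(n_rec) || n_rec == 0) {
    attr(empty, "rejected") <- rejected
    attr(empty, "samples") <- samples
    return(empty)
  }

  rec <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]),
    ref = toupper(fix[, "REF"]),
    alt = toupper(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  bad <- is.na(rec$pos) | is.na(rec$ref) | is.na(rec$alt)
  if (any(bad)) {
    abort(paste0("malformed VCF record at data line(s) ",
                 paste(which(bad), collapse = ", "), " of '", path, "'"))
  }
  rec$qual[is.na(rec$qual)] <- 0

  gt_raw <- vcf@gt[, samples, drop = FALSE]
  if (n_rec == 1) gt_raw <- matrix(gt_raw, nrow = 1,
                                   dimnames = list(NULL, samples))

  multi <- grepl(",", rec$alt, fixed = TRUE)
  keep_idx <- which(!multi)
  out_list <- list()
  if (length(keep_idx) > 0) {
    gt_keep <- gt_raw[keep_idx, , drop = FALSE]
    out_list[[length(out_list) + 1]] <- tibble(
      chrom = rep(rec$chrom[keep_idx], each = length(samples)),
      pos = rep(rec$pos[keep_idx], each = length(samples)),
      ref = rep(rec$ref[keep_idx], each = length(samples)),
      alt = rep(rec$alt[keep_idx], each = length(samples)),
      qual = rep(rec$qual[keep_idx], each = length(samples)),
      sample_id = rep(samples, times = length(keep_idx)),
      gt = gt_string_to_state(as.vector(t(gt_keep)))
    )
  }
  if (any(multi)) {
    if (split_multiallelic) {
      for (i in which(multi)) {
        alts <- strsplit(rec$alt[i], ",", fixed = TRUE)[[1]]
        for (k in seq_along(alts)) {
          out_list[[length(out_list) + 1]] <- tibble(
            chrom = rec$chrom[i], pos = rec$pos[i], ref = rec$ref[i],
            alt = alts[k], qual = rec$qual[i], sample_id = samples,
            gt = gt_string_to_state(gt_raw[i, ], allele = k)
          )
        }
      }
    } else {
      rejected <- bind_rows(rejected, tibble(
        chrom = rec$chrom[multi], pos = rec$pos[multi], ref = rec$ref[multi],
        alt = rec$alt[multi], reason = "multiallelic"
      ))
      warn(paste0(sum(multi), " multi-allelic record(s) rejected ",
                  "(set split_multiallelic = TRUE to split)"))
    }
  }
  out <- if (length(out_list) > 0) bind_rows(out_list) else empty

  if (!is.null(region)) {
    rg <- parse_region(region)
    if (nrow(out) > 0 && !rg$chrom %in% unique(out$chrom)) {
      warn(paste0("region chromosome '", rg$chrom, "' not present in VCF"))
      out <- out[0, ]
    } else {
      out <- filter(out, .data$chrom == rg$chrom,
                    .data$pos >= rg$start, .data$pos <= rg$end)
    }
  }
  out <- arrange(out, .data$chrom, .data$pos, .data$alt,
                 match(.data$sample_id, samples))
  out <- as_geno_tbl(out)
  attr(out, "rejected") <- rejected
  attr(out, "samples") <- samples
  out
}

#' Write genotype calls to a VCF file
#'
#' Emits a minimal valid VCF v4.2 with a single `GT` FORMAT field. Records
#' are written in deterministic `(chrom, pos, alt)` order; sample columns
#' follow the order of first appearance in the table. Missing calls are
#' written as `./.`.
#'
#' @param calls A [geno_tbl][as_geno_tbl].
#' @param path Output path.
#' @param samples Optional character vector fixing the sample column order
#'   (defaults to order of first appearance).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, samples = NULL) {
  calls <- as_geno_tbl(calls)
  samples <- samples %||% attr(calls, "samples") %||% sample_ids(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recleth",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            samples), collapse = "\t")
  )
  sites <- variant_sites(calls)
  body <- character(0)
  if (nrow(sites) > 0) {
    wide <- calls |>
      select("chrom", "pos", "ref", "alt", "sample_id", "gt") |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "gt",
                         values_fill = "missing")
    wide <- left_join(sites, wide, by = c("chrom", "pos", "ref", "alt"))
    gt_cols <- as.matrix(wide[, samples, drop = FALSE])
    gt_cols[] <- state_to_gt_string(gt_cols)
    body <- paste(
      wide$chrom, format(wide$pos, scientific = FALSE, trim = TRUE), ".",
      wide$ref, wide$alt,
      format(wide$qual, scientific = FALSE, trim = TRUE, digits = 10),
      ".", "GT",
      apply(gt_cols, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write ", path)))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

normalize_status <- function(status) {
  s <- trimws(status)
  canon <- s %in% status_levels()
  out <- ifelse(canon, s, NA_character_)
  ## haplotype-notation synonyms: "+/+", "HAP/+", "HAP/HAP"
  hap <- stringr::str_match(s, "^([^/]+)/([^/]+)$")
  syn <- !canon & !is.na(hap[, 1])
  out[syn & hap[, 2] == "+" & hap[, 3] == "+"] <- "non_carrier"
  out[syn & xor(hap[, 2] == "+", hap[, 3] == "+")] <- "carrier_het"
  out[syn & hap[, 2] != "+" & hap[, 3] != "+" & hap[, 2] == hap[, 3]] <- "carrier_hom"
  out
}

#' Read a sample-status table
#'
#' Reads a tab-separated table of per-sample haplotype carrier status with
#' columns `sample_id`, `breed`, `haplotype_status`, `sequenced` and
#' optionally `cohort_year`. Status labels may use either the canonical
#' levels (`carrier_het`, `carrier_hom`, `non_carrier`, `unknown`) or
#' haplotype notation (`+/+`, `LDHH6/+`, `LDHH6/LDHH6`, ...). Unrecognised
#' labels become `unknown` with a warning giving their count.
#'
#' @param path Path to the TSV file.
#' @return A tibble with validated `haplotype_status`.
#' @export
read_status_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("sample_id", "haplotype_status") %in% names(x))) {
    abort("status table needs columns sample_id and haplotype_status")
  }
  if (anyDuplicated(x$sample_id) > 0) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(paste0("duplicate sample_id in status table: ",
                 paste(dup, collapse = ", ")))
  }
  mapped <- normalize_status(x$haplotype_status)
  n_unknown <- sum(is.na(mapped))
  if (n_unknown > 0) {
    warn(paste0(n_unknown, " unrecognised status label(s) set to 'unknown'"))
    mapped[is.na(mapped)] <- "unknown"
  }
  x$haplotype_status <- mapped
  if ("sequenced" %in% names(x)) {
    x$sequenced <- as.logical(toupper(x$sequenced) %in% c("TRUE", "T", "1", "YES"))
  }
  if ("cohort_year" %in% names(x)) x$cohort_year <- as.integer(x$cohort_year)
  x
}

#' @rdname read_status_table
#' @param status A status tibble as returned by `read_status_table()`.
#' @export
write_status_table <- function(status, path) {
  readr::write_tsv(status, path, progress = FALSE)
  invisible(path)
}

#' Read and write mating records
#'
#' Mating tables are TSVs with one row per lamb (plus one row with empty
#' lamb fields for matings without offspring): `mating_id`,
#' `sire_genotype`, `dam_genotype`, `inseminated`, `pregnant`, `lamb_id`,
#' `sex` (`M`/`F`), `genotype`, `birthweight` (kg), `weight_d15` (kg),
#' `survival_days`, `censored`. The average daily gain over days 0-15,
#' `adg_0_15` (g/day), is recomputed on read as
#' `(weight_d15 - birthweight) / 15 * 1000`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of mating/lamb records.
#' @export
read_matings <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    mating_id = "c", sire_genotype = "c", dam_genotype = "c",
    inseminated = "l", pregnant = "l", lamb_id = "c", sex = "c",
    genotype = "c", birthweight = "d", weight_d15 = "d",
    survival_days = "d", censored = "l"
  ), progress = FALSE)
  bad_preg <- x |>
    group_by(.data$mating_id) |>
    summarise(bad = any(!.data$pregnant & !is.na(.data$lamb_id)),
              .groups = "drop")
  if (any(bad_preg$bad)) {
    abort("mating table has offspring rows for non-pregnant matings")
  }
  mutate(x, adg_0_15 = (.data$weight_d15 - .data$birthweight) / 15 * 1000)
}

#' @rdname read_matings
#' @param matings A mating tibble.
#' @export
write_matings <- function(matings, path) {
  readr::write_tsv(select(matings, -dplyr::any_of("adg_0_15")), path,
                   progress = FALSE)
  invisible(path)
}
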