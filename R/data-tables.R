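#' Candidate SNVs of the LDHH6 screen
#'
#' The eleven candidate single-nucleotide variants that survive the
#' carrier-concordance screen in the extended LDHH6 region on ovine
#' chromosome 3 (Oar_rambouillet_v1.0, NC_040254.1), with their published
#' positions, alleles, calling quality scores and predicted impact. The
#' single HIGH-impact candidate is the CCDC65 stop-gain at
#' g.147,207,999C>A.
#'
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `qual`, `location`,
#'   `impact` (raw annotation-style labels; see [normalize_impact()]).
#' @export
ldhh6_candidate_variants <- function() {
  tibble(
    chrom = "NC_040254.1",
    pos = c(145928967, 146173708, 146566556, 146718479, 146809812,
            147207999, 147345297, 148189184, 148212194, 148417713,
            148904267),
    ref = c("C", "G", "C", "G", "T", "C", "G", "A", "A", "A", "G"),
    alt = c("G", "A", "T", "A", "C", "A", "A", "G", "C", "G", "A"),
    qual = c(347.3, 396.0, 133.1, 272.7, 604.4, 506.7, 192.3, 596.7,
             181.7, 545.8, 439.1),
    location = c("intergenic, downstream of FAM186A",
                 "intergenic, upstream of ASIC1",
                 "intronic, FAM186B", "intronic, SPATS2",
                 "intronic, DNAJC22", "exonic, CCDC65 (c.521G>T)",
                 "intergenic, upstream of TEX49", "intergenic",
                 "intergenic", "intergenic, downstream of ZNF641",
                 "intronic, HDAC7"),
    impact = c(rep("Modifier", 5), "High, stop-gain (p.Glu111*)",
               rep("Modifier", 5))
  )
}

#' Extended LDHH6 screening region
#'
#' The LDHH6 haplotype span extended by 1 Mb on each side, the window
#' within which candidate variants were extracted.
#'
#' @return The region string `"NC_040254.1:145243481-148946399"`.
#' @export
ldhh6_region <- function() "NC_040254.1:145243481-148946399"

#' Genotyped Lacaune cohort: haplotype status by CCDC65 genotype
#'
#' Counts from the 2952-lamb Lacaune genomic-selection cohort genotyped
#' both for LDHH6 status (SNP-array haplotyping) and for the CCDC65
#' c.521G>T variant (direct assay). Rows are variant genotypes (G/G =
#' `hom_ref`, G/T = `het`, T/T = `hom_alt`), columns LDHH6 status.
#'
#' @param as_cohort If `TRUE`, expand the counts into a per-sample tibble
#'   (`sample_id`, `haplotype_status`, `genotype`) suitable for
#'   [concordance_audit()] and [status_genotype_table()].
#' @return A 3x3 count matrix, or the expanded tibble.
#' @export
ldhh6_cohort_counts <- function(as_cohort = FALSE) {
  m <- matrix(
    c(2540, 3, 0,
      9, 399, 0,
      0, 0, 1),
    nrow = 3, byrow = TRUE,
    dimnames = list(genotype = c("hom_ref", "het", "hom_alt"),
                    status = c("non_carrier", "carrier_het", "carrier_hom"))
  )
  if (!as_cohort) return(m)
  cells <- as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(cells) <- c("genotype", "haplotype_status", "n_samples")
  cells <- filter(cells, .data$n_samples > 0)
  out <- tidyr::uncount(cells, weights = .data$n_samples)
  mutate(out, sample_id = sprintf("COHORT_%04d", row_number()),
         .before = 1)
}

#' Sheep diversity-panel genotype counts for the CCDC65 variant
#'
#' Per-breed G/G and G/T counts from a DNA diversity panel of French (FR)
#' and Swiss (CH) sheep breeds genotyped for CCDC65 c.521G>T. No T/T
#' animal was observed in the panel.
#'
#' @return A tibble: `breed`, `country`, `total`, `n_hom_ref`, `n_het`.
#' @export
sheep_diversity_panel <- function() {
  tibble::tribble(
    ~breed, ~country, ~total, ~n_hom_ref, ~n_het,
    "Berrichon du Cher", "FR", 30, 30, 0,
    "Blanche du Massif Central", "FR", 31, 29, 2,
    "Causse du Lot", "FR", 32, 32, 0,
    "Charmoise", "FR", 31, 31, 0,
    "Charollais", "FR", 30, 30, 0,
    "Corse", "FR", 30, 30, 0,
    "East Friesian", "CH", 18, 18, 0,
    "Engadine Red", "CH", 3, 3, 0,
    "Ile de France", "FR", 28, 28, 0,
    "Lacaune (meat)", "FR", 45, 43, 2,
    "Lacaune (milk)", "FR", 40, 37, 3,
    "Lacaune (milk)", "CH", 37, 27, 10,
    "Limousine", "FR", 30, 30, 0,
    "Manech tete rousse", "FR", 29, 29, 0,
    "Martinik", "FR", 23, 23, 0,
    "Merinos d'Arles", "FR", 27, 27, 0,
    "Mourerous", "FR", 27, 27, 0,
    "Mouton Vendeen", "FR", 30, 30, 0,
    "Noir du Velay", "FR", 28, 28, 0,
    "Prealpes du sud", "FR", 27, 27, 0,
    "Rava", "FR", 29, 29, 0,
    "Romane", "FR", 30, 30, 0,
    "Romanov", "FR", 26, 26, 0,
    "Rouge de l'Ouest", "FR", 30, 30, 0,
    "Roussin", "FR", 30, 30, 0,
    "Saaser Mutte", "CH", 10, 10, 0,
    "Suffolk", "FR", 29, 29, 0,
    "Swiss Mirror", "CH", 11, 11, 0,
    "Swiss White Alpine", "CH", 14, 14, 0,
    "Tarasconnaise", "FR", 33, 33, 0,
    "Texel", "FR", 27, 27, 0,
    "Valais Blacknose", "CH", 14, 14, 0,
    "Valais Red", "CH", 13, 13, 0
  )
}

#' Protein domains of CCDC65
#'
#' Approximate residue coordinates of the CCDC65 domain layout used by the
#' packaged gene-model fixture: an N-terminal NYD-SP28 domain followed by
#' three coiled-coil (CC) domains, with the premature stop at residue 111
#' falling inside the first CC domain. Exact residue bounds are synthetic
#' (the published schematic gives the order and the stop position, not the
#' bounds); they are chosen so the truncated protein keeps NYD-SP28 and
#' loses the two distal CC domains.
#'
#' @return A tibble: `name`, `start_res`, `end_res`.
#' @export
ccdc65_domains <- function() {
  tibble(
    name = c("NYD-SP28", "CC1", "CC2", "CC3"),
    start_res = c(5, 108, 200, 300),
    end_res = c(105, 150, 260, 360)
  )
}
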