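#' Transcript models
#'
#' A `transcript_model` carries the strand-aware exon geometry and spliced
#' sequence needed to map a genomic SNV onto transcript, CDS and protein
#' coordinates. Exons are genomic intervals (1-based inclusive) listed in
#' *transcript* order: ascending genomic position on `+`, descending on
#' `-`. `sequence` is the spliced transcript on the sense (mRNA) strand.
#' The CDS starts at transcript position `cds_start_tx` (so the 5'UTR is
#' `cds_start_tx - 1` nt long) and runs to the first in-frame stop codon of
#' the reference sequence, which must exist; the reference frame therefore
#' contains no internal stop by construction.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble with columns `start`, `end` (genomic, 1-based
#'   inclusive), rows in transcript order.
#' @param cds_start_tx 1-based transcript coordinate of the first CDS base.
#' @param sequence Spliced transcript sequence (sense strand).
#' @return A list of class `transcript_model` with derived fields
#'   `cds_len` (nt, including the stop codon) and `ref_protein_len`
#'   (residues, excluding the stop).
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             cds_start_tx, sequence) {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  exons <- as_tibble(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), nrow(exons) >= 1)
  if (any(exons$start > exons$end)) abort("exon start must be <= end")
  ord <- order(exons$start)
  ov <- any(exons$end[ord][-nrow(exons)] >= exons$start[ord][-1])
  if (ov) abort("exons must be non-overlapping")
  expected_order <- if (strand == "+") order(exons$start) else
    order(exons$start, decreasing = TRUE)
  if (!identical(expected_order, seq_len(nrow(exons)))) {
    abort("exons must be listed in transcript order for the given strand")
  }
  sequence <- toupper(sequence)
  tx_len <- sum(exons$end - exons$start + 1)
  if (tx_len != nchar(sequence)) {
    abort(sprintf("spliced exon length (%d) != sequence length (%d)",
                  tx_len, nchar(sequence)))
  }
  if (cds_start_tx < 1 || cds_start_tx > tx_len - 2) {
    abort("cds_start_tx outside transcript")
  }
  tr <- translate_to_stop(substr(sequence, cds_start_tx, tx_len))
  if (!tr$has_stop) abort("reference CDS frame reaches transcript end without a stop codon")
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, cds_start_tx = cds_start_tx, sequence = sequence,
         cds_len = 3L * (tr$len + 1L), ref_protein_len = tr$len,
         ref_protein = tr$protein),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s strand)\n", x$transcript_id,
              x$chrom, x$strand))
  cat(sprintf("  %d exon(s), transcript %d nt, 5'UTR %d nt, CDS %d nt, protein %d aa\n",
              nrow(x$exons), nchar(x$sequence), x$cds_start_tx - 1,
              x$cds_len, x$ref_protein_len))
  invisible(x)
}

## translate from the first base of `s`, stopping at the first stop codon
translate_to_stop <- function(s) {
  n <- 3L * (nchar(s) %/% 3L)
  if (n == 0) return(list(protein = "", len = 0L, has_stop = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1, n)), no.init.codon = TRUE
  ))
  stop_at <- as.integer(regexpr("*", aa, fixed = TRUE))
  if (stop_at < 0) {
    list(protein = aa, len = nchar(aa), has_stop = FALSE)
  } else {
    list(protein = substr(aa, 1, stop_at - 1L), len = stop_at - 1L,
         has_stop = TRUE)
  }
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Map a genomic position onto a spliced transcript
#'
#' Converts a 1-based genomic position (and optionally the forward-strand
#' allele observed there) to the 1-based spliced-transcript coordinate. On
#' minus-strand models the allele is complemented, so a genomic `C>A`
#' becomes a transcript `G>T`.
#'
#' @param model A [transcript_model()].
#' @param pos Genomic position (1-based).
#' @param allele_fwd Optional single base on the genomic forward strand.
#' @return A list with `region` (`"exonic"`, `"intronic"` or
#'   `"intergenic"`), and for exonic positions `tx_pos` and (if supplied)
#'   `allele_tx`.
#' @export
genomic_to_transcript <- function(model, pos, allele_fwd = NULL) {
  ex <- model$exons
  cum <- cumsum(ex$end - ex$start + 1)
  before <- c(0, head(cum, -1))
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0) {
    region <- if (pos >= min(ex$start) && pos <= max(ex$end)) "intronic"
    else "intergenic"
    return(list(region = region, tx_pos = NA_integer_))
  }
  offset <- if (model$strand == "+") pos - ex$start[hit] else ex$end[hit] - pos
  tx_pos <- as.integer(before[hit] + offset + 1)
  out <- list(region = "exonic", tx_pos = tx_pos)
  if (!is.null(allele_fwd)) {
    out$allele_tx <- if (model$strand == "-") complement_base(allele_fwd)
    else allele_fwd
  }
  out
}

#' @rdname genomic_to_transcript
#' @param tx_pos Spliced-transcript position (1-based) to map back to the
#'   genome.
#' @return `transcript_to_genomic()` returns the genomic position.
#' @export
transcript_to_genomic <- function(model, tx_pos) {
  ex <- model$exons
  lens <- ex$end - ex$start + 1
  cum <- cumsum(lens)
  if (tx_pos < 1 || tx_pos > cum[length(cum)]) abort("tx_pos outside transcript")
  hit <- which(tx_pos <= cum)[1]
  offset <- tx_pos - c(0, cum)[hit] - 1
  if (model$strand == "+") ex$start[hit] + offset else ex$end[hit] - offset
}

aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

#' Call the coding consequence of an SNV on a transcript model
#'
#' Substitutes the variant base into the spliced transcript, translates the
#' reference and mutant CDS (each up to its first in-frame stop), and
#' classifies the consequence: `stop_gained` (impact `HIGH`), `missense`
#' (`MODERATE`), `synonymous` (`LOW`), `stop_lost` (`MODERATE`), or the
#' non-coding classes `5_prime_utr` / `3_prime_utr` / `intronic` /
#' `intergenic` (all `MODIFIER`). Only single-nucleotide substitutions are
#' supported; the model sequence at the mapped position must equal the
#' strand-adjusted reference allele (a mismatch is a hard error guarding
#' against coordinate bugs).
#'
#' HGVS-style names are emitted at the genomic (`g.`), coding (`c.`) and
#' protein (`p.`) levels. With `dialect = "cds"` (strict HGVS) the `c.`
#' position is counted from the first CDS base; with
#' `dialect = "transcript"` it is counted from transcript base 1, the
#' convention some annotation pipelines print when the 5'UTR is folded into
#' the coding coordinate.
#'
#' @param model A [transcript_model()].
#' @param variant A one-row data frame (or list) with `chrom`, `pos`,
#'   `ref`, `alt` on the genomic forward strand.
#' @param dialect `"cds"` or `"transcript"` numbering for `hgvs_c`.
#' @return A one-row tibble: `hgvs_g`, `hgvs_c`, `hgvs_p`,
#'   `consequence_term`, `impact`, `codon_index`, `ref_protein_len`,
#'   `alt_protein_len`.
#' @export
call_consequence <- function(model, variant, dialect = c("cds", "transcript")) {
  dialect <- match.arg(dialect)
  v <- as.list(variant)
  if (nchar(v$ref) != 1 || nchar(v$alt) != 1) {
    abort("only single-nucleotide substitutions are supported (InDel given)")
  }
  if (!is.null(v$chrom) && v$chrom != model$chrom) {
    abort(sprintf("variant chromosome %s does not match model chromosome %s",
                  v$chrom, model$chrom))
  }
  hgvs_g <- sprintf("%s:g.%s%s>%s", model$chrom,
                    format(v$pos, scientific = FALSE, trim = TRUE),
                    v$ref, v$alt)
  base_call <- function(term, impact, hgvs_c = NA_character_,
                        hgvs_p = NA_character_, codon_index = NA_integer_,
                        alt_len = model$ref_protein_len) {
    tibble(hgvs_g = hgvs_g, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
           consequence_term = term, impact = impact,
           codon_index = codon_index,
           ref_protein_len = model$ref_protein_len,
           alt_protein_len = alt_len)
  }

  mp <- genomic_to_transcript(model, v$pos, v$ref)
  if (mp$region != "exonic") {
    return(base_call(mp$region, "MODIFIER"))
  }
  tx_pos <- mp$tx_pos
  ref_tx <- mp$allele_tx
  alt_tx <- if (model$strand == "-") complement_base(v$alt) else v$alt
  seq_base <- substr(model$sequence, tx_pos, tx_pos)
  if (seq_base != ref_tx) {
    abort(sprintf(
      "reference mismatch at %s:%s (transcript pos %d): model has %s, VCF ref maps to %s",
      model$chrom, format(v$pos, scientific = FALSE), tx_pos, seq_base, ref_tx))
  }

  u <- model$cds_start_tx - 1L
  c_num <- if (dialect == "transcript") tx_pos else tx_pos - u
  hgvs_c <- sprintf("c.%d%s>%s", c_num, ref_tx, alt_tx)

  if (tx_pos <= u) return(base_call("5_prime_utr", "MODIFIER", hgvs_c))
  if (tx_pos > u + model$cds_len) {
    return(base_call("3_prime_utr", "MODIFIER", hgvs_c))
  }

  mut_seq <- model$sequence
  substr(mut_seq, tx_pos, tx_pos) <- alt_tx
  tx_len <- nchar(model$sequence)
  ref_tr <- list(protein = model$ref_protein, len = model$ref_protein_len)
  mut_tr <- translate_to_stop(substr(mut_seq, model$cds_start_tx, tx_len))
  cds_pos <- tx_pos - u
  codon_at_variant <- as.integer(ceiling(cds_pos / 3))

  if (mut_tr$len < ref_tr$len) {
    idx <- mut_tr$len + 1L
    ref_aa <- substr(ref_tr$protein, idx, idx)
    hgvs_p <- sprintf("p.%s%d*", aa3[[ref_aa]], idx)
    return(base_call("stop_gained", "HIGH", hgvs_c, hgvs_p, idx,
                     alt_len = mut_tr$len))
  }
  if (mut_tr$len > ref_tr$len || !mut_tr$has_stop) {
    hgvs_p <- sprintf("p.*%dext", ref_tr$len + 1L)
    return(base_call("stop_lost", "MODERATE", hgvs_c, hgvs_p,
                     codon_at_variant, alt_len = mut_tr$len))
  }
  if (identical(mut_tr$protein, ref_tr$protein)) {
    idx <- codon_at_variant
    ref_aa <- if (idx > ref_tr$len) "*" else substr(ref_tr$protein, idx, idx)
    lab <- if (ref_aa == "*") "*" else aa3[[ref_aa]]
    return(base_call("synonymous", "LOW", hgvs_c,
                     sprintf("p.%s%d=", lab, idx), idx))
  }
  diff_at <- which(strsplit(mut_tr$protein, "")[[1]] !=
                     strsplit(ref_tr$protein, "")[[1]])[1]
  ref_aa <- substr(ref_tr$protein, diff_at, diff_at)
  alt_aa <- substr(mut_tr$protein, diff_at, diff_at)
  base_call("missense", "MODERATE", hgvs_c,
            sprintf("p.%s%d%s", aa3[[ref_aa]], diff_at, aa3[[alt_aa]]),
            as.integer(diff_at))
}

#' Summarise protein domains retained or lost by a truncating variant
#'
#' Given a `stop_gained` consequence call and a table of protein domains,
#' reports which domains the truncated protein keeps: a domain ending
#' before the premature stop residue is `retained`, one straddling it is
#' `partially_retained`, one starting at or after it is `lost`.
#'
#' @param call A one-row consequence tibble from [call_consequence()] with
#'   `consequence_term == "stop_gained"`.
#' @param domains Tibble with columns `name`, `start_res`, `end_res`
#'   (1-based residue coordinates).
#' @return The `domains` tibble with a `status` column.
#' @export
truncation_summary <- function(call, domains) {
  if (!identical(call$consequence_term, "stop_gained")) {
    abort("truncation_summary requires a stop_gained call")
  }
  idx <- call$codon_index
  as_tibble(domains) |>
    mutate(status = dplyr::case_when(
      .data$end_res < idx ~ "retained",
      .data$start_res >= idx ~ "lost",
      TRUE ~ "partially_retained"
    ))
}

#' Read and write gene-model files
#'
#' A gene model is a TSV with columns `transcript_id`, `chrom`, `strand`,
#' `exons` (semicolon-separated `start-end` genomic intervals in transcript
#' order) and `cds_start_tx`, paired with a transcript FASTA keyed by
#' `transcript_id`.
#'
#' @param path Path to the gene-model TSV.
#' @param fasta_path Path to the transcript FASTA.
#' @return A [transcript_model()] (or a named list of them if the TSV has
#'   several rows).
#' @export
read_gene_model <- function(path, fasta_path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", chrom = "c", strand = "c", exons = "c",
    cds_start_tx = "i"
  ), progress = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  models <- purrr::pmap(tb, function(transcript_id, chrom, strand, exons,
                                     cds_start_tx) {
    if (!transcript_id %in% names(seqs)) {
      abort(paste0("transcript ", transcript_id, " absent from FASTA"))
    }
    iv <- stringr::str_match_all(exons, "([0-9]+)-([0-9]+)")[[1]]
    transcript_model(
      transcript_id, chrom, strand,
      tibble(start = as.numeric(iv[, 2]), end = as.numeric(iv[, 3])),
      cds_start_tx, as.character(seqs[[transcript_id]])
    )
  })
  names(models) <- tb$transcript_id
  if (length(models) == 1) models[[1]] else models
}

#' @rdname read_gene_model
#' @param model A [transcript_model()].
#' @export
write_gene_model <- function(model, path, fasta_path) {
  tb <- tibble(
    transcript_id = model$transcript_id, chrom = model$chrom,
    strand = model$strand,
    exons = paste(sprintf("%d-%d", as.integer(model$exons$start),
                          as.integer(model$exons$end)), collapse = ";"),
    cds_start_tx = model$cds_start_tx
  )
  readr::write_tsv(tb, path, progress = FALSE)
  seqs <- Biostrings::DNAStringSet(setNames(model$sequence, model$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(path)
}
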