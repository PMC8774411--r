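test_that("genomic/transcript mapping is a bijection over all exonic positions", {
  for (seed in c(101, 102, 103, 104)) {
    m <- random_model(seed)
    tx_len <- nchar(m$sequence)
    for (tx in seq_len(tx_len)) {
      g <- transcript_to_genomic(m, tx)
      expect_equal(genomic_to_transcript(m, g)$tx_pos, tx)
    }
    # exon boundaries map consistently with cumulative exon lengths
    lens <- m$exons$end - m$exons$start + 1
    firsts <- cumsum(c(1, utils::head(lens, -1)))
    for (i in seq_along(firsts)) {
      g <- transcript_to_genomic(m, firsts[i])
      expect_true(g %in% c(m$exons$start[i], m$exons$end[i]))
    }
  }
})

test_that("minus-strand mapping complements alleles; plus strand is the identity", {
  fx <- gene_model_fixture()
  mp <- genomic_to_transcript(fx$model, fx$variant$pos, fx$variant$ref)
  expect_equal(mp$tx_pos, 521L)
  expect_equal(mp$allele_tx, "G")

  plus <- random_model(110, strand = "+")
  g1 <- plus$exons$start[1]
  mp2 <- genomic_to_transcript(plus, g1, "A")
  expect_equal(mp2$tx_pos, 1L)
  expect_equal(mp2$allele_tx, "A")
})

test_that("intronic and intergenic positions are classified, not mapped", {
  m <- random_model(120)
  if (nrow(m$exons) > 1) {
    by_start <- m$exons[order(m$exons$start), ]
    gap_pos <- by_start$end[1] + 1
    expect_equal(genomic_to_transcript(m, gap_pos)$region, "intronic")
  }
  expect_equal(genomic_to_transcript(m, max(m$exons$end) + 10)$region,
               "intergenic")
  cc <- call_consequence(m, list(chrom = "chrT",
                                 pos = max(m$exons$end) + 10,
                                 ref = "A", alt = "C"))
  expect_equal(cc$consequence_term, "intergenic")
  expect_equal(cc$impact, "MODIFIER")
})

test_that("the CCDC65-like fixture reproduces the published stop-gain call", {
  fx <- gene_model_fixture()
  expect_equal(fx$model$ref_protein_len, 498L)
  cc <- call_consequence(fx$model, fx$variant, dialect = "transcript")
  expect_equal(cc$consequence_term, "stop_gained")
  expect_equal(cc$impact, "HIGH")
  expect_equal(cc$codon_index, 111L)
  expect_equal(cc$alt_protein_len, 110L)
  expect_equal(cc$hgvs_c, "c.521G>T")
  expect_equal(cc$hgvs_p, "p.Glu111*")
  expect_equal(cc$hgvs_g, "NC_040254.1:g.147207999C>A")
  # strict-HGVS dialect numbers the same change from the CDS start
  cc_cds <- call_consequence(fx$model, fx$variant, dialect = "cds")
  expect_equal(cc_cds$hgvs_c, "c.331G>T")
  expect_equal(cc_cds$codon_index, 111L)
})

test_that("a plus-strand mirror of the fixture gives the identical call", {
  fx <- gene_model_fixture()
  m <- fx$model
  lens <- m$exons$end - m$exons$start + 1
  starts <- ends <- integer(length(lens))
  gpos <- 1000L
  for (i in seq_along(lens)) {
    starts[i] <- gpos
    ends[i] <- gpos + lens[i] - 1
    gpos <- ends[i] + 500L
  }
  mirror <- transcript_model("TX_MIRROR", m$chrom, "+",
                             tibble::tibble(start = starts, end = ends),
                             m$cds_start_tx, m$sequence)
  gpos_var <- transcript_to_genomic(mirror, 521L)
  cc <- call_consequence(mirror, list(chrom = m$chrom, pos = gpos_var,
                                      ref = "G", alt = "T"),
                         dialect = "transcript")
  orig <- call_consequence(m, fx$variant, dialect = "transcript")
  expect_equal(cc[c("hgvs_c", "hgvs_p", "consequence_term", "impact",
                    "codon_index", "ref_protein_len", "alt_protein_len")],
               orig[c("hgvs_c", "hgvs_p", "consequence_term", "impact",
                      "codon_index", "ref_protein_len", "alt_protein_len")])
})

test_that("random SNVs classify identically to an independent translate-both oracle", {
  n_checked <- 0
  for (seed in c(131, 132, 133)) {
    m <- random_model(seed)
    u <- m$cds_start_tx - 1
    tx_len <- nchar(m$sequence)
    withr::with_seed(seed + 1000, {
      tx_positions <- sample(seq(u + 1, u + m$cds_len), 25, replace = FALSE)
    })
    for (tx in tx_positions) {
      ref_tx <- substr(m$sequence, tx, tx)
      for (alt_tx in setdiff(c("A", "C", "G", "T"), ref_tx)) {
        gpos <- transcript_to_genomic(m, tx)
        flip <- function(b) if (m$strand == "-") chartr("ACGT", "TGCA", b) else b
        cc <- call_consequence(m, list(chrom = "chrT", pos = gpos,
                                       ref = flip(ref_tx),
                                       alt = flip(alt_tx)))
        # oracle: translate full reference and mutant CDS with seqinr
        mut <- m$sequence
        substr(mut, tx, tx) <- alt_tx
        translate_oracle <- function(s) {
          aa <- seqinr::translate(strsplit(substr(
            s, m$cds_start_tx, tx_len), "")[[1]])
          stop_at <- which(aa == "*")[1]
          if (is.na(stop_at)) aa else aa[seq_len(stop_at - 1)]
        }
        p_ref <- translate_oracle(m$sequence)
        p_mut <- translate_oracle(mut)
        want <- if (length(p_mut) < length(p_ref)) "stop_gained"
        else if (length(p_mut) > length(p_ref)) "stop_lost"
        else if (identical(p_ref, p_mut)) "synonymous"
        else "missense"
        expect_equal(cc$consequence_term, want,
                     info = sprintf("seed %d tx %d %s>%s", seed, tx,
                                    ref_tx, alt_tx))
        if (want == "stop_gained") {
          expect_equal(cc$alt_protein_len, cc$codon_index - 1L)
          expect_equal(cc$alt_protein_len, length(p_mut))
        }
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 200)
})

test_that("synonymous substitutions leave the protein length unchanged with LOW impact", {
  fx <- gene_model_fixture()
  # third base of the Glu111 GAA codon: GAA -> GAG is still Glu
  gpos <- transcript_to_genomic(fx$model, 523L)
  cc <- call_consequence(fx$model, list(chrom = fx$model$chrom, pos = gpos,
                                        ref = "T", alt = "C"))
  expect_equal(cc$consequence_term, "synonymous")
  expect_equal(cc$impact, "LOW")
  expect_equal(cc$alt_protein_len, cc$ref_protein_len)
})

test_that("reference mismatches and InDels are hard errors", {
  fx <- gene_model_fixture()
  bad <- fx$variant
  bad$ref <- "T"
  expect_error(call_consequence(fx$model, bad), "mismatch")
  indel <- fx$variant
  indel$alt <- "AT"
  expect_error(call_consequence(fx$model, indel), "single-nucleotide")
})

test_that("truncation summaries match an interval-overlap oracle", {
  fx <- gene_model_fixture()
  cc <- call_consequence(fx$model, fx$variant, dialect = "transcript")
  ts <- truncation_summary(cc, fx$domains)
  expect_equal(ts$status[ts$name == "NYD-SP28"], "retained")
  expect_equal(ts$status[ts$name %in% c("CC2", "CC3")], rep("lost", 2))

  withr::with_seed(55, {
    for (i in 1:20) {
      doms <- tibble::tibble(
        name = sprintf("D%d", 1:5),
        start_res = sample(1:400, 5)
      )
      doms$end_res <- doms$start_res + sample(5:80, 5)
      got <- truncation_summary(cc, doms)
      idx <- cc$codon_index
      want <- ifelse(doms$end_res < idx, "retained",
                     ifelse(doms$start_res >= idx, "lost",
                            "partially_retained"))
      expect_equal(got$status, want)
    }
  })

  syn <- call_consequence(fx$model, list(chrom = fx$model$chrom,
                                         pos = transcript_to_genomic(fx$model, 523L),
                                         ref = "T", alt = "C"))
  expect_error(truncation_summary(syn, fx$domains), "stop_gained")
})

test_that("a stop at residue 1 loses every domain", {
  fx <- gene_model_fixture()
  cc <- call_consequence(fx$model, fx$variant, dialect = "transcript")
  cc$codon_index <- 1L
  ts <- truncation_summary(cc, fx$domains)
  expect_true(all(ts$status == "lost"))
})

test_that("gene models round-trip through their TSV + FASTA representation", {
  fx <- gene_model_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gene_model(fx$model, tsv, fa)
  back <- read_gene_model(tsv, fa)
  expect_equal(back$exons, fx$model$exons)
  expect_equal(back$sequence, fx$model$sequence)
  expect_equal(back$cds_start_tx, fx$model$cds_start_tx)
  expect_equal(back$ref_protein_len, 498L)
  cc <- call_consequence(back, fx$variant, dialect = "transcript")
  expect_equal(cc$hgvs_p, "p.Glu111*")
})

test_that("model construction rejects inconsistent geometry", {
  expect_error(transcript_model("T", "c", "+",
                                tibble::tibble(start = 10, end = 5),
                                1, "ACGT"), "start")
  expect_error(transcript_model("T", "c", "+",
                                tibble::tibble(start = c(1, 5), end = c(6, 9)),
                                1, paste(rep("A", 11), collapse = "")),
               "overlap")
  expect_error(transcript_model("T", "c", "+",
                                tibble::tibble(start = 1, end = 12),
                                1, "ATGAAACCC"), "length")
  # frame that never reaches a stop codon
  expect_error(transcript_model("T", "c", "+",
                                tibble::tibble(start = 1, end = 9),
                                1, "ATGAAACCC"), "stop")
})
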