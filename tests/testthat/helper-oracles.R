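# Independent oracles and generators used across the suite.

# random long genotype table: n_var distinct sites x n_samp samples
random_geno <- function(n_var, n_samp, seed, chrom = "chr1",
                        pos_range = c(1e6, 2e6), p_missing = 0.05) {
  withr::with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samp))
    pos <- sort(sample(seq(pos_range[1], pos_range[2]), n_var))
    ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    qual <- round(runif(n_var, 1, 900), 1)
    gt <- sample(c("hom_ref", "het", "hom_alt", "missing"), n_var * n_samp,
                 replace = TRUE, prob = c(0.6, 0.25, 0.1, p_missing))
    as_geno_tbl(tibble::tibble(
      chrom = chrom, pos = rep(pos, each = n_samp),
      ref = rep(ref, each = n_samp), alt = rep(alt, each = n_samp),
      qual = rep(qual, each = n_samp),
      sample_id = rep(samples, times = n_var), gt = gt
    ))
  })
}

# normalize a genotype table for equality comparison
norm_geno <- function(x) {
  x <- as.data.frame(x)[, c("chrom", "pos", "ref", "alt", "qual",
                            "sample_id", "gt")]
  x <- x[order(x$chrom, x$pos, x$alt, x$sample_id), ]
  rownames(x) <- NULL
  x
}

# per-variant brute-force evaluation of the three-condition predicate
brute_force_survivors <- function(calls, carriers, noncarriers, region,
                                  flank = 0, min_qual = 30) {
  rg <- parse_region(region)
  sites <- unique(as.data.frame(calls)[, c("chrom", "pos", "ref", "alt",
                                           "qual")])
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (!(s$chrom == rg$chrom && s$pos >= rg$start - flank &&
          s$pos <= rg$end + flank)) next
    if (!(s$qual > min_qual)) next
    sub <- calls[calls$chrom == s$chrom & calls$pos == s$pos &
                   calls$alt == s$alt, ]
    gt_of <- function(id) sub$gt[sub$sample_id == id]
    if (!all(vapply(carriers, gt_of, character(1)) == "het")) next
    if (!all(vapply(noncarriers, gt_of, character(1)) == "hom_ref")) next
    keep[i] <- TRUE
  }
  sites[keep, ]
}

# lower-tail Poisson probability by independent log-space term summation
poisson_tail_oracle <- function(observed, expected) {
  k <- 0:observed
  logs <- -expected + k * log(expected) - lgamma(k + 1)
  m <- max(logs)
  exp(m) * sum(exp(logs - m))
}

# two-sided Fisher p by full enumeration of the hypergeometric support
fisher_enum_oracle <- function(m) {
  r1 <- m[1, 1] + m[1, 2]
  r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact rank-sum two-sided p by explicit enumeration of all assignments
wilcoxon_enum_oracle <- function(a, b) {
  r <- rank(c(a, b))
  n_a <- length(a)
  idx <- utils::combn(length(r), n_a)
  sums <- apply(idx, 2, function(j) sum(r[j]))
  w <- sum(r[seq_len(n_a)])
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random multi-exon transcript model; CDS built from stop-free codons
random_model <- function(seed, strand = NULL) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    strand <- strand %||% sample(c("+", "-"), 1)
    n_res <- sample(20:60, 1)
    u <- sample(0:30, 1)
    utr3 <- sample(3:30, 1)
    sense <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    sense <- setdiff(sense, c("TAA", "TAG", "TGA"))
    codons <- sample(sense, n_res, replace = TRUE)
    codons[1] <- "ATG"
    seq <- paste0(paste(sample(bases, u, replace = TRUE), collapse = ""),
                  paste(codons, collapse = ""), "TAA",
                  paste(sample(bases, utr3, replace = TRUE), collapse = ""))
    tx_len <- nchar(seq)
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq_len(tx_len - 1), n_ex - 1))
    lens <- diff(c(0, cuts, tx_len))
    gaps <- sample(50:500, n_ex)
    starts <- ends <- integer(n_ex)
    if (strand == "+") {        # transcript order runs left to right
      gpos <- sample(1e4:2e4, 1)
      for (i in seq_len(n_ex)) {
        starts[i] <- gpos
        ends[i] <- gpos + lens[i] - 1
        gpos <- ends[i] + gaps[i]
      }
    } else {                    # transcript order runs right to left
      gpos <- sample(5e4:6e4, 1)
      for (i in seq_len(n_ex)) {
        ends[i] <- gpos
        starts[i] <- gpos - lens[i] + 1
        gpos <- starts[i] - gaps[i]
      }
    }
    transcript_model("TX_RAND", "chrT", strand,
                     tibble::tibble(start = starts, end = ends),
                     cds_start_tx = u + 1L, sequence = seq)
  })
}

# forward-strand base at a genomic position, read off the model itself
model_fwd_base <- function(model, gpos) {
  tx <- genomic_to_transcript(model, gpos)$tx_pos
  b <- substr(model$sequence, tx, tx)
  if (model$strand == "-") chartr("ACGT", "TGCA", b) else b
}

`%||%` <- rlang::`%||%`
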