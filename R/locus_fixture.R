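# Synthetic genotyping locus: a deterministic stand-in emulating the
# exon 10-16 neighbourhood of a collagen-gene splice-mutation screen. No
# real genomic sequence is used or retrieved; only the printed arithmetic
# (amplicon spans, exon length) is reproduced by construction.

# deterministic base generator that never touches the global RNG stream
.lcg_bases <- function(n, state = 20150729) {
  out <- character(n)
  for (i in seq_len(n)) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    out[i] <- c("A", "C", "G", "T")[state %% 4 + 1]
  }
  paste(out, collapse = "")
}

#' Synthetic splice-assay locus fixture
#'
#' Builds a fully synthetic gene model emulating the structure of a
#' col6a1-like exon 10-16 region around a 54 bp central exon ("exon 14"):
#' seven exons, GT..AG introns, a genotyping primer pair planted so the
#' genomic amplicon is 246 bp with the exon-14/intron-14 junction 136 bp
#' from the forward primer start, and an RT-PCR primer pair (exons 10 and
#' 16) planted so the spliced product is 298 bp with the intact exon 14 and
#' 244 bp without it. The sequence between the planted landmarks is
#' deterministic pseudo-random filler; primer uniqueness is asserted at
#' build time.
#'
#' @return list with `model` (`fq_gene_model`), `primers_genomic` and
#'   `primers_transcript` (lists with `forward`, `reverse`), `central_exon`
#'   (index of the 54 bp exon in the model) and `exon14_end` (its last
#'   genomic position).
#' @export
synthetic_splice_locus <- function() {
  gp_fwd <- "TGCCACCATGAAGAAGAGTG"        # genotyping, 20 nt
  gp_rev <- "TCAGATGTGAGTTGCTCAGAC"       # genotyping, 21 nt
  sp_fwd <- "GGTCCAGTCGGTTACCAAGG"        # RT-PCR, exon 10, 20 nt
  sp_rev <- "CAGATGGTCCGTAGTTTCCAGG"      # RT-PCR, exon 16, 22 nt

  exon_len <- c(e10 = 60, e11 = 40, e12 = 50, e13 = 60, e14 = 54,
                e15 = 50, e16 = 70)
  intron_len <- c(i10 = 80, i11 = 70, i12 = 75, i13 = 90, i14 = 120,
                  i15 = 80)
  filler <- function(n, salt) .lcg_bases(n, 20150729 + salt)
  intron_seq <- function(n, salt) {
    stopifnot(n >= 4)
    paste0("GT", filler(n - 4, salt), "AG")
  }
  # exon 10 ends with the RT-PCR forward primer (transcript offset 0)
  e10 <- paste0(filler(exon_len[1] - nchar(sp_fwd), 1), sp_fwd)
  e11 <- filler(exon_len[2], 2)
  e12 <- filler(exon_len[3], 3)
  e13 <- filler(exon_len[4], 6)
  # intron 13 carries the genotyping forward primer at positions 9-28: the
  # primer plus the 62 remaining intron nt plus the 54 bp exon place the
  # exon14/intron14 junction 20 + 62 + 54 = 136 nt from the primer 5' start
  i13 <- paste0("GT", filler(6, 4), gp_fwd,
                filler(intron_len[4] - 8 - nchar(gp_fwd) - 2, 5), "AG")
  e14 <- filler(exon_len[5], 7)
  # intron 14 carries the reverse-complemented genotyping reverse primer at
  # positions 90-110, so the amplicon ends 110 nt into the intron: total
  # amplicon 136 + 110 = 246 bp
  rc_gp_rev <- .revcomp(gp_rev)
  i14 <- paste0("GT", filler(87, 8), rc_gp_rev,
                filler(intron_len[5] - 89 - nchar(rc_gp_rev) - 2, 9), "AG")
  e15 <- filler(exon_len[6], 10)
  # exon 16 carries the reverse-complemented RT-PCR reverse primer ending
  # 24 nt into the exon: spliced amplicon 20 + 40 + 50 + 60 + 54 + 50 + 24
  # = 298 bp
  rc_sp_rev <- .revcomp(sp_rev)
  e16 <- paste0(filler(2, 11), rc_sp_rev,
                filler(exon_len[7] - 2 - nchar(rc_sp_rev), 12))
  pieces <- list(e10, intron_seq(intron_len[1], 13), e11,
                 intron_seq(intron_len[2], 14), e12,
                 intron_seq(intron_len[3], 15), e13, i13, e14, i14, e15,
                 intron_seq(intron_len[6], 16), e16)
  seq <- paste(unlist(pieces), collapse = "")
  lens <- nchar(unlist(pieces))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  exon_rows <- c(1L, 3L, 5L, 7L, 9L, 11L, 13L)
  exons <- data.frame(start = starts[exon_rows], end = ends[exon_rows])
  model <- gene_model("synthetic_col6a1like_locus", seq, exons,
                      exon_names = paste0("exon", 10:16))
  for (p in c(gp_fwd, .revcomp(gp_rev), sp_fwd)) .find_unique(seq, p, p)
  tx <- transcript_sequence(model)
  .find_unique(tx, sp_fwd, "transcript forward")
  .find_unique(tx, rc_sp_rev, "transcript reverse")
  list(model = model,
       primers_genomic = list(forward = gp_fwd, reverse = gp_rev),
       primers_transcript = list(forward = sp_fwd, reverse = sp_rev),
       central_exon = 5L, exon14_end = exons$end[5])
}

#' Synthetic mutation panel for the splice locus
#'
#' Six deletion footprints around the central exon's donor site, emulating
#' the footprint classes recovered in a TALEN splice-donor screen: five
#' overlap the first two intron nucleotides (two of those also truncate the
#' exon end) and one is a single-nucleotide exon-only deletion that leaves
#' the donor intact.
#'
#' @param locus result of [synthetic_splice_locus()].
#' @return named list of six `fq_mutation` objects (`M1`-`M6`).
#' @export
synthetic_mutation_panel <- function(locus = synthetic_splice_locus()) {
  E <- locus$exon14_end
  list(
    M1 = mutation("M1", "deletion", E + 1L, 2L),   # donor GT removed
    M2 = mutation("M2", "deletion", E - 2L, 6L),   # exon end + donor
    M3 = mutation("M3", "deletion", E + 1L, 4L),   # donor + 2 intron nt
    M4 = mutation("M4", "deletion", E - 3L, 1L),   # exon-only, frameshift
    M5 = mutation("M5", "deletion", E + 1L, 3L),   # donor + 1 intron nt
    M6 = mutation("M6", "deletion", E - 4L, 9L)    # exon end + donor
  )
}

#' Genotyping report for a mutation panel
#'
#' Runs donor classification and transcript-outcome prediction for each
#' mutation and tabulates the predicted wild-type and mutant RT-PCR product
#' sizes.
#'
#' @param locus result of [synthetic_splice_locus()].
#' @param muts list of `fq_mutation` (default: the synthetic panel).
#' @return data.frame
#'   `id,affects_donor,outcome,wt_product_bp,mut_product_bp`.
#' @export
genotype_report <- function(locus = synthetic_splice_locus(),
                            muts = synthetic_mutation_panel(locus)) {
  tx <- transcript_sequence(locus$model)
  wt_bp <- as.integer(amplicon_length(tx, locus$primers_transcript$forward,
                                      locus$primers_transcript$reverse))
  rows <- lapply(muts, function(m) {
    donor <- affects_splice_donor(m, locus$model, locus$central_exon)
    out <- predict_transcript_outcome(m, locus$model)
    mut_bp <- if (startsWith(out$outcome, "exon_skip"))
      skipped_product_length(wt_bp, out$skipped_exon_bp) else NA_integer_
    data.frame(id = m$id, affects_donor = donor, outcome = out$outcome,
               wt_product_bp = wt_bp, mut_product_bp = mut_bp)
  })
  do.call(rbind, rows)
}
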