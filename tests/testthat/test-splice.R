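test_that("gene model validates exon structure", {
  seqn <- strrep("ACGT", 30)
  expect_s3_class(gene_model("g", seqn, data.frame(start = c(1, 21),
                                                   end = c(10, 30))),
                  "fq_gene_model")
  expect_error(gene_model("g", seqn, data.frame(start = c(1, 12),
                                                end = c(10, 20))),
               "introns")
  expect_error(gene_model("g", seqn, data.frame(start = 1, end = 200)),
               "outside")
})

test_that("amplicon length: full span, deletion conservation, planted oracle", {
  set.seed(20)
  fwd <- random_dna(20)
  rev_p <- random_dna(20)
  mid <- random_dna(60)
  seqn <- paste0(fwd, mid, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_p))))
  expect_equal(as.numeric(amplicon_length(seqn, fwd, rev_p)), 100)

  del <- mutation("d", "deletion", 31, 10)
  expect_equal(as.numeric(amplicon_length(apply_mutation(seqn, del),
                                          fwd, rev_p)), 90)

  for (i in 1:30) {
    pre <- sample(0:40, 1)
    inner <- sample(10:80, 1)
    post <- sample(0:40, 1)
    s <- paste0(random_dna(pre), fwd, random_dna(inner),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(rev_p))), random_dna(post))
    got <- amplicon_length(s, fwd, rev_p)
    # brute-force: locate substrings and count the span
    f0 <- regexpr(fwd, s, fixed = TRUE)[1]
    r0 <- regexpr(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev_p))), s, fixed = TRUE)[1]
    expect_equal(as.numeric(got), r0 + 20 - f0)
  }
  expect_error(amplicon_length(seqn, "GGGGGGGGGGGGGGGGGGGG", rev_p),
               "not found")
})

test_that("exon-skip product arithmetic and frame rule", {
  expect_equal(skipped_product_length(298, 54), 244)
  expect_equal(skipped_product_length(100, 0), 100)
  expect_error(skipped_product_length(54, 54), "shorter")
  expect_true(is_in_frame_skip(54))
  expect_false(is_in_frame_skip(1))
  expect_equal(vapply(0:300, is_in_frame_skip, TRUE), (0:300) %% 3 == 0)
})

test_that("skipped product equals the amplicon on the exon-deleted transcript", {
  set.seed(25)
  for (i in 1:10) {
    lens <- sample(seq(30, 90, by = 3), 5)
    introns <- sample(20:50, 4)
    pieces <- character(0)
    starts <- integer(0); ends <- integer(0)
    pos <- 0L
    for (k in 1:5) {
      pieces <- c(pieces, random_dna(lens[k]))
      starts <- c(starts, pos + 1L)
      ends <- c(ends, pos + lens[k])
      pos <- pos + lens[k]
      if (k < 5) {
        pieces <- c(pieces, paste0("GT", random_dna(introns[k] - 4), "AG"))
        pos <- pos + introns[k]
      }
    }
    gm <- gene_model("rand", paste(pieces, collapse = ""),
                     data.frame(start = starts, end = ends))
    fwd <- substr(transcript_sequence(gm), 1, 18)
    tx <- transcript_sequence(gm)
    rev_p <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(tx, nchar(tx) - 17, nchar(tx)))))
    wt <- amplicon_length(tx, fwd, rev_p)
    sk <- amplicon_length(transcript_sequence(gm, skip_exon = 3), fwd, rev_p)
    expect_equal(as.numeric(sk),
                 skipped_product_length(as.numeric(wt), lens[3]))
  }
})

test_that("T7EI fragments always partition the amplicon", {
  expect_equal(unname(t7ei_fragments(246, 136)), c(136, 110))
  expect_equal(unname(t7ei_fragments(200, 100)), c(100, 100))
  set.seed(26)
  for (i in 1:50) {
    amp <- sample(50:500, 1)
    cut <- sample(seq_len(amp - 1), 1)
    fr <- t7ei_fragments(amp, cut)
    expect_equal(sum(fr), amp)
    expect_true(all(fr > 0))
  }
  expect_error(t7ei_fragments(246, 0), "strictly inside")
  expect_error(t7ei_fragments(246, 246), "strictly inside")
})

test_that("heteroduplex cut helper places the cut at the indel midpoint", {
  m <- mutation("m", "deletion", 150, 4)
  expect_equal(t7ei_cut_site(m, 15), 150 + 2 - 15 + 1)
  expect_error(t7ei_cut_site(m, 200), "before the amplicon")
})

test_that("indel calling: identity, planted deletion, and the F0/F1 filter", {
  set.seed(27)
  ref <- random_dna(246)
  expect_length(call_indels(ref, ref, mode = "F1"), 0)

  del8 <- mutation("d", "deletion", 100, 8)
  got <- call_indels(ref, apply_mutation(ref, del8), mode = "F0")
  expect_length(got, 1)
  expect_equal(got[[1]]$kind, "deletion")
  expect_equal(got[[1]]$length, 8)
  expect_equal(got[[1]]$position,
               oracle_leftmost_deletion(ref, apply_mutation(ref, del8), 8))

  del1 <- mutation("d1", "deletion", 120, 1)
  read1 <- apply_mutation(ref, del1)
  expect_length(call_indels(ref, read1, mode = "F0"), 0)
  f1 <- call_indels(ref, read1, mode = "F1")
  expect_length(f1, 1)
  expect_equal(f1[[1]]$length, 1)
})

test_that("indel calling recovers planted indels with left-aligned positions", {
  set.seed(28)
  for (i in 1:40) {
    ref <- random_dna(sample(200:300, 1))
    len <- sample(1:20, 1)
    if (sample(c(TRUE, FALSE), 1)) {
      pos <- sample(20:(nchar(ref) - len - 25), 1)
      m <- mutation("p", "deletion", pos, len)
      read <- apply_mutation(ref, m)
      got <- call_indels(ref, read, min_indel_bp = 1)
      expect_length(got, 1)
      expect_equal(got[[1]]$kind, "deletion")
      expect_equal(got[[1]]$length, len)
      expect_equal(got[[1]]$position, oracle_leftmost_deletion(ref, read, len))
    } else {
      pos <- sample(20:(nchar(ref) - 25), 1)
      m <- mutation("p", "insertion", pos, len,
                    inserted_sequence = random_dna(len))
      read <- apply_mutation(ref, m)
      got <- call_indels(ref, read, min_indel_bp = 1)
      expect_length(got, 1)
      expect_equal(got[[1]]$kind, "insertion")
      expect_equal(got[[1]]$length, len)
      expect_equal(got[[1]]$position,
                   oracle_leftmost_insertion(ref, read, len))
    }
  }
})

test_that("indel positions are normalized to the leftmost placement in repeats", {
  flank <- "ACGTC"
  ref <- paste0(flank, strrep("A", 10), "GTCCA", strrep("CT", 6), "GACGT")
  # delete 2 A's from the middle of the homopolymer: leftmost is position 6
  read <- paste0(flank, strrep("A", 8), "GTCCA", strrep("CT", 6), "GACGT")
  got <- call_indels(ref, read, min_indel_bp = 1)
  expect_length(got, 1)
  expect_equal(got[[1]]$position, 6)
  # delete one CT unit: leftmost placement of the 2 nt event
  read2 <- paste0(flank, strrep("A", 10), "GTCCA", strrep("CT", 5), "GACGT")
  got2 <- call_indels(ref, read2, min_indel_bp = 1)
  expect_length(got2, 1)
  expect_equal(got2[[1]]$length, 2)
  expect_equal(got2[[1]]$position,
               oracle_leftmost_deletion(ref, read2, 2))
})

test_that("splice-donor classification follows the first-two-intron-nt rule", {
  loc <- synthetic_splice_locus()
  E <- loc$exon14_end
  # deletion exactly covering intron +1..+2
  expect_true(affects_splice_donor(mutation("x", "deletion", E + 1, 2),
                                   loc$model, loc$central_exon))
  # deletion strictly inside the exon, ending 2 nt before the junction
  expect_false(affects_splice_donor(mutation("x", "deletion", E - 4, 3),
                                    loc$model, loc$central_exon))
  # deletion starting at intron +3 misses the donor
  expect_false(affects_splice_donor(mutation("x", "deletion", E + 3, 5),
                                    loc$model, loc$central_exon))
  # insertion splitting the GT disrupts; insertion after it does not
  expect_true(affects_splice_donor(
    mutation("x", "insertion", E + 1, 2, "AA"), loc$model, loc$central_exon))
  expect_false(affects_splice_donor(
    mutation("x", "insertion", E + 2, 2, "AA"), loc$model, loc$central_exon))
  # widened donor window catches deeper intronic edits
  expect_true(affects_splice_donor(mutation("x", "deletion", E + 3, 2),
                                   loc$model, loc$central_exon, window = 6))
  expect_error(affects_splice_donor(mutation("x", "deletion", E + 1, 2),
                                    loc$model, nrow(loc$model$exons)),
               "no downstream intron")
})

test_that("the synthetic mutation panel classifies 5 donor hits and 1 exonic", {
  loc <- synthetic_splice_locus()
  muts <- synthetic_mutation_panel(loc)
  hits <- vapply(muts, affects_splice_donor, TRUE, model = loc$model,
                 exon_index = loc$central_exon)
  expect_equal(sum(hits), 5)
  expect_false(hits[["M4"]])
  rep <- genotype_report(loc, muts)
  expect_equal(rep$outcome[rep$id == "M4"], "coding_frameshift")
  expect_true(all(rep$outcome[rep$id != "M4"] == "exon_skip_in_frame"))
  expect_equal(unique(rep$wt_product_bp), 298)
  expect_equal(unique(rep$mut_product_bp[rep$id != "M4"]), 244)
})

test_that("transcript outcome cascade covers every branch", {
  loc <- synthetic_splice_locus()
  E <- loc$exon14_end
  donor_del <- predict_transcript_outcome(
    mutation("x", "deletion", E + 1, 4), loc$model)
  expect_equal(donor_del$outcome, "exon_skip_in_frame")
  expect_equal(donor_del$skipped_exon_bp, 54)
  expect_match(donor_del$caveat, "prediction")

  expect_equal(predict_transcript_outcome(
    mutation("x", "deletion", E - 3, 1), loc$model)$outcome,
    "coding_frameshift")
  expect_equal(predict_transcript_outcome(
    mutation("x", "deletion", E - 10, 3), loc$model)$outcome,
    "coding_in_frame_del")
  # deep intronic, outside the donor window
  expect_equal(predict_transcript_outcome(
    mutation("x", "deletion", E + 30, 4), loc$model)$outcome,
    "no_effect_predicted")
  expect_error(predict_transcript_outcome(
    mutation("x", "deletion", nchar(loc$model$sequence) + 10, 2), loc$model),
    "outside")
})

test_that("coordinate convention helpers invert each other", {
  z <- as_zero_based(10, 20)
  expect_equal(unname(z), c(9, 20))
  expect_equal(unname(do.call(as_one_based, as.list(z))), c(10, 20))
})
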