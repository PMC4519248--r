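#' Gene model with reference sequence
#'
#' Minimal exon/intron representation: a reference nucleotide sequence plus
#' ordered, non-overlapping exon coordinates (1-based, inclusive — the
#' convention biologists annotate loci in; see [as_zero_based()] for
#' conversion). Every intron must be at least 2 nt long so it can carry a
#' splice donor dinucleotide.
#'
#' @param name locus name.
#' @param sequence reference nucleotide string (A/C/G/T).
#' @param exons data.frame or matrix with columns `start`, `end` (1-based
#'   inclusive), one row per exon, in transcription order.
#' @param strand `"+"` or `"-"` (coordinates are always on the given
#'   sequence; `"-"` is informational).
#' @param exon_names optional labels (e.g. exon numbers within the full
#'   gene).
#' @return `fq_gene_model`.
#' @export
gene_model <- function(name, sequence, exons, strand = "+",
                       exon_names = NULL) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must be A/C/G/T")
  ex <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(ex)))
    stop("exons need start and end columns")
  ex <- ex[c("start", "end")]
  n <- nrow(ex)
  if (n < 1) stop("at least one exon required")
  if (any(ex$start > ex$end)) stop("exon start > end")
  if (any(ex$start < 1) || any(ex$end > nchar(sequence)))
    stop("exon coordinates outside the reference sequence")
  if (n > 1) {
    gaps <- ex$start[-1] - ex$end[-n] - 1L
    if (any(gaps < 2)) stop("exons must be ordered with introns >= 2 nt")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  ex$name <- if (is.null(exon_names)) paste0("exon", seq_len(n)) else
    as.character(exon_names)
  structure(list(name = name, sequence = sequence, exons = ex,
                 strand = strand),
            class = "fq_gene_model")
}

#' @export
print.fq_gene_model <- function(x, ...) {
  cat(sprintf("<fq_gene_model> %s (%s): %d nt, %d exons (%s)\n",
              x$name, x$strand, nchar(x$sequence), nrow(x$exons),
              paste(x$exons$end - x$exons$start + 1, collapse = "/")))
  invisible(x)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' @param start,end 1-based inclusive range (for `as_zero_based`) or 0-based
#'   half-open range (for `as_one_based`).
#' @return named vector `c(start, end)` in the other convention.
#' @export
as_zero_based <- function(start, end) c(start = start - 1L, end = end)

#' @rdname as_zero_based
#' @export
as_one_based <- function(start, end) c(start = start + 1L, end = end)

#' Describe an indel mutation
#'
#' @param id mutation label.
#' @param kind `"deletion"` or `"insertion"`.
#' @param position 1-based start of the deleted run, or the reference
#'   position immediately *before* the inserted bases.
#' @param length number of deleted or inserted nucleotides.
#' @param inserted_sequence the inserted bases (insertions only).
#' @return `fq_mutation`.
#' @export
mutation <- function(id, kind = c("deletion", "insertion"), position,
                     length, inserted_sequence = NULL) {
  kind <- match.arg(kind)
  stopifnot(position >= ifelse(kind == "insertion", 0, 1), length >= 1)
  if (kind == "insertion") {
    if (is.null(inserted_sequence) ||
        nchar(inserted_sequence) != length)
      stop("insertion needs inserted_sequence of the stated length")
    inserted_sequence <- toupper(inserted_sequence)
  }
  structure(list(id = id, kind = kind, position = as.integer(position),
                 length = as.integer(length),
                 inserted_sequence = inserted_sequence),
            class = "fq_mutation")
}

#' @export
print.fq_mutation <- function(x, ...) {
  cat(sprintf("<fq_mutation> %s: %s of %d nt at %d%s\n", x$id, x$kind,
              x$length, x$position,
              if (x$kind == "insertion") paste0(" (+", x$inserted_sequence, ")")
              else ""))
  invisible(x)
}

#' Apply a mutation to a reference sequence
#'
#' @param sequence reference nucleotide string.
#' @param mut `fq_mutation`.
#' @return mutated sequence string.
#' @export
apply_mutation <- function(sequence, mut) {
  stopifnot(inherits(mut, "fq_mutation"))
  n <- nchar(sequence)
  if (mut$kind == "deletion") {
    if (mut$position + mut$length - 1L > n)
      stop("deletion extends past the end of the sequence")
    paste0(substr(sequence, 1, mut$position - 1L),
           substr(sequence, mut$position + mut$length, n))
  } else {
    if (mut$position > n) stop("insertion position outside the sequence")
    paste0(substr(sequence, 1, mut$position), mut$inserted_sequence,
           substr(sequence, mut$position + 1L, n))
  }
}

.find_unique <- function(seq, pattern, what) {
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) stop(what, " primer not found in the sequence")
  if (length(hits) > 1L) stop(what, " primer maps ", length(hits), " times")
  as.integer(hits[1])
}

.revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

#' PCR amplicon length
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the template (each must match exactly once) and returns the
#' span from the forward primer's 5' start through the reverse primer's 5'
#' start, inclusive — the length of the amplified product.
#'
#' @param seq template nucleotide string (genomic or cDNA).
#' @param forward,reverse primer sequences, 5' to 3'.
#' @return amplicon length in bp, with attribute `range` (1-based start and
#'   end on the template).
#' @export
amplicon_length <- function(seq, forward, reverse) {
  seq <- toupper(seq)
  fs <- .find_unique(seq, toupper(forward), "forward")
  rc <- .revcomp(toupper(reverse))
  rs <- .find_unique(seq, rc, "reverse")
  re <- rs + nchar(rc) - 1L     # plus-strand position of the reverse 5' end
  if (re <= fs) stop("primers do not face each other on this template")
  out <- re - fs + 1L
  attr(out, "range") <- c(start = fs, end = re)
  out
}

#' Spliced transcript sequence from a gene model
#'
#' Concatenates the exon sequences, optionally skipping one exon — the
#' in-silico equivalent of an exon-skipping splice outcome.
#'
#' @param model `fq_gene_model`.
#' @param skip_exon optional index (in `model$exons`) of an exon to omit.
#' @return nucleotide string.
#' @export
transcript_sequence <- function(model, skip_exon = NULL) {
  stopifnot(inherits(model, "fq_gene_model"))
  idx <- seq_len(nrow(model$exons))
  if (!is.null(skip_exon)) {
    stopifnot(skip_exon %in% idx)
    idx <- setdiff(idx, skip_exon)
  }
  paste(substring(model$sequence, model$exons$start[idx],
                  model$exons$end[idx]), collapse = "")
}

#' Exon-skipped RT-PCR product size
#'
#' @param wt_product_bp RT-PCR product length from the intact transcript.
#' @param exon_length_bp length of the skipped exon.
#' @return `wt_product_bp - exon_length_bp`.
#' @export
skipped_product_length <- function(wt_product_bp, exon_length_bp) {
  stopifnot(exon_length_bp >= 0)
  if (exon_length_bp >= wt_product_bp)
    stop("skipped exon must be shorter than the wild-type product")
  wt_product_bp - exon_length_bp
}

#' Is an exon skip in frame?
#'
#' Skipping an exon preserves the downstream reading frame exactly when the
#' exon length is a multiple of 3.
#'
#' @param exon_length_bp non-negative exon length.
#' @return logical.
#' @export
is_in_frame_skip <- function(exon_length_bp) {
  stopifnot(exon_length_bp >= 0, exon_length_bp == round(exon_length_bp))
  exon_length_bp %% 3 == 0
}

#' T7 endonuclease I cleavage fragments
#'
#' T7EI cuts a re-annealed heteroduplex at the mismatch bubble, converting
#' one amplicon into two diagnostic fragments whose lengths always sum to
#' the amplicon length.
#'
#' @param amplicon_bp amplicon length.
#' @param cut_position_bp cut offset from the amplicon's 5' end, strictly
#'   inside the amplicon.
#' @return numeric vector `c(fragment1, fragment2)`.
#' @export
t7ei_fragments <- function(amplicon_bp, cut_position_bp) {
  if (cut_position_bp <= 0 || cut_position_bp >= amplicon_bp)
    stop("cut position must lie strictly inside the amplicon")
  c(fragment1 = cut_position_bp, fragment2 = amplicon_bp - cut_position_bp)
}

#' Heteroduplex cut position implied by an indel
#'
#' T7EI cleaves near the mismatch bubble an indel forms in a WT/mutant
#' heteroduplex; this helper places the cut at the indel's midpoint,
#' expressed as an offset from the amplicon's 5' (forward primer) start.
#'
#' @param mut `fq_mutation` in reference coordinates.
#' @param amplicon_start 1-based reference position of the forward primer's
#'   5' end.
#' @return cut offset in bp.
#' @export
t7ei_cut_site <- function(mut, amplicon_start) {
  stopifnot(inherits(mut, "fq_mutation"))
  mid <- mut$position + floor(mut$length / 2)
  off <- mid - amplicon_start + 1L
  if (off <= 0) stop("indel lies before the amplicon start")
  off
}

# ---- indel calling -------------------------------------------------------

# left-align one event against the reference (VCF-style normalization)
.left_align <- function(ref_chars, kind, pos, len, ins = NULL) {
  if (kind == "deletion") {
    while (pos > 1L && ref_chars[pos - 1L] == ref_chars[pos + len - 1L])
      pos <- pos - 1L
    list(position = pos, inserted = NULL)
  } else {
    ins <- strsplit(ins, "")[[1]]
    while (pos >= 1L && ref_chars[pos] == ins[length(ins)]) {
      ins <- c(ins[length(ins)], ins[-length(ins)])
      pos <- pos - 1L
    }
    list(position = pos, inserted = paste(ins, collapse = ""))
  }
}

#' Call indels from a read against a reference
#'
#' Globally aligns the read to the reference (affine gap penalties, via
#' Biostrings), extracts contiguous gap runs as deletion/insertion events,
#' merges same-kind runs separated by fewer than 3 aligned matching
#' nucleotides into one event (reporting the summed length from the first
#' run's position — the footprint of a single repair event), left-aligns
#' each event to its leftmost equivalent placement, and filters events
#' shorter than the minimum length.
#'
#' The minimum defaults by screening mode: mosaic F0 material uses
#' `>= 2 bp` (single-base events are indistinguishable from amplification
#' errors there), while non-mosaic F1 material is sequenced directly and
#' keeps single-base events.
#'
#' @param reference,read non-empty nucleotide strings.
#' @param min_indel_bp override of the minimum reported event length.
#' @param mode `"F0"` (minimum 2 bp) or `"F1"` (minimum 1 bp); ignored when
#'   `min_indel_bp` is given.
#' @return list of `fq_mutation` (possibly empty), positions 1-based on the
#'   reference, left-aligned.
#' @export
call_indels <- function(reference, read, min_indel_bp = NULL,
                        mode = c("F0", "F1")) {
  mode <- match.arg(mode)
  if (is.null(min_indel_bp)) min_indel_bp <- if (mode == "F0") 2L else 1L
  reference <- toupper(reference); read <- toupper(read)
  if (!nchar(reference) || !nchar(read)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read),
    subject = Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 1)
  pc <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  if (length(pc) != length(sc)) stop("alignment failure")
  ref_pos <- cumsum(sc != "-")           # reference coordinate per column
  gap_p <- pc == "-"                     # deletion columns
  gap_s <- sc == "-"                     # insertion columns
  events <- list()
  add_runs <- function(mask, kind) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      col0 <- starts[k]
      len <- r$lengths[k]
      if (kind == "deletion") {
        events[[length(events) + 1L]] <<- list(
          kind = kind, col = col0, len = len, pos = ref_pos[col0],
          ins = NULL)
      } else {
        events[[length(events) + 1L]] <<- list(
          kind = kind, col = col0, len = len,
          pos = if (col0 == 1L) 0L else ref_pos[col0 - 1L],
          ins = paste(pc[col0:(col0 + len - 1L)], collapse = ""))
      }
    }
  }
  add_runs(gap_p, "deletion")
  add_runs(gap_s, "insertion")
  if (!length(events)) return(list())
  events <- events[order(vapply(events, `[[`, 0, "col"))]
  # merge same-kind runs separated by < 3 aligned non-gap columns
  merged <- list(events[[1]])
  for (ev in events[-1]) {
    last <- merged[[length(merged)]]
    spacer <- ev$col - (last$col + last$len)
    if (ev$kind == last$kind && spacer < 3) {
      last$len <- last$len + ev$len
      if (ev$kind == "insertion") last$ins <- paste0(last$ins, ev$ins)
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- ev
    }
  }
  ref_chars <- strsplit(reference, "")[[1]]
  out <- list()
  for (ev in merged) {
    if (ev$len < min_indel_bp) next
    la <- .left_align(ref_chars, ev$kind, ev$pos, ev$len, ev$ins)
    out[[length(out) + 1L]] <- mutation(
      id = sprintf("%s_%d", substr(ev$kind, 1, 3), la$position),
      kind = ev$kind, position = la$position,
      length = ev$len, inserted_sequence = la$inserted)
  }
  out
}

#' Does a mutation disrupt the splice donor site?
#'
#' The operative rule: any mutation touching one of the first `window`
#' nucleotides of the intron downstream of an exon (canonically the GT
#' dinucleotide, `window = 2`) is predicted to cause skipping of that exon.
#' A deletion disrupts the donor when its footprint intersects the window;
#' an insertion when it lands inside the window (splitting the donor).
#'
#' @param mut `fq_mutation` in reference coordinates.
#' @param model `fq_gene_model`.
#' @param exon_index index of the exon whose downstream donor is examined.
#' @param window donor width in nt (default 2; widen to examine a larger
#'   donor consensus).
#' @return logical.
#' @export
affects_splice_donor <- function(mut, model, exon_index, window = 2) {
  stopifnot(inherits(mut, "fq_mutation"), inherits(model, "fq_gene_model"))
  n <- nrow(model$exons)
  if (exon_index < 1 || exon_index >= n)
    stop("exon ", exon_index, " has no downstream intron donor")
  d0 <- model$exons$end[exon_index] + 1L        # intron position +1
  d1 <- d0 + window - 1L
  if (mut$kind == "deletion") {
    mut$position <= d1 && (mut$position + mut$length - 1L) >= d0
  } else {
    # inserted between position and position+1: inside the window iff the
    # junction it splits lies strictly within [d0, d1]
    mut$position >= d0 && mut$position < d1
  }
}

#' Predict the transcript outcome of a mutation
#'
#' Rule cascade: a donor-disrupting mutation (see [affects_splice_donor()])
#' predicts skipping of the preceding exon, in frame iff the exon length is
#' a multiple of 3; an indel overlapping an exon predicts a coding
#' frameshift unless its length is a multiple of 3; anything else (deep
#' intronic) predicts no effect. Splicing outcomes are heuristic
#' predictions, not certainties: a donor mutation can instead yield an
#' unstable transcript that is degraded (e.g. by nonsense-mediated decay)
#' and never observed — the returned `caveat` says so and is never silently
#' dropped.
#'
#' @param mut `fq_mutation`.
#' @param model `fq_gene_model`.
#' @param donor_window donor width passed to [affects_splice_donor()].
#' @return list `outcome` (one of `no_effect_predicted`,
#'   `exon_skip_in_frame`, `exon_skip_frameshift`, `coding_frameshift`,
#'   `coding_in_frame_del`), `skipped_exon` (index or `NA`),
#'   `skipped_exon_bp`, `caveat`.
#' @export
predict_transcript_outcome <- function(mut, model, donor_window = 2) {
  stopifnot(inherits(mut, "fq_mutation"), inherits(model, "fq_gene_model"))
  nref <- nchar(model$sequence)
  foot <- if (mut$kind == "deletion")
    c(mut$position, mut$position + mut$length - 1L)
  else c(mut$position, mut$position + 1L)
  if (foot[1] < 1L && mut$kind == "deletion" || foot[2] > nref + 1L ||
      mut$position > nref)
    stop("mutation lies outside the modeled region")
  caveat <- paste("splicing outcomes are predictions from the donor-site",
                  "rule; transcript fate (e.g. nonsense-mediated decay)",
                  "must be confirmed by RT-PCR")
  for (i in seq_len(nrow(model$exons) - 1L)) {
    if (affects_splice_donor(mut, model, i, donor_window)) {
      ebp <- model$exons$end[i] - model$exons$start[i] + 1L
      out <- if (is_in_frame_skip(ebp)) "exon_skip_in_frame" else
        "exon_skip_frameshift"
      return(list(outcome = out, skipped_exon = i, skipped_exon_bp = ebp,
                  caveat = caveat))
    }
  }
  exonic <- any(foot[1] <= model$exons$end & foot[2] >= model$exons$start)
  if (exonic) {
    out <- if (mut$length %% 3 == 0) "coding_in_frame_del" else
      "coding_frameshift"
    return(list(outcome = out, skipped_exon = NA_integer_,
                skipped_exon_bp = NA_integer_, caveat = caveat))
  }
  list(outcome = "no_effect_predicted", skipped_exon = NA_integer_,
       skipped_exon_bp = NA_integer_, caveat = caveat)
}
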