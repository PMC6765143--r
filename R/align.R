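#' Alignment scoring and acceptance parameters
#'
#' BLASTN-style scoring defaults: reward +2, penalty -3, gap open 5, gap
#' extend 2 (a k-base gap costs `gap_open + k * gap_extend`). The acceptance
#' thresholds (`min_score`, `min_identity`, `min_length`) decide which local
#' alignments count as homology hits in [cross_compare()] and
#' [extend_orthologs()]; raw-score acceptance is used rather than E-values.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open,gap_extend Non-negative gap costs.
#' @param min_score Minimum alignment score for a passing hit.
#' @param min_identity Minimum identity fraction over aligned columns
#'   (gap columns count).
#' @param min_length Minimum aligned length (columns).
#' @param max_len Size cap on input sequences (nt); this is a TR-scale
#'   aligner, not a genome aligner.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -3L,
                             gap_open = 5L, gap_extend = 2L,
                             min_score = 40L, min_identity = 0.70,
                             min_length = 40L, max_len = 100000L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_identity > 0, min_identity <= 1, min_length >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score),
                 min_identity = min_identity,
                 min_length = as.integer(min_length),
                 max_len = as.integer(max_len)),
            class = "alignment_params")
}

# plus-strand score-only batch; a, b recycled pairwise
.sw_scores <- function(a, b, params) {
  .sw_score_many(a, b, params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps, searched over both
#' strands of the subject (the better-scoring strand is reported; plus wins
#' ties). Traceback ties are resolved diagonal > up > left. Coordinates are
#' 0-based half-open on the original (plus-strand) sequences.
#'
#' @param a Query DNA string.
#' @param b Subject DNA string.
#' @param params An [alignment_params()] object.
#' @return Object of class `local_alignment`: `score`, `query_interval` and
#'   `subject_interval` (integer length-2, 0-based half-open), `strand`
#'   ("+"/"-"), `length` (aligned columns), `matches`, `identity`,
#'   `query_aln`/`subject_aln` (gapped alignment strings, subject in aligned
#'   orientation).
#' @examples
#' aln <- local_align("GACG", "GACG", alignment_params())
#' aln$score    # 8
#' aln$identity # 1
#' @export
local_align <- function(a, b, params = alignment_params()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  if (nchar(a) > params$max_len || nchar(b) > params$max_len)
    stop("sequence exceeds the aligner size cap (", params$max_len,
         " nt); this is a TR-scale aligner", call. = FALSE)
  plus <- .sw_align(a, b, params$match, params$mismatch,
                    params$gap_open, params$gap_extend)
  brc <- reverse_complement(b)
  minus <- .sw_align(a, brc, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
  if (minus$score > plus$score) {
    hit <- minus
    nb <- nchar(b)
    s_int <- c(nb - hit$s_end, nb - hit$s_start)
    strand <- "-"
  } else {
    hit <- plus
    s_int <- c(hit$s_start, hit$s_end)
    strand <- "+"
  }
  structure(list(
    score = hit$score,
    query_interval = c(hit$q_start, hit$q_end),
    subject_interval = as.integer(s_int),
    strand = strand,
    length = hit$columns,
    matches = hit$matches,
    identity = if (hit$columns > 0L) hit$matches / hit$columns else 0,
    query_aln = hit$q_aln,
    subject_aln = hit$s_aln), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("Local alignment: score ", x$score, ", strand ", x$strand,
      ", identity ", sprintf("%.1f%%", 100 * x$identity),
      " over ", x$length, " columns\n", sep = "")
  cat("  query   [", x$query_interval[1], ", ", x$query_interval[2], ")  ",
      x$query_aln, "\n", sep = "")
  cat("  subject [", x$subject_interval[1], ", ", x$subject_interval[2], ")  ",
      x$subject_aln, "\n", sep = "")
  invisible(x)
}

# does an alignment pass the acceptance thresholds?
.passes <- function(aln, params) {
  aln$score >= params$min_score &&
    aln$identity >= params$min_identity &&
    aln$length >= params$min_length
}
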