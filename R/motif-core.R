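#' @useDynLib teloseeker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# -- internal sequence helpers -------------------------------------------------

.check_alphabet <- function(seq, allowed = c("A", "C", "G", "T"), what = "sequence") {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L)
    stop(what, " contains non-nucleotide characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(seq)
}

.rotations <- function(unit) {
  n <- nchar(unit)
  d <- paste0(unit, unit)
  substring(d, seq_len(n), seq_len(n) + n - 1L)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. `N` maps to `N`.
#'
#' @param seq A DNA string over `{A,C,G,T,N}` (upper case).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("TTAGGG") # "CCCTAA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  .check_alphabet(seq, c("A", "C", "G", "T", "N"))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Smallest period of a string
#'
#' The smallest `p >= 1` with `seq[i] == seq[i + p]` for every valid `i`
#' (self-overlap periodicity); equals `nchar(seq)` when no shorter period
#' exists.
#'
#' @param seq Non-empty string.
#' @return Integer period.
#' @examples
#' minimal_period("CTAAACCCT")          # 7
#' minimal_period("AACCGAGCCCATAACCGA") # 12
#' @export
minimal_period <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence has no period", call. = FALSE)
  for (p in seq_len(n - 1L)) {
    if (substr(seq, 1L, n - p) == substr(seq, p + 1L, n)) return(p)
  }
  n
}

#' Lexicographically minimal rotation of a repeat unit
#'
#' Rotation-invariant canonical spelling used for motif identity and
#' comparison: all rotations of the same circular unit map to the same string.
#'
#' @param unit Non-empty ACGT string.
#' @return The minimal rotation.
#' @examples
#' canonical_rotation("TTAGGG") # "AGGGTT"
#' @export
canonical_rotation <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  if (nchar(unit) == 0L) stop("cannot rotate an empty unit", call. = FALSE)
  .check_alphabet(unit)
  min(.rotations(unit))
}

#' Display rotation of a telomere repeat unit
#'
#' The human-facing spelling convention for telomere motifs: start the unit
#' immediately 3' of the longest circular run of G, so that the G-tract ends
#' the spelling (TTAGGG, TTTAGGG, CTCGGTTATGGG, ...). Ties between equally
#' long G-runs are broken by taking the lexicographically smallest candidate
#' rotation. Units without any G fall back to [canonical_rotation()].
#'
#' @param unit Non-empty ACGT string.
#' @return A rotation of `unit`.
#' @examples
#' display_rotation("GGTTTAG")      # "TTTAGGG"
#' display_rotation("ATGGGCTCGGTT") # "CTCGGTTATGGG"
#' @export
display_rotation <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  n <- nchar(unit)
  if (n == 0L) stop("cannot rotate an empty unit", call. = FALSE)
  .check_alphabet(unit)
  chars <- strsplit(paste0(unit, unit), "", fixed = TRUE)[[1]]
  is_g <- chars == "G"
  if (!any(is_g[seq_len(n)])) return(canonical_rotation(unit))
  # maximal G-runs in the doubled string; candidate runs start in the first copy
  r <- rle(is_g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g_idx <- which(r$values)
  run_start <- starts[g_idx]
  run_len <- pmin(r$lengths[g_idx], n)  # a circular run cannot exceed the unit
  keep <- run_start <= n
  run_start <- run_start[keep]
  run_len <- run_len[keep]
  best <- run_len == max(run_len)
  cand_start <- ((run_start[best] - 1L + run_len[best]) %% n) + 1L
  cand <- vapply(cand_start,
                 function(s) substr(paste0(unit, unit), s, s + n - 1L),
                 character(1))
  min(cand)
}

# a unit is primitive iff it is not a power of a shorter word,
# i.e. all rotations are distinct
.is_primitive <- function(unit) {
  length(unique(.rotations(unit))) == nchar(unit)
}

# strong condition for unambiguous template windows: every window of length
# L+1 of the circular repeat has smallest period exactly L (longer windows
# inherit this, since a weak period restricts to prefixes).  Near-homopolymer
# units like AAAAC are primitive yet fail this: some of their windows carry a
# genuinely shorter period, so no method could recover the unit from them.
.is_circularly_primitive <- function(unit) {
  n <- nchar(unit)
  if (!.is_primitive(unit)) return(FALSE)
  d <- strrep(unit, 2L)
  wins <- substring(d, seq_len(n), seq_len(n) + n)
  all(vapply(wins, minimal_period, integer(1)) == n)
}

#' Construct a telomere repeat motif
#'
#' A telomere motif is a primitive circular DNA repeat unit, stored in
#' G-strand convention (5'->3' on the guanine-rich strand synthesized by
#' telomerase). Identity is rotation-invariant via the canonical form; the
#' display form follows the field's G-tract-last spelling.
#'
#' The unit must be primitive: not a power of a shorter word (homopolymers,
#' `TATA`-like doubled dinucleotides and the like are rejected). A
#' non-primitive unit would make permutation sets and template spans
#' ambiguous. Primitivity is rotation-invariant, so every rotation of a
#' valid unit is itself a valid spelling of the same motif.
#'
#' @param g_strand_unit ACGT string, the repeat unit on the G-rich strand.
#' @return An object of class `telomere_motif` with fields `g_strand_unit`,
#'   `length`, `canonical_form`, `display_form`.
#' @examples
#' telomere_motif("TTTAGGG")
#' telomere_motif("CTCGGTTATGGG")
#' @export
telomere_motif <- function(g_strand_unit) {
  if (inherits(g_strand_unit, "telomere_motif")) return(g_strand_unit)
  stopifnot(is.character(g_strand_unit), length(g_strand_unit) == 1L)
  g_strand_unit <- toupper(g_strand_unit)
  if (nchar(g_strand_unit) < 1L) stop("motif unit must be non-empty", call. = FALSE)
  .check_alphabet(g_strand_unit, what = "motif unit")
  if (!.is_primitive(g_strand_unit))
    stop("motif unit is not primitive (it is a power of a shorter unit)",
         call. = FALSE)
  structure(
    list(g_strand_unit = g_strand_unit,
         length = nchar(g_strand_unit),
         canonical_form = canonical_rotation(g_strand_unit),
         display_form = display_rotation(g_strand_unit)),
    class = "telomere_motif")
}

#' @export
print.telomere_motif <- function(x, ...) {
  cat("Telomere motif (", x$length, " bp): (", x$display_form, ")n\n", sep = "")
  cat("  canonical form: ", x$canonical_form, "\n", sep = "")
  cat("  C-strand unit:  ", c_strand_unit(x), "\n", sep = "")
  invisible(x)
}

#' C-strand repeat unit of a telomere motif
#'
#' Reverse complement of the G-strand unit: one rotation of the repeat unit
#' on the template (C-rich) strand, the strand a TR template region copies.
#'
#' @param motif A [telomere_motif()] (or a unit string, coerced).
#' @return DNA string.
#' @examples
#' c_strand_unit(telomere_motif("TTAGGG")) # "CCCTAA"
#' @export
c_strand_unit <- function(motif) {
  motif <- telomere_motif(motif)
  reverse_complement(motif$g_strand_unit)
}

#' Minimal-template permutation set
#'
#' All distinct windows of length `L + extension` of the circular C-strand
#' repeat of an L-bp telomere motif. A TR template region must span at least
#' one full repeat unit plus an anchor of `extension >= 1` nucleotides, so
#' these windows are the exhaustive k-mer set for screening transcriptomes
#' for candidate TRs. For a primitive unit and `extension < L` there are
#' exactly L of them (for TTAGGG and extension 1: the six 7-mers CCCTAAC,
#' CCTAACC, CTAACCC, TAACCCT, AACCCTA, ACCCTAA).
#'
#' @param motif A [telomere_motif()] or unit string.
#' @param extension Anchor length added to one full unit; default 1.
#' @return Character vector of distinct permutations, in circular order
#'   starting from the C-strand unit spelling.
#' @examples
#' template_permutations("TTAGGG", 1)
#' @export
template_permutations <- function(motif, extension = 1L) {
  motif <- telomere_motif(motif)
  extension <- as.integer(extension)
  if (extension < 1L) stop("extension must be >= 1", call. = FALSE)
  L <- motif$length
  if (extension >= L)
    warning("extension ", extension, " >= unit length ", L,
            ": permutations wrap around the repeat", call. = FALSE)
  cu <- c_strand_unit(motif)
  reps <- strrep(cu, ceiling((L + extension) / L) + 1L)
  unique(substring(reps, seq_len(L), seq_len(L) + L + extension - 1L))
}

#' Infer the telomere motif encoded by a TR template region
#'
#' Treats the template as a window of the circular C-strand repeat: infers
#' the repeat period by smallest-period computation, takes the first
#' period-length prefix as the C-strand unit, and reverse-complements it into
#' the G-strand telomere motif that telomerase would synthesize from this
#' template. The template must exceed one unit by at least one nucleotide
#' (the anchor that positions the telomere 3' end on the template).
#'
#' @param template C-rich template sequence as present 5'->3' in the TR.
#' @param min_unit,max_unit Accepted repeat-unit lengths (nt); defaults 5 and
#'   15 bracket the known plant telomere units (6-12 bp) with slack.
#' @param start,end Optional 0-based half-open coordinates of the template
#'   within its host transcript (metadata only).
#' @return An object of class `template_region`: fields `sequence`, `start`,
#'   `end`, `unit_c`, `period`, `predicted_motif` ([telomere_motif()]),
#'   `anchor_nt`, `span_units`.
#' @examples
#' tr <- predict_telomere_motif("CTAAACCCT")
#' tr$predicted_motif$display_form # "TTTAGGG"
#' tr$anchor_nt                    # 2
#' predict_telomere_motif("AACCGAGCCCATAACCGA")$span_units # 1.5
#' @export
predict_telomere_motif <- function(template, min_unit = 5L, max_unit = 15L,
                                   start = NA_integer_, end = NA_integer_) {
  stopifnot(is.character(template), length(template) == 1L)
  template <- toupper(template)
  .check_alphabet(template, c("A", "C", "G", "T", "N"), what = "template")
  n <- nchar(template)
  if (n < min_unit + 1L)
    stop("template shorter than min_unit + 1 (", min_unit + 1L, " nt)", call. = FALSE)
  if (grepl("N", template, fixed = TRUE))
    stop("no periodic template: template contains N", call. = FALSE)
  p <- minimal_period(template)
  if (p < min_unit)
    stop("degenerate template: smallest period ", p, " < min_unit ", min_unit,
         call. = FALSE)
  if (p > max_unit || n < p + 1L)
    stop("no periodic template: no period <= ", max_unit,
         " with at least one anchor nucleotide", call. = FALSE)
  unit_c <- substr(template, 1L, p)
  g_unit <- reverse_complement(unit_c)
  motif <- telomere_motif(display_rotation(g_unit))
  span <- n / p
  anchor <- if (span < 2) n - p else n %% p
  structure(
    list(sequence = template, start = start, end = end,
         unit_c = unit_c, period = p,
         predicted_motif = motif,
         anchor_nt = as.integer(anchor),
         span_units = span),
    class = "template_region")
}

#' @export
print.template_region <- function(x, ...) {
  cat("TR template region (", nchar(x$sequence), " nt): ", x$sequence, "\n", sep = "")
  if (!is.na(x$start))
    cat("  transcript coords: [", x$start, ", ", x$end, ") (0-based)\n", sep = "")
  cat("  period: ", x$period, " nt; span: ", format(x$span_units),
      " units; anchor: ", x$anchor_nt, " nt\n", sep = "")
  cat("  predicted motif: (", x$predicted_motif$display_form, ")n\n", sep = "")
  invisible(x)
}

#' Repeat-unit span of a template region
#'
#' Length of the template divided by the motif unit length, after verifying
#' that the template really is a window of the motif's circular C-strand
#' repeat (e.g. the 18-nt Allium consensus template covers 1.5 units of the
#' 12-bp repeat).
#'
#' @param template Template sequence (C-strand window).
#' @param motif A [telomere_motif()] or unit string.
#' @return Numeric span in repeat units.
#' @examples
#' template_span("AACCGAGCCCATAACCGA", "CTCGGTTATGGG") # 1.5
#' @export
template_span <- function(template, motif) {
  motif <- telomere_motif(motif)
  stopifnot(is.character(template), length(template) == 1L, nchar(template) > 0L)
  template <- toupper(template)
  cu <- c_strand_unit(motif)
  reps <- strrep(cu, ceiling(nchar(template) / motif$length) + 1L)
  if (!grepl(template, reps, fixed = TRUE))
    stop("template/motif mismatch: template is not a window of the circular ",
         "C-strand repeat of (", motif$display_form, ")n", call. = FALSE)
  nchar(template) / motif$length
}

#' Enumerate all telomere motifs compatible with a template
#'
#' For every candidate period p in `[min_unit, max_unit]`, finds every
#' maximal window of the template that is p-periodic with length >= p + 1
#' (one unit plus anchor) and reports the telomere motif encoded by that
#' window. Useful for mixed-type templates that can template more than one
#' repeat (e.g. Agave/Nolina-type TRs compatible with both human- and
#' Arabidopsis-type repeats). Windows whose inferred unit is not primitive
#' are skipped (they re-describe a shorter-period window). Any window
#' containing N is non-periodic by definition.
#'
#' @inheritParams predict_telomere_motif
#' @return A data.frame with columns `start`, `end` (0-based half-open on the
#'   template), `period`, `unit_c`, `motif` (display form), `span_units`,
#'   sorted by window length descending then period ascending. Zero rows when
#'   no periodic window exists.
#' @examples
#' enumerate_compatible_motifs("ACCCTAACCCTAAACCCT", 5, 15)
#' @export
enumerate_compatible_motifs <- function(template, min_unit = 5L, max_unit = 15L) {
  stopifnot(is.character(template), length(template) == 1L)
  template <- toupper(template)
  .check_alphabet(template, c("A", "C", "G", "T", "N"), what = "template")
  n <- nchar(template)
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  out <- list()
  for (p in seq.int(min_unit, max_unit)) {
    if (n < p + 1L) break
    ok <- chars[seq_len(n - p)] == chars[seq_len(n - p) + p] &
      chars[seq_len(n - p)] != "N"
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      w_start <- starts[k]                 # 1-based
      w_end <- ends[k] + p                 # 1-based inclusive
      win <- substr(template, w_start, w_end)
      if (grepl("N", win, fixed = TRUE)) next
      unit <- substr(template, w_start, w_start + p - 1L)
      if (!.is_primitive(unit)) next
      g_unit <- reverse_complement(unit)
      out[[length(out) + 1L]] <- data.frame(
        start = w_start - 1L, end = w_end, period = p,
        unit_c = unit, motif = display_rotation(g_unit),
        span_units = (w_end - w_start + 1L) / p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      unit_c = character(), motif = character(),
                      span_units = numeric(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(-(df$end - df$start), df$period, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
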