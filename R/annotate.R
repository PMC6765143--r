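#' Locate candidate template domains in a TR transcript
#'
#' Scans the whole transcript for periodic windows
#' ([enumerate_compatible_motifs()]) and keeps those that look like genuine
#' telomerase template regions: span of at least `min_span` repeat units
#' (default 9/7, the one-unit-plus-2-nt-anchor geometry of the Arabidopsis
#' template), C content of the inferred C-strand unit of at least 0.25, and
#' at least 3 distinct bases in the unit (rejects homopolymer and
#' dinucleotide artifacts). Candidates are ranked by span descending, then
#' 5'-most first.
#'
#' @param tr_seq Transcript sequence.
#' @param min_unit,max_unit Accepted repeat-unit lengths.
#' @param min_span Minimum span in repeat units.
#' @return Data.frame like [enumerate_compatible_motifs()] (0-based half-open
#'   `start`, `end`, plus `period`, `unit_c`, `motif`, `span_units`).
#' @export
find_template_domain <- function(tr_seq, min_unit = 5L, max_unit = 15L,
                                 min_span = 9 / 7) {
  cand <- enumerate_compatible_motifs(tr_seq, min_unit, max_unit)
  if (nrow(cand) == 0L) return(cand)
  c_frac <- vapply(cand$unit_c, function(u) {
    ch <- strsplit(u, "", fixed = TRUE)[[1]]
    mean(ch == "C")
  }, numeric(1))
  n_bases <- vapply(cand$unit_c, function(u)
    length(unique(strsplit(u, "", fixed = TRUE)[[1]])), integer(1))
  keep <- cand$span_units >= min_span & c_frac >= 0.25 & n_bases >= 3L
  out <- cand[keep, , drop = FALSE]
  out <- out[order(-out$span_units, out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window base-composition features
#'
#' Flags G-rich, C-rich and AT-rich regions by sliding-window composition
#' (defaults: G >= 0.5, C >= 0.5, A+T >= 0.8 over 15-nt windows) and merges
#' overlapping or adjacent same-type windows into maximal intervals scored by
#' the maximum window fraction; each merged interval is trimmed to its first
#' and last contributing base (G for `g_rich`, C for `c_rich`, A/T for
#' `at_rich`), since a qualifying window can overhang the rich block. These
#' are the 5' G-rich, near-3' C-rich and 3' AT-rich blocks of the conserved
#' TR architecture.
#'
#' @param seq DNA string.
#' @param window Window width (nt).
#' @param thresholds Named list of minimum fractions for `g_rich`, `c_rich`,
#'   `at_rich`.
#' @return Data.frame: `feature`, `start`, `end` (0-based half-open),
#'   `score` (max window fraction).
#' @export
composition_scan <- function(seq, window = 15L,
                             thresholds = list(g_rich = 0.5, c_rich = 0.5,
                                               at_rich = 0.8)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (window > n) stop("window larger than sequence", call. = FALSE)
  freqs <- Biostrings::letterFrequencyInSlidingView(
    Biostrings::DNAString(seq), window, c("G", "C", "AT")) / window
  colnames(freqs) <- c("g_rich", "c_rich", "at_rich")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  contributes <- list(g_rich = chars == "G", c_rich = chars == "C",
                      at_rich = chars %in% c("A", "T"))
  out <- list()
  for (feat in names(thresholds)) {
    flag <- freqs[, feat] >= thresholds[[feat]]
    if (!any(flag)) next
    starts <- which(flag)                      # 1-based window starts
    ir <- IRanges::reduce(IRanges::IRanges(start = starts,
                                           width = window))
    for (k in seq_len(length(ir))) {
      s <- IRanges::start(ir)[k]; e <- IRanges::end(ir)[k]
      in_win <- starts >= s & starts <= e - window + 1L
      # trim the merged window union to the rich block itself: a sliding
      # window overhangs the block by up to window-1 non-contributing bases
      hit <- which(contributes[[feat]][s:e]) + s - 1L
      if (length(hit) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        feature = feat, start = min(hit) - 1L, end = max(hit),
        score = max(freqs[starts[in_win], feat]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(feature = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a position weight matrix from aligned sites
#'
#' Log-odds (base 2) PWM with pseudocount:
#' `weight[b, i] = log2(((count[b, i] + pc) / (n + 4 pc)) / background[b])`.
#' Intended for promoter elements (USE, TATA box) learned from user-supplied
#' aligned site collections.
#'
#' @param sites Character vector (>= 2) of equal-length ungapped ACGT sites.
#' @param pseudocount Positive pseudocount (default 0.5).
#' @param background Named base frequencies (default uniform).
#' @return Object of class `pwm`: `weights` (4 x width matrix, rows ACGT),
#'   `background`, `pseudocount`, `n_sites`, `width`, `max_score` (sum of
#'   per-column maxima).
#' @export
build_pwm <- function(sites, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(is.character(sites))
  if (length(sites) < 2L)
    stop("need at least 2 sites to build a PWM", call. = FALSE)
  sites <- toupper(sites)
  if (length(unique(nchar(sites))) != 1L)
    stop("sites must be equal-length and ungapped", call. = FALSE)
  for (s in sites) .check_alphabet(s, what = "PWM site")
  stopifnot(pseudocount > 0, all(c("A", "C", "G", "T") %in% names(background)))
  m <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  w <- nchar(sites[1])
  n <- length(sites)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(w), function(i)
    vapply(bases, function(b) sum(m[, i] == b), numeric(1)), numeric(4))
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  weights <- log2(freq / background[bases])
  dimnames(weights) <- list(bases, NULL)
  structure(list(weights = weights, background = background[bases],
                 pseudocount = pseudocount, n_sites = n, width = w,
                 max_score = sum(apply(weights, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM: width ", x$width, ", built from ", x$n_sites,
      " sites (pseudocount ", x$pseudocount, ")\n", sep = "")
  cat("  consensus: ",
      paste(rownames(x$weights)[apply(x$weights, 2, which.max)],
            collapse = ""),
      "; max score ", sprintf("%.2f", x$max_score), " bits\n", sep = "")
  invisible(x)
}

# raw PWM scores at every offset of seq (1-based starts); windows with N
# score -Inf
.pwm_scores <- function(seq, pwm) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars); w <- pwm$width
  if (n < w) return(numeric(0))
  idx <- match(chars, rownames(pwm$weights))   # NA for N etc.
  vapply(seq_len(n - w + 1L), function(s) {
    cols <- idx[s:(s + w - 1L)]
    if (anyNA(cols)) return(-Inf)
    sum(pwm$weights[cbind(cols, seq_len(w))])
  }, numeric(1))
}

#' Scan a sequence with a PWM
#'
#' Reports every window scoring at least `min_fraction_of_max` times the
#' PWM's maximum attainable score, sorted by score descending (ties by
#' position). `best_per_locus = TRUE` greedily drops hits overlapping a
#' better one.
#'
#' @param seq DNA string (length >= PWM width).
#' @param pwm A [build_pwm()] object.
#' @param min_fraction_of_max Score threshold as a fraction of the maximum.
#' @param strand_mode `"sense"` or `"both"`.
#' @param best_per_locus Resolve overlapping hits to the best one.
#' @param feature Feature label for the output rows.
#' @return Data.frame: `feature`, `start`, `end` (0-based half-open on the
#'   input), `score`, `strand`.
#' @export
scan_pwm <- function(seq, pwm, min_fraction_of_max = 0.8,
                     strand_mode = c("sense", "both"),
                     best_per_locus = FALSE, feature = "pwm_hit") {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(pwm, "pwm"))
  seq <- toupper(seq)
  if (nchar(seq) < pwm$width)
    stop("sequence shorter than PWM width", call. = FALSE)
  thr <- min_fraction_of_max * pwm$max_score
  collect <- function(s, strand) {
    sc <- .pwm_scores(s, pwm)
    hit <- which(sc >= thr)
    if (length(hit) == 0L) return(NULL)
    start0 <- hit - 1L
    if (strand == "-") start0 <- nchar(seq) - (hit - 1L) - pwm$width
    data.frame(feature = feature, start = start0, end = start0 + pwm$width,
               score = sc[hit], strand = strand, stringsAsFactors = FALSE)
  }
  out <- collect(seq, "+")
  if (strand_mode == "both")
    out <- rbind(out, collect(reverse_complement(seq), "-"))
  if (is.null(out))
    return(data.frame(feature = character(), start = integer(),
                      end = integer(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(-out$score, out$start, out$strand), , drop = FALSE]
  if (best_per_locus && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      for (j in seq_len(i - 1L)) {
        if (keep[j] && out$start[i] < out$end[j] && out$end[i] > out$start[j]) {
          keep[i] <- FALSE; break
        }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Find a Pol III terminator (poly-T run)
#'
#' RNA polymerase III terminates at a run of thymidines on the non-template
#' strand; plant Pol III genes typically use runs of 4 or more. Returns the
#' first run of at least `min_t` consecutive T whose start lies within
#' `search_span` nt of the sequence start; the reported interval covers the
#' whole run.
#'
#' @param downstream_seq Sense-strand sequence downstream of the gene body.
#' @param min_t Minimum run length (default 4).
#' @param search_span How far from the start to search (nt).
#' @return Data.frame with one row (`feature = "terminator"`, `start`, `end`
#'   0-based half-open, `score` = run length) or zero rows if absent.
#' @export
find_pol3_terminator <- function(downstream_seq, min_t = 4L,
                                 search_span = 200L) {
  stopifnot(is.character(downstream_seq), length(downstream_seq) == 1L)
  s <- toupper(downstream_seq)
  m <- gregexpr(paste0("T{", min_t, ",}"), s)[[1]]
  empty <- data.frame(feature = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  ok <- which(m <= search_span)   # run starts within the span (1-based)
  if (length(ok) == 0L) return(empty)
  i <- ok[1]
  data.frame(feature = "terminator", start = m[i] - 1L,
             end = m[i] - 1L + len[i], score = as.numeric(len[i]),
             stringsAsFactors = FALSE)
}

#' Read support for transcript ends
#'
#' Counts reads containing the transcript's first / last k bases in either
#' orientation, the evidence used to fix a TR's transcription start and
#' termination sites (a read may support both ends). With
#' `max_mismatch > 0`, terminal k-mers are matched allowing that many
#' mismatches.
#'
#' @param transcript Transcript sequence.
#' @param reads Character vector, `DNAStringSet`, or FASTA/FASTQ path.
#' @param k Terminal k-mer length (default 20; must not exceed read or
#'   transcript length).
#' @param max_mismatch Allowed mismatches in the k-mer match (default 0).
#' @return Named integer vector `c(n5 = ..., n3 = ...)`.
#' @export
end_support <- function(transcript, reads, k = 20L, max_mismatch = 0L) {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  transcript <- toupper(transcript)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (!methods::is(reads, "XStringSet"))
    reads <- Biostrings::DNAStringSet(toupper(reads))
  n <- nchar(transcript)
  if (k > n) stop("k exceeds transcript length", call. = FALSE)
  if (length(reads) > 0L && k > min(Biostrings::width(reads)))
    stop("k exceeds read length", call. = FALSE)
  count_kmer <- function(kmer) {
    pat <- Biostrings::DNAString(kmer)
    fwd <- Biostrings::vcountPattern(pat, reads, max.mismatch = max_mismatch)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), reads,
                                     max.mismatch = max_mismatch)
    sum(fwd + rev > 0L)
  }
  c(n5 = count_kmer(substr(transcript, 1L, k)),
    n3 = count_kmer(substr(transcript, n - k + 1L, n)))
}

#' Annotate the conserved architecture of a TR gene
#'
#' Orchestrates the feature finders over a TR transcript and its optional
#' genomic context: template domain(s) and base-composition blocks on the
#' transcript; TATA box and USE promoter scans on the upstream context only;
#' Pol III terminator on the downstream context only. When no TATA PWM is
#' supplied, a literal heuristic matcher (TATAAA, at most 1 mismatch) is
#' used. Overlapping template candidates are all reported and flagged.
#'
#' @param tr_seq Transcript sequence.
#' @param upstream,downstream Optional genomic context sequences (sense
#'   strand; upstream given 5'->3' ending at the transcription start).
#' @param pwms Optional named list of [build_pwm()] objects: elements `use`,
#'   `tata`, `conserved_box` are scanned if present.
#' @param config Named list overriding defaults: `window`, `thresholds`
#'   (see [composition_scan()]), `min_unit`, `max_unit`, `min_span`,
#'   `min_fraction_of_max`, `min_t`, `search_span`.
#' @return Data.frame of class `tr_annotation`: `seqid`
#'   (`transcript`/`upstream`/`downstream`), `feature`, `start`, `end`
#'   (0-based half-open on the respective sequence), `score`, `strand`,
#'   `note`; ordered by seqid then coordinate. Convert with [write_gff3()].
#' @export
annotate_tr <- function(tr_seq, upstream = NULL, downstream = NULL,
                        pwms = list(), config = list()) {
  cfg <- utils::modifyList(list(
    window = 15L,
    thresholds = list(g_rich = 0.5, c_rich = 0.5, at_rich = 0.8),
    min_unit = 5L, max_unit = 15L, min_span = 9 / 7,
    min_fraction_of_max = 0.8, min_t = 4L, search_span = 200L), config)
  feats <- list()
  add <- function(df, seqid) {
    if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
    df$seqid <- seqid
    if (is.null(df$strand)) df$strand <- "+"
    if (is.null(df$note)) df$note <- ""
    feats[[length(feats) + 1L]] <<- df[, c("seqid", "feature", "start", "end",
                                           "score", "strand", "note")]
    invisible(NULL)
  }

  tmpl <- find_template_domain(tr_seq, cfg$min_unit, cfg$max_unit, cfg$min_span)
  if (nrow(tmpl) > 0L) {
    overlaps_best <- tmpl$start < tmpl$end[1] & tmpl$end > tmpl$start[1]
    df <- data.frame(feature = "template", start = tmpl$start, end = tmpl$end,
                     score = tmpl$span_units,
                     note = paste0("motif=", tmpl$motif, ";period=",
                                   tmpl$period,
                                   ifelse(seq_len(nrow(tmpl)) > 1L &
                                            overlaps_best,
                                          ";overlaps_primary", "")),
                     stringsAsFactors = FALSE)
    add(df, "transcript")
  }
  add(composition_scan(tr_seq, cfg$window, cfg$thresholds), "transcript")
  if (!is.null(pwms$conserved_box))
    add(scan_pwm(tr_seq, pwms$conserved_box, cfg$min_fraction_of_max,
                 feature = "conserved_box"), "transcript")

  if (!is.null(upstream)) {
    if (!is.null(pwms$use))
      add(scan_pwm(upstream, pwms$use, cfg$min_fraction_of_max,
                   feature = "use"), "upstream")
    if (!is.null(pwms$tata)) {
      add(scan_pwm(upstream, pwms$tata, cfg$min_fraction_of_max,
                   feature = "tata"), "upstream")
    } else {
      # heuristic fallback: literal TATAAA with at most one mismatch
      hits <- Biostrings::matchPattern("TATAAA",
                                       Biostrings::DNAString(toupper(upstream)),
                                       max.mismatch = 1)
      if (length(hits) > 0L) {
        mm <- vapply(as.character(hits), function(s)
          sum(strsplit(s, "")[[1]] != strsplit("TATAAA", "")[[1]]),
          numeric(1))
        add(data.frame(feature = "tata",
                       start = Biostrings::start(hits) - 1L,
                       end = Biostrings::end(hits),
                       score = 6 - mm,
                       note = "heuristic=TATAAA<=1mm",
                       stringsAsFactors = FALSE), "upstream")
      }
    }
  } else {
    warning("no upstream context: promoter features (USE, TATA) not scanned",
            call. = FALSE)
  }
  if (!is.null(downstream)) {
    add(find_pol3_terminator(downstream, cfg$min_t, cfg$search_span),
        "downstream")
  } else {
    warning("no downstream context: terminator not scanned", call. = FALSE)
  }
  if (length(feats) == 0L)
    out <- data.frame(seqid = character(), feature = character(),
                      start = integer(), end = integer(), score = numeric(),
                      strand = character(), note = character(),
                      stringsAsFactors = FALSE)
  else out <- do.call(rbind, feats)
  ord <- order(factor(out$seqid,
                      levels = c("upstream", "transcript", "downstream")),
               out$start, out$end, out$feature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tr_annotation", "data.frame")
  out
}
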