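#' Write sequences to FASTA
#'
#' Wraps sequence lines at 60 columns. Deterministic output: identical input
#' gives byte-identical files.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqs <- .as_seqs(seqs)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Fixed quality character for every base (simulated reads carry no quality
#' model).
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @param quality_char Quality character (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  reads <- .as_seqs(reads, what = "reads")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep(quality_char, nchar(reads[[i]]))), con, sep = "\n")
  }
  invisible(path)
}

#' Write a feature annotation as GFF3
#'
#' Converts a [annotate_tr()] table (0-based half-open intervals) to GFF3
#' (1-based inclusive). Feature types go to column 3, scores to column 6;
#' the note (if any) becomes a `Note=` attribute. Output is deterministic.
#'
#' @param annotation A `tr_annotation` data.frame.
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, source = "teloseeker") {
  stopifnot(is.data.frame(annotation))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(annotation) > 0L) {
    score <- ifelse(is.na(annotation$score), ".",
                    vapply(annotation$score, function(x)
                      format(x, digits = 6, trim = TRUE), character(1)))
    note <- if (!is.null(annotation$note)) annotation$note else ""
    attrs <- ifelse(nzchar(note), paste0("Note=", note), ".")
    strand <- if (!is.null(annotation$strand)) annotation$strand else "+"
    lines <- paste(annotation$seqid, source, annotation$feature,
                   annotation$start + 1L, annotation$end, score, strand,
                   ".", attrs, sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a TRF intensity profile
#'
#' Two-column TSV/CSV (size_bp, intensity), with or without a header line.
#'
#' @param path Input file.
#' @return Data.frame with columns `size`, `intensity`.
#' @export
read_trf_profile <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("size", "intensity")
  df[, 1:2]
}
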