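# coerce DNAStringSet / named character to a named upper-case character vector
.as_seqs <- function(x, what = "transcripts") {
  if (methods::is(x, "XStringSet")) {
    out <- toupper(as.character(x))
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop(what, " must be a DNAStringSet or a named character vector",
         call. = FALSE)
  }
  ids <- names(out)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every ", what, " record needs a non-empty id", call. = FALSE)
  # FASTA headers: id is the first whitespace-delimited token
  names(out) <- sub("\\s.*$", "", ids)
  if (anyDuplicated(names(out)))
    stop("duplicate transcript ids within one dataset: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  out
}

#' Read a transcript FASTA file
#'
#' Reads a (wrapped or single-line) multi-FASTA of assembled transcripts,
#' upper-casing sequences; soft-masked regions are kept. Ids are the first
#' whitespace-delimited header token and must be unique within the file.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  .as_seqs(Biostrings::readDNAStringSet(path))
}

#' Screen transcripts for minimal-template permutations
#'
#' The grep step of TR candidate discovery: pull out every transcript that
#' contains any permutation of the minimal template region. Matching is exact
#' and case-insensitive (sequences are upper-cased on read), works across the
#' whole record regardless of FASTA line wrapping, and `N` never matches.
#' With `strand_mode = "both"`, matches of the reverse-complemented
#' permutations are reported as `antisense` (default is sense-only: stranded
#' assemblies are screened on the given strand, as a stranded Trinity
#' assembly would be).
#'
#' @param records Named character vector or `DNAStringSet` of transcripts.
#' @param permutations Character vector of equal-length permutations, e.g.
#'   from [template_permutations()].
#' @param strand_mode `"sense"` (default) or `"both"`.
#' @param dataset Dataset label attached to the hits (default `"dataset1"`).
#' @return A data.frame of class `candidate_hits`, one row per occurrence:
#'   `dataset`, `transcript_id`, `permutation` (as given, G-strand of the
#'   match is the reverse complement for antisense rows), `position`
#'   (0-based start of the match on the transcript), `strand`
#'   (`sense`/`antisense`), sorted by transcript id, permutation, position.
#' @examples
#' perms <- template_permutations("TTAGGG", 1)
#' scan_transcripts(c(tx1 = "GGACCCTAACGG"), perms)
#' @export
scan_transcripts <- function(records, permutations,
                             strand_mode = c("sense", "both"),
                             dataset = "dataset1") {
  strand_mode <- match.arg(strand_mode)
  seqs <- .as_seqs(records)
  if (length(permutations) == 0L)
    stop("permutation set must be non-empty", call. = FALSE)
  permutations <- toupper(permutations)
  if (length(unique(nchar(permutations))) != 1L)
    stop("permutations must all have the same length", call. = FALSE)
  subj <- Biostrings::DNAStringSet(seqs)
  pats <- Biostrings::DNAStringSet(permutations)
  pd <- Biostrings::PDict(pats)

  scan_one_strand <- function(patterns_pd, strand_label) {
    rows <- vector("list", length(subj))
    for (i in seq_along(subj)) {
      m <- Biostrings::matchPDict(patterns_pd, subj[[i]])
      counts <- lengths(m)
      hit_idx <- which(counts > 0L)
      if (length(hit_idx) == 0L) next
      rows[[i]] <- do.call(rbind, lapply(hit_idx, function(k) {
        data.frame(dataset = dataset,
                   transcript_id = names(seqs)[i],
                   permutation = permutations[k],
                   position = Biostrings::start(m[[k]]) - 1L,
                   strand = strand_label,
                   stringsAsFactors = FALSE)
      }))
    }
    do.call(rbind, rows)
  }

  out <- scan_one_strand(pd, "sense")
  if (strand_mode == "both") {
    # an antisense hit means the reverse complement of the (as-given)
    # permutation occurs at `position`
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(pats))
    anti <- scan_one_strand(pd_rc, "antisense")
    if (!is.null(anti)) out <- rbind(out, anti)
  }
  if (is.null(out))
    out <- data.frame(dataset = character(), transcript_id = character(),
                      permutation = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$permutation, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_hits", "data.frame")
  out
}

#' Screen several datasets at once
#'
#' @param datasets Named list: dataset label -> transcripts (named character
#'   vector, `DNAStringSet`, or FASTA path).
#' @inheritParams scan_transcripts
#' @return List with `hits` (row-bound [scan_transcripts()] output across
#'   datasets), `totals` (named transcript counts) and `candidates` (named
#'   list of candidate transcript sequence vectors per dataset).
#' @export
scan_datasets <- function(datasets, permutations,
                          strand_mode = c("sense", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.list(datasets), !is.null(names(datasets)),
            all(nzchar(names(datasets))))
  if (anyDuplicated(names(datasets)))
    stop("dataset labels must be unique", call. = FALSE)
  hits <- list(); totals <- integer(0); cands <- list()
  for (ds in names(datasets)) {
    x <- datasets[[ds]]
    if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
      x <- read_transcripts(x)
    seqs <- .as_seqs(x)
    h <- scan_transcripts(seqs, permutations, strand_mode, dataset = ds)
    hits[[ds]] <- h
    totals[ds] <- length(seqs)
    cands[[ds]] <- seqs[unique(h$transcript_id)]
  }
  all_hits <- do.call(rbind, hits)
  rownames(all_hits) <- NULL
  class(all_hits) <- c("candidate_hits", "data.frame")
  list(hits = all_hits, totals = totals, candidates = cands)
}

#' Summarize a candidate screen
#'
#' Per-dataset totals and candidate counts (the statistic the comparative
#' screen reports: how many transcripts carry any minimal-template
#' permutation), plus per-permutation hit counts, in deterministic
#' (dataset, permutation) order.
#'
#' @param hits A `candidate_hits` data.frame (possibly from several datasets).
#' @param totals Named integer vector, dataset -> total transcript count.
#' @return List with `datasets` (data.frame `dataset`, `total_transcripts`,
#'   `candidate_transcripts`) and `permutations` (data.frame `dataset`,
#'   `permutation`, `n_hits`, `n_transcripts`).
#' @export
summarize_screen <- function(hits, totals) {
  stopifnot(is.data.frame(hits))
  missing_ds <- setdiff(unique(hits$dataset), names(totals))
  if (length(missing_ds) > 0L)
    stop("datasets present in hits but missing from totals: ",
         paste(missing_ds, collapse = ", "), call. = FALSE)
  ds_names <- sort(names(totals))
  per_ds <- data.frame(
    dataset = ds_names,
    total_transcripts = as.integer(totals[ds_names]),
    candidate_transcripts = vapply(ds_names, function(d)
      length(unique(hits$transcript_id[hits$dataset == d])), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(hits) > 0L) {
    agg_hits <- stats::aggregate(position ~ dataset + permutation, data = hits,
                                 FUN = length)
    names(agg_hits)[3] <- "n_hits"
    agg_tx <- stats::aggregate(transcript_id ~ dataset + permutation,
                               data = hits,
                               FUN = function(x) length(unique(x)))
    names(agg_tx)[3] <- "n_transcripts"
    per_perm <- merge(agg_hits, agg_tx, by = c("dataset", "permutation"))
    per_perm <- per_perm[order(per_perm$dataset, per_perm$permutation), ,
                         drop = FALSE]
    rownames(per_perm) <- NULL
  } else {
    per_perm <- data.frame(dataset = character(), permutation = character(),
                           n_hits = integer(), n_transcripts = integer(),
                           stringsAsFactors = FALSE)
  }
  list(datasets = per_ds, permutations = per_perm)
}
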