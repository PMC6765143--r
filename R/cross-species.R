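#' All-to-all cross-dataset homology comparison of candidate transcripts
#'
#' The ortholog-intersection step: every candidate transcript of every
#' dataset is aligned (both strands, [local_align()]) against the candidates
#' of every other dataset. A candidate is "present" in another dataset when
#' at least one alignment passes the acceptance thresholds in `params`
#' (score, identity and aligned length). Rows are classified
#' `shared_in_all` / `shared_in_some` / `unique` by the number of datasets
#' they are present in; a row's own dataset always counts as present.
#'
#' An optional exact k-mer pre-filter (`prefilter_k`) skips sequence pairs
#' sharing no k-mer on either strand; by default every pair is aligned by
#' full dynamic programming.
#'
#' @param candidate_sets Named list: dataset -> named character vector (or
#'   `DNAStringSet`) of candidate transcripts. At least 2 datasets; a dataset
#'   with zero candidates keeps its column (all-false presence).
#' @param params [alignment_params()].
#' @param prefilter_k `NULL` (no pre-filter) or an integer k.
#' @return Object of class `presence_matrix`: list with `matrix` (data.frame:
#'   `dataset`, `transcript_id`, one logical column per dataset, `class`),
#'   `hits` (data.frame of passing pairwise hits: `dataset_a`,
#'   `transcript_a`, `dataset_b`, `transcript_b`, `score`, `identity`,
#'   `length`, `strand`) and `params`. Row order is deterministic
#'   (dataset, transcript id).
#' @export
cross_compare <- function(candidate_sets, params = alignment_params(),
                          prefilter_k = NULL) {
  stopifnot(is.list(candidate_sets), !is.null(names(candidate_sets)))
  if (length(candidate_sets) < 2L)
    stop("cross_compare needs at least 2 datasets", call. = FALSE)
  sets <- lapply(candidate_sets, function(x)
    if (length(x) == 0L) character(0) else .as_seqs(x))
  ds <- names(sets)

  kmer_sets <- NULL
  if (!is.null(prefilter_k)) {
    k <- as.integer(prefilter_k)
    kmers_of <- function(s) {
      if (nchar(s) < k) return(character(0))
      ss <- unique(substring(s, seq_len(nchar(s) - k + 1L),
                             seq_len(nchar(s) - k + 1L) + k - 1L))
      unique(c(ss, vapply(ss, reverse_complement, character(1))))
    }
    kmer_sets <- lapply(sets, function(v) lapply(v, kmers_of))
  }

  hits <- list()
  for (ia in seq_along(ds)[-length(ds)]) {
    for (ib in seq.int(ia + 1L, length(ds))) {
      a <- sets[[ia]]; b <- sets[[ib]]
      if (length(a) == 0L || length(b) == 0L) next
      grid <- expand.grid(i = seq_along(a), j = seq_along(b))
      if (!is.null(kmer_sets)) {
        keep <- mapply(function(i, j)
          any(kmer_sets[[ia]][[i]] %in% kmer_sets[[ib]][[j]]),
          grid$i, grid$j)
        grid <- grid[keep, , drop = FALSE]
        if (nrow(grid) == 0L) next
      }
      # cheap score-only pass over both strands, then traceback on survivors
      s_plus <- .sw_scores(a[grid$i], b[grid$j], params)
      brc <- vapply(b, reverse_complement, character(1))
      s_minus <- .sw_scores(a[grid$i], brc[grid$j], params)
      cand <- which(pmax(s_plus, s_minus) >= params$min_score)
      for (r in cand) {
        aln <- local_align(a[grid$i[r]], b[grid$j[r]], params)
        if (.passes(aln, params)) {
          hits[[length(hits) + 1L]] <- data.frame(
            dataset_a = ds[ia], transcript_a = names(a)[grid$i[r]],
            dataset_b = ds[ib], transcript_b = names(b)[grid$j[r]],
            score = aln$score, identity = aln$identity,
            length = aln$length, strand = aln$strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(dataset_a = character(), transcript_a = character(),
               dataset_b = character(), transcript_b = character(),
               score = integer(), identity = numeric(), length = integer(),
               strand = character(), stringsAsFactors = FALSE)

  rows <- do.call(rbind, lapply(ds, function(d) {
    if (length(sets[[d]]) == 0L) return(NULL)
    data.frame(dataset = d, transcript_id = names(sets[[d]]),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$dataset, rows$transcript_id), , drop = FALSE]
  pres <- matrix(FALSE, nrow = nrow(rows), ncol = length(ds),
                 dimnames = list(NULL, ds))
  key <- paste(rows$dataset, rows$transcript_id, sep = "\r")
  pres[cbind(seq_len(nrow(rows)), match(rows$dataset, ds))] <- TRUE
  if (nrow(hits) > 0L) {
    ka <- match(paste(hits$dataset_a, hits$transcript_a, sep = "\r"), key)
    kb <- match(paste(hits$dataset_b, hits$transcript_b, sep = "\r"), key)
    pres[cbind(ka, match(hits$dataset_b, ds))] <- TRUE
    pres[cbind(kb, match(hits$dataset_a, ds))] <- TRUE
  }
  n_present <- rowSums(pres)
  cls <- ifelse(n_present == length(ds), "shared_in_all",
                ifelse(n_present == 1L, "unique", "shared_in_some"))
  mat <- cbind(rows, as.data.frame(pres), class = cls,
               stringsAsFactors = FALSE)
  rownames(mat) <- NULL
  structure(list(matrix = mat, hits = hits, datasets = ds, params = params),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence matrix: ", nrow(x$matrix), " candidates across ",
      length(x$datasets), " datasets\n", sep = "")
  print(table(x$matrix$class))
  invisible(x)
}

#' Ortholog groups and the final candidate set
#'
#' Single-linkage grouping: candidates are nodes, passing pairwise hits are
#' edges, ortholog groups are connected components. The final TR candidate
#' set consists of the groups whose members cover every dataset (candidates
#' sharing sequence similarity in all datasets). Each group reports its
#' representative: the longest member, ties broken by lexicographically
#' smallest id.
#'
#' @param pm A `presence_matrix` from [cross_compare()].
#' @param candidate_sets The same named list given to [cross_compare()]
#'   (needed for member lengths).
#' @return List with `groups` (data.frame: `group`, `n_members`,
#'   `n_datasets`, `representative`, `members` as "dataset:id" comma-string),
#'   `membership` (data.frame: `group`, `dataset`, `transcript_id`) and
#'   `final` (membership rows of groups covering all datasets). Groups are
#'   sorted by dataset coverage then size, descending.
#' @export
classify_and_group <- function(pm, candidate_sets) {
  stopifnot(inherits(pm, "presence_matrix"))
  sets <- lapply(candidate_sets, function(x)
    if (length(x) == 0L) character(0) else .as_seqs(x))
  nodes <- paste(pm$matrix$dataset, pm$matrix$transcript_id, sep = "\r")
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(pm$hits) > 0L) {
    ea <- paste(pm$hits$dataset_a, pm$hits$transcript_a, sep = "\r")
    eb <- paste(pm$hits$dataset_b, pm$hits$transcript_b, sep = "\r")
    g <- igraph::add_edges(g, rbind(match(ea, nodes), match(eb, nodes)))
  }
  comp <- igraph::components(g)$membership
  memb <- data.frame(component = comp,
                     dataset = pm$matrix$dataset,
                     transcript_id = pm$matrix$transcript_id,
                     stringsAsFactors = FALSE)
  memb$len <- mapply(function(d, id) nchar(sets[[d]][[id]]),
                     memb$dataset, memb$transcript_id)
  comps <- split(memb, memb$component)
  info <- do.call(rbind, lapply(comps, function(cm) {
    best <- cm[order(-cm$len, cm$transcript_id), , drop = FALSE][1, ]
    data.frame(component = cm$component[1],
               n_members = nrow(cm),
               n_datasets = length(unique(cm$dataset)),
               representative = best$transcript_id,
               representative_dataset = best$dataset,
               members = paste(paste(cm$dataset, cm$transcript_id, sep = ":"),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  info <- info[order(-info$n_datasets, -info$n_members, info$representative), ,
               drop = FALSE]
  info$group <- seq_len(nrow(info))
  memb$group <- info$group[match(memb$component, info$component)]
  memb <- memb[order(memb$group, memb$dataset, memb$transcript_id),
               c("group", "dataset", "transcript_id"), drop = FALSE]
  rownames(memb) <- NULL
  groups <- info[, c("group", "n_members", "n_datasets", "representative",
                     "representative_dataset", "members")]
  rownames(groups) <- NULL
  final_groups <- groups$group[groups$n_datasets == length(pm$datasets)]
  final <- memb[memb$group %in% final_groups, , drop = FALSE]
  rownames(final) <- NULL
  list(groups = groups, membership = memb, final = final)
}

#' Extend the ortholog search to a new species
#'
#' Uses one known TR transcript as a query against another dataset, ranking
#' passing hits by alignment score. `relaxed = TRUE` switches to permissive
#' +1/-1 match/mismatch scoring and halves the score threshold (the second,
#' permissive search pass for diverged orthologs). Each hit is annotated with
#' whether the target transcript contains a periodic template-domain window
#' ([find_template_domain()]), the computational stand-in for manual
#' inspection of conserved regions.
#'
#' @param query Named length-1 character vector (or unnamed string) with the
#'   query TR sequence.
#' @param targets Named character vector or `DNAStringSet` of target
#'   transcripts.
#' @param params [alignment_params()].
#' @param relaxed Use permissive scoring (+1/-1, half `min_score`).
#' @param min_unit,max_unit Passed to the template-window annotation.
#' @return Data.frame ranked by score descending: `transcript_id`, `score`,
#'   `identity`, `length`, `strand`, `has_template_window`.
#' @export
extend_orthologs <- function(query, targets, params = alignment_params(),
                             relaxed = FALSE, min_unit = 5L, max_unit = 15L) {
  q <- toupper(if (!is.null(names(query))) query[[1]] else query)
  tg <- .as_seqs(targets, what = "targets")
  if (relaxed) {
    params$match <- 1L
    params$mismatch <- -1L
    params$min_score <- as.integer(ceiling(params$min_score / 2))
  }
  rows <- list()
  for (i in seq_along(tg)) {
    aln <- local_align(q, tg[[i]], params)
    if (aln$score >= params$min_score) {
      has_tmpl <- nrow(find_template_domain(tg[[i]], min_unit = min_unit,
                                            max_unit = max_unit)) > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = names(tg)[i], score = aln$score,
        identity = aln$identity, length = aln$length, strand = aln$strand,
        has_template_window = has_tmpl, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(transcript_id = character(), score = integer(),
               identity = numeric(), length = integer(), strand = character(),
               has_template_window = logical(), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identity of aligned sequences to their consensus
#'
#' Consensus is the per-column majority over non-gap residues (tie broken
#' alphabetically; all-gap columns give a gap). Each sequence's identity is
#' its fraction of matches to the consensus over the columns where the
#' sequence itself is non-gap. The mean over sequences is the summary the
#' comparative screen reports for a recovered ortholog family.
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (gap character `-`), or a `DNAStringSet`.
#' @return List: `consensus` (string), `per_sequence` (named numeric),
#'   `mean` (numeric).
#' @seealso [mean_pairwise_identity()] for the all-pairs variant.
#' @export
identity_to_consensus <- function(msa) {
  m <- .msa_matrix(msa)
  consensus <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("-")
    tab <- table(col)
    names(tab)[which.max(tab)]  # ties: first alphabetically (table is sorted)
  })
  per_seq <- apply(m, 1, function(row) {
    keep <- row != "-"
    if (!any(keep)) return(NA_real_)
    mean(row[keep] == consensus[keep])
  })
  list(consensus = paste(consensus, collapse = ""),
       per_sequence = per_seq,
       mean = mean(per_seq, na.rm = TRUE))
}

#' Mean pairwise identity of an alignment
#'
#' All-pairs variant of family identity: for each pair of rows, identity is
#' matches over columns where both are non-gap; the mean over pairs is
#' returned.
#'
#' @inheritParams identity_to_consensus
#' @return Numeric.
#' @export
mean_pairwise_identity <- function(msa) {
  m <- .msa_matrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  ids <- c()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    keep <- m[i, ] != "-" & m[j, ] != "-"
    ids <- c(ids, if (any(keep)) mean(m[i, keep] == m[j, keep]) else NA_real_)
  }
  mean(ids, na.rm = TRUE)
}

.msa_matrix <- function(msa) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  stopifnot(is.character(msa), length(msa) >= 1L)
  msa <- toupper(msa)
  if (length(unique(nchar(msa))) != 1L)
    stop("ragged alignment: all rows must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}
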