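.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(.BASES, n, replace = TRUE, prob = prob[.BASES]), collapse = "")
}

# i.i.d. substitutions at `rate` (to a uniformly drawn different base),
# skipping 1-based positions in `protect`
.mutate <- function(seq, rate, protect = integer(0)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Specification for a synthetic comparative-transcriptome experiment
#'
#' Defines the study conditions the simulator emulates: several species
#' datasets of decoy transcripts, each hiding one planted TR ortholog
#' descended from a common ancestral TR, with a fraction of decoys
#' contaminated by one telomere-like minimal-template permutation (the
#' telomere-like k-mers that make the screen's raw candidate lists large).
#'
#' Defaults model the discovery regime: 4 datasets of 500 decoys (200-600
#' nt, uniform base composition), the 12-bp Allium-type telomere motif with
#' a 1.5-unit template, a 240-nt TR, per-ortholog substitution rate 0.15
#' from the ancestor (so family identity-to-consensus sits in the ~85%
#' regime), 10% decoy contamination, and a mutation-protected template
#' domain (the template is the conserved core of a real TR family, and an
#' intact template is what the screen keys on).
#'
#' @param seed Mandatory integer seed; every stochastic stage derives from it.
#' @param n_datasets Number of species datasets.
#' @param decoys_per_dataset Decoy transcripts per dataset.
#' @param decoy_length Length-2 integer range of decoy lengths (nt).
#' @param background Named base frequencies for decoys and TR spacers.
#' @param motif Telomere motif (unit string or [telomere_motif()]).
#' @param template_span_units Template span in repeat units (>= 1 + 1/L).
#' @param tr_length Planted TR transcript length (nt).
#' @param element_lengths Named lengths of the planted architecture blocks:
#'   `g_rich`, `conserved_box`, `c_rich`, `at_rich`.
#' @param divergence Per-ortholog substitution rate from the ancestral TR.
#' @param contamination Fraction of decoys given one random permutation.
#' @param protect_template Exclude template positions from mutation.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed,
                            n_datasets = 4L,
                            decoys_per_dataset = 500L,
                            decoy_length = c(200L, 600L),
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                            motif = "CTCGGTTATGGG",
                            template_span_units = 1.5,
                            tr_length = 240L,
                            element_lengths = c(g_rich = 20L,
                                                conserved_box = 15L,
                                                c_rich = 20L,
                                                at_rich = 25L),
                            divergence = 0.15,
                            contamination = 0.10,
                            protect_template = TRUE) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  motif <- telomere_motif(motif)
  stopifnot(n_datasets >= 1L, decoys_per_dataset >= 0L,
            length(decoy_length) == 2L, decoy_length[1] <= decoy_length[2],
            divergence >= 0, divergence <= 1,
            contamination >= 0, contamination <= 1,
            all(c("g_rich", "conserved_box", "c_rich", "at_rich") %in%
                  names(element_lengths)))
  if (template_span_units < 1 + 1 / motif$length)
    stop("template must span at least one unit plus one anchor nucleotide",
         call. = FALSE)
  spec <- structure(list(
    seed = as.integer(seed), n_datasets = as.integer(n_datasets),
    decoys_per_dataset = as.integer(decoys_per_dataset),
    decoy_length = as.integer(decoy_length),
    background = background, motif = motif,
    template_span_units = template_span_units,
    tr_length = as.integer(tr_length),
    element_lengths = element_lengths,
    divergence = divergence, contamination = contamination,
    protect_template = isTRUE(protect_template)), class = "simulation_spec")
  .tr_layout(spec)  # validates that the architecture fits
  spec
}

# fixed architecture layout: 0-based half-open intervals within the TR
.tr_layout <- function(spec) {
  L <- spec$motif$length
  tlen <- as.integer(round(spec$template_span_units * L))
  el <- as.integer(spec$element_lengths)
  names(el) <- names(spec$element_lengths)
  lay <- list(
    g_rich = c(10L, 10L + el[["g_rich"]]),
    template = c(60L, 60L + tlen),
    conserved_box = c(60L + tlen, 60L + tlen + el[["conserved_box"]]),
    c_rich = c(spec$tr_length - 70L, spec$tr_length - 70L + el[["c_rich"]]),
    at_rich = c(spec$tr_length - 40L, spec$tr_length - 40L + el[["at_rich"]]))
  ends <- vapply(lay, `[`, integer(1), 2L)
  starts <- vapply(lay, `[`, integer(1), 1L)
  ord <- order(starts)
  if (any(starts < 0L) || any(ends > spec$tr_length) ||
      any(utils::head(ends[ord], -1) > utils::tail(starts[ord], -1)))
    stop("planted architecture does not fit in tr_length ", spec$tr_length,
         call. = FALSE)
  lay
}

#' Simulate stranded transcript datasets with planted TR orthologs
#'
#' Generates one planted TR per dataset (all derived from a common ancestral
#' TR by i.i.d. substitutions at the spec's divergence rate, the template
#' optionally protected) hidden among background decoys, a stated fraction
#' of which carry one random minimal-template permutation. Byte-identical
#' output for identical seeds.
#'
#' @param spec A [simulation_spec()].
#' @param dir If non-`NULL`, write one FASTA per dataset into this directory.
#' @return List: `datasets` (named list of named sequence vectors),
#'   `truth` (list: `tr` data.frame with the planted id and 0-based element
#'   intervals per dataset; `decoys` data.frame with contamination truth),
#'   `ancestor` (ancestral TR sequence), `layout`, `spec`, and `files` when
#'   `dir` was given.
#' @export
simulate_datasets <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  lay <- .tr_layout(spec)
  L <- spec$motif$length
  tlen <- lay$template[2] - lay$template[1]
  perms <- template_permutations(spec$motif, 1L)
  withr::with_seed(spec$seed, {
    # ancestral TR: background backbone, architecture blocks overwritten
    chars <- strsplit(.rand_seq(spec$tr_length, spec$background), "",
                      fixed = TRUE)[[1]]
    put <- function(iv, s) {
      chars[(iv[1] + 1L):iv[2]] <<- strsplit(s, "", fixed = TRUE)[[1]]
    }
    put(lay$g_rich, .rand_seq(lay$g_rich[2] - lay$g_rich[1],
                              c(A = 0.1, C = 0.1, G = 0.7, T = 0.1)))
    cu <- c_strand_unit(spec$motif)
    put(lay$template, substr(strrep(cu, ceiling(tlen / L) + 1L), 1L, tlen))
    put(lay$conserved_box,
        .rand_seq(lay$conserved_box[2] - lay$conserved_box[1],
                  spec$background))
    put(lay$c_rich, .rand_seq(lay$c_rich[2] - lay$c_rich[1],
                              c(A = 0.1, C = 0.7, G = 0.1, T = 0.1)))
    put(lay$at_rich, .rand_seq(lay$at_rich[2] - lay$at_rich[1],
                               c(A = 0.425, C = 0.075, G = 0.075, T = 0.425)))
    ancestor <- paste(chars, collapse = "")

    protect <- if (spec$protect_template)
      (lay$template[1] + 1L):lay$template[2] else integer(0)

    datasets <- list(); tr_rows <- list(); decoy_rows <- list()
    for (d in seq_len(spec$n_datasets)) {
      ds <- sprintf("sp%d", d)
      tr_seq <- .mutate(ancestor, spec$divergence, protect)
      n_dec <- spec$decoys_per_dataset
      lens <- sample(seq.int(spec$decoy_length[1], spec$decoy_length[2]),
                     n_dec, replace = TRUE)
      decoys <- vapply(lens, .rand_seq, character(1), prob = spec$background)
      contam <- stats::runif(n_dec) < spec$contamination
      perm_used <- rep(NA_character_, n_dec)
      perm_pos <- rep(NA_integer_, n_dec)
      for (i in which(contam)) {
        p <- sample(perms, 1L)
        pos <- sample.int(lens[i] - nchar(p) + 1L, 1L)  # 1-based
        substr(decoys[i], pos, pos + nchar(p) - 1L) <- p
        perm_used[i] <- p
        perm_pos[i] <- pos - 1L
      }
      seqs <- c(decoys, tr_seq)
      ord <- sample.int(length(seqs))   # hide the TR at a random index
      seqs <- seqs[ord]
      ids <- sprintf("%s_tx%05d", ds, seq_along(seqs))
      names(seqs) <- ids
      tr_id <- ids[which(ord == length(ord))]
      datasets[[ds]] <- seqs
      tr_rows[[ds]] <- data.frame(
        dataset = ds, id = tr_id,
        template_start = lay$template[1], template_end = lay$template[2],
        g_rich_start = lay$g_rich[1], g_rich_end = lay$g_rich[2],
        conserved_box_start = lay$conserved_box[1],
        conserved_box_end = lay$conserved_box[2],
        c_rich_start = lay$c_rich[1], c_rich_end = lay$c_rich[2],
        at_rich_start = lay$at_rich[1], at_rich_end = lay$at_rich[2],
        stringsAsFactors = FALSE)
      decoy_ids <- ids[match(seq_len(n_dec), ord)]
      decoy_rows[[ds]] <- data.frame(
        dataset = rep(ds, n_dec), id = decoy_ids, contaminated = contam,
        permutation = perm_used, position = perm_pos,
        stringsAsFactors = FALSE)
    }
  })
  out <- list(datasets = datasets,
              truth = list(tr = do.call(rbind, c(tr_rows,
                                                 make.row.names = FALSE)),
                           decoys = do.call(rbind, c(decoy_rows,
                                                     make.row.names = FALSE))),
              ancestor = ancestor, layout = lay, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$files <- vapply(names(datasets), function(ds) {
      f <- file.path(dir, paste0(ds, ".fasta"))
      write_fasta(datasets[[ds]], f)
      f
    }, character(1))
  }
  out
}

#' Simulate reads over a transcript
#'
#' Uniform start positions (truncated so every read fits), strand flipped
#' with probability 0.5, fixed quality. Feeds [end_support()].
#'
#' @param transcript Transcript sequence.
#' @param n Number of reads (> 0).
#' @param read_len Read length (<= transcript length).
#' @param seed Integer seed.
#' @return Named character vector of read sequences (names `read1`, ...).
#' @export
simulate_reads <- function(transcript, n, read_len, seed) {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  transcript <- toupper(transcript)
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (read_len > nchar(transcript))
    stop("read_len exceeds transcript length", call. = FALSE)
  withr::with_seed(seed, {
    starts <- sample.int(nchar(transcript) - read_len + 1L, n, replace = TRUE)
    reads <- substring(transcript, starts, starts + read_len - 1L)
    flip <- stats::runif(n) < 0.5
    reads[flip] <- vapply(reads[flip], reverse_complement, character(1))
  })
  names(reads) <- sprintf("read%d", seq_len(n))
  reads
}

#' Simulate sequenced TRAP products
#'
#' Products are substrate primer + k tandem repeat units + the reverse
#' complement of the reverse primer, with k drawn as 1 plus a geometric
#' variable (mean `mean_units`). Each unit independently carries one planted
#' substitution with probability `variant_prob`. Default primers are
#' synthetic examples; supply the assay's real primers in practice.
#'
#' @param n Number of products.
#' @param motif Telomere motif.
#' @param substrate_primer,reverse_primer Primer sequences.
#' @param mean_units Mean repeat-unit count (>= 1).
#' @param variant_prob Per-unit probability of one substitution.
#' @param seed Integer seed.
#' @return List: `products` (named character vector) and `truth`
#'   (data.frame: `id`, `n_units`, `n_variant`).
#' @export
simulate_trap_products <- function(n, motif = "TTTAGGG",
                                   substrate_primer = "GACGAGTCATCGAGCAGAGT",
                                   reverse_primer = "TGCTAGCGTACTGAGGATCC",
                                   mean_units = 5, variant_prob = 0.2,
                                   seed) {
  motif <- telomere_motif(motif)
  stopifnot(mean_units >= 1, n >= 1L)
  unit <- motif$display_form
  L <- motif$length
  rc_rev <- reverse_complement(toupper(reverse_primer))
  withr::with_seed(seed, {
    ks <- 1L + stats::rgeom(n, prob = 1 / mean_units)
    products <- character(n)
    n_var <- integer(n)
    for (i in seq_len(n)) {
      units <- rep(unit, ks[i])
      vari <- which(stats::runif(ks[i]) < variant_prob)
      for (j in vari) {
        pos <- sample.int(L, 1L)
        old <- substr(units[j], pos, pos)
        substr(units[j], pos, pos) <- sample(setdiff(.BASES, old), 1L)
      }
      n_var[i] <- length(vari)
      products[i] <- paste0(toupper(substrate_primer),
                            paste(units, collapse = ""), rc_rev)
    }
  })
  names(products) <- sprintf("product%d", seq_len(n))
  list(products = products,
       truth = data.frame(id = names(products), n_units = ks,
                          n_variant = n_var, stringsAsFactors = FALSE))
}

#' Simulate a TRF intensity profile
#'
#' Discretized log-normal fragment-size distribution with known median,
#' sampled on a linear size grid, plus an optional constant background
#' offset. Deterministic for `noise_sd = 0`.
#'
#' @param median_bp True median telomere length (bp).
#' @param sdlog Log-scale standard deviation of the distribution.
#' @param n_bins Number of grid points.
#' @param size_range Length-2 size grid range (bp).
#' @param background Constant offset added to every intensity.
#' @param noise_sd Multiplicative log-normal noise (requires `seed`).
#' @param seed Seed, needed only when `noise_sd > 0`.
#' @return Data.frame: `size`, `intensity`.
#' @export
simulate_trf_profile <- function(median_bp = 3000, sdlog = 0.3,
                                 n_bins = 200L, size_range = c(500, 10000),
                                 background = 0, noise_sd = 0, seed = NULL) {
  sizes <- seq(size_range[1], size_range[2], length.out = n_bins)
  intensity <- stats::dlnorm(sizes, meanlog = log(median_bp), sdlog = sdlog)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("noise requires a seed", call. = FALSE)
    withr::with_seed(seed, {
      intensity <- intensity * exp(stats::rnorm(n_bins, 0, noise_sd))
    })
  }
  data.frame(size = sizes, intensity = intensity + background)
}

#' Simulate TRAP products and a TRF profile together
#'
#' Convenience wrapper pairing [simulate_trap_products()] with
#' [simulate_trf_profile()] under one seed.
#'
#' @inheritParams simulate_trap_products
#' @inheritParams simulate_trf_profile
#' @return List with elements `trap` and `trf`.
#' @export
simulate_trap_and_trf <- function(n = 100L, motif = "TTTAGGG",
                                  median_bp = 3000, seed) {
  list(trap = simulate_trap_products(n, motif, seed = seed),
       trf = simulate_trf_profile(median_bp = median_bp))
}

#' Simulate TR gene loci with promoter and terminator context
#'
#' Builds full gene models around planted TR transcripts: an upstream region
#' carrying a USE (upstream sequence element) site and a TATA box at fixed
#' offsets, and a downstream region carrying a poly-T Pol III terminator.
#' USE sites are degenerate copies of a fixed 10-nt consensus (one random
#' substitution per site with probability `use_variant_prob`), so a PWM
#' built from the emitted sites has realistic column entropy.
#'
#' @param n Number of genes.
#' @param seed Integer seed.
#' @param spec A [simulation_spec()] describing the transcript architecture;
#'   defaults to `simulation_spec(seed, n_datasets = 1)`.
#' @param upstream_len,downstream_len Context lengths (nt).
#' @param use_offset,tata_offset 0-based offsets of the planted USE and TATA
#'   within the upstream region.
#' @param terminator_offset 0-based offset of the planted T-run downstream.
#' @param terminator_t Length of the planted T-run.
#' @param use_variant_prob Per-site probability of one USE substitution.
#' @return List of `n` gene records, each a list with `upstream`,
#'   `transcript`, `downstream`, `use_site`, and `truth` (planted 0-based
#'   intervals).
#' @export
simulate_tr_genes <- function(n = 1L, seed, spec = NULL,
                              upstream_len = 100L, downstream_len = 60L,
                              use_offset = 15L, tata_offset = 65L,
                              terminator_offset = 20L, terminator_t = 6L,
                              use_variant_prob = 0.2) {
  use_consensus <- "TCCCACATCG"
  if (is.null(spec)) spec <- simulation_spec(seed, n_datasets = 1L,
                                             decoys_per_dataset = 0L)
  lay <- .tr_layout(spec)
  withr::with_seed(seed, {
    genes <- vector("list", n)
    for (g in seq_len(n)) {
      sim_seed <- sample.int(.Machine$integer.max, 1L)
      sub <- spec; sub$seed <- sim_seed
      tx <- simulate_datasets(sub)$datasets[[1]]
      tx <- tx[[length(tx)]]  # the planted TR is the only guaranteed record
      up <- .rand_seq(upstream_len, spec$background)
      use_site <- use_consensus
      if (stats::runif(1) < use_variant_prob) {
        pos <- sample.int(nchar(use_site), 1L)
        old <- substr(use_site, pos, pos)
        substr(use_site, pos, pos) <- sample(setdiff(.BASES, old), 1L)
      }
      substr(up, use_offset + 1L, use_offset + nchar(use_site)) <- use_site
      substr(up, tata_offset + 1L, tata_offset + 6L) <- "TATAAA"
      down <- .rand_seq(downstream_len, spec$background)
      substr(down, terminator_offset + 1L,
             terminator_offset + terminator_t) <- strrep("T", terminator_t)
      genes[[g]] <- list(
        upstream = up, transcript = tx, downstream = down,
        use_site = use_site,
        truth = list(use = c(use_offset, use_offset + nchar(use_consensus)),
                     tata = c(tata_offset, tata_offset + 6L),
                     terminator = c(terminator_offset,
                                    terminator_offset + terminator_t),
                     layout = lay))
    }
  })
  genes
}
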