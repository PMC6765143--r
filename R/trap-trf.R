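.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Decompose a sequenced TRAP product
#'
#' Parses a cloned-and-sequenced TRAP (telomere repeat amplification
#' protocol) product into substrate primer + tandem telomere repeat units +
#' optional trailing partial unit + reverse-primer segment. After locating
#' the substrate primer at the product start (at most 1 mismatch), units are
#' parsed greedily left to right: each length-L window is compared against
#' all rotations of the G-strand repeat unit and the rotation with fewest
#' mismatches is accepted if within `max_mismatch_per_unit`; mismatch ties
#' prefer the rotation continuing the phase of the previous unit (tandem
#' repeats keep phase). Parsing stops at the reverse complement of the
#' reverse primer (at most 1 mismatch) or at the end of the sequence.
#'
#' @param product Sequenced product (DNA string).
#' @param substrate_primer Substrate (forward) primer sequence.
#' @param reverse_primer Reverse primer sequence (as primer, 5'->3'; its
#'   reverse complement is searched in the product).
#' @param motif [telomere_motif()] expected in the product.
#' @param max_mismatch_per_unit Mismatch budget per repeat unit (default 1).
#' @return Object of class `trap_decomposition`: `product`,
#'   `primer_interval` (0-based half-open), `units` (data.frame: `start`,
#'   `sequence`, `rotation`, `mismatches`), `n_complete_units`,
#'   `variant_units` (units with >= 1 mismatch), `trailing_partial`,
#'   `reverse_primer_found`, `reverse_primer_segment`. The concatenation
#'   primer + units + partial + reverse-primer segment reconstructs the
#'   input exactly.
#' @export
parse_trap_product <- function(product, substrate_primer, reverse_primer,
                               motif, max_mismatch_per_unit = 1L) {
  stopifnot(is.character(product), length(product) == 1L)
  if (nchar(product) == 0L) stop("empty product", call. = FALSE)
  product <- toupper(product)
  substrate_primer <- toupper(substrate_primer)
  reverse_primer <- toupper(reverse_primer)
  motif <- telomere_motif(motif)
  np <- nchar(substrate_primer)
  if (nchar(product) < np ||
      .hamming(substr(product, 1L, np), substrate_primer) > 1L)
    stop("primer not located at product start", call. = FALSE)

  L <- motif$length
  # rotations in circular order starting from the display spelling
  rots <- .rotations(motif$display_form)
  rc_rev <- reverse_complement(reverse_primer)
  nr <- nchar(rc_rev)

  pos <- np + 1L                    # 1-based parse position
  n <- nchar(product)
  units <- list()
  trailing <- ""
  rp_found <- FALSE
  rp_segment <- ""
  prev_rot <- 1L
  while (pos <= n) {
    remaining <- n - pos + 1L
    if (remaining >= nr &&
        .hamming(substr(product, pos, pos + nr - 1L), rc_rev) <= 1L) {
      rp_found <- TRUE
      rp_segment <- substr(product, pos, n)
      pos <- n + 1L
      break
    }
    if (remaining < L) {
      trailing <- substr(product, pos, n)
      pos <- n + 1L
      break
    }
    win <- substr(product, pos, pos + L - 1L)
    mm <- vapply(rots, .hamming, numeric(1), a = win)
    best <- min(mm)
    if (best > max_mismatch_per_unit) {
      trailing <- substr(product, pos, n)
      pos <- n + 1L
      break
    }
    tied <- which(mm == best)
    rot <- if (prev_rot %in% tied) prev_rot else tied[1]
    units[[length(units) + 1L]] <- data.frame(
      start = pos - 1L, sequence = win, rotation = rots[rot],
      mismatches = as.integer(best), stringsAsFactors = FALSE)
    prev_rot <- rot
    pos <- pos + L
  }
  units <- if (length(units) > 0L) do.call(rbind, units) else
    data.frame(start = integer(), sequence = character(),
               rotation = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  structure(list(
    product = product,
    primer_interval = c(0L, np),
    units = units,
    n_complete_units = nrow(units),
    variant_units = sum(units$mismatches > 0L),
    trailing_partial = trailing,
    reverse_primer_found = rp_found,
    reverse_primer_segment = rp_segment), class = "trap_decomposition")
}

#' @export
print.trap_decomposition <- function(x, ...) {
  cat("TRAP product (", nchar(x$product), " nt): ",
      x$n_complete_units, " repeat units (", x$variant_units, " variant)",
      if (nzchar(x$trailing_partial))
        paste0(" + partial '", x$trailing_partial, "'"),
      if (x$reverse_primer_found) " + reverse primer", "\n", sep = "")
  invisible(x)
}

#' Periodicity of a TRAP ladder
#'
#' TRAP products form a ladder whose step equals the telomere repeat length.
#' Returns the most frequent positive difference between successive sorted
#' unique product lengths (ties broken towards the smallest difference).
#'
#' @param product_lengths Integer vector of product lengths (>= 3 values).
#' @return Integer periodicity.
#' @examples
#' ladder_periodicity(c(50, 62, 74, 86)) # 12
#' @export
ladder_periodicity <- function(product_lengths) {
  if (length(product_lengths) < 3L)
    stop("need at least 3 product lengths", call. = FALSE)
  u <- sort(unique(as.integer(product_lengths)))
  if (length(u) < 2L)
    stop("need at least 2 distinct product lengths", call. = FALSE)
  d <- diff(u)
  tab <- table(d)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' Weighted median telomere length from a TRF profile
#'
#' Summarizes a terminal restriction fragment (TRF) Southern intensity
#' profile as the weighted median fragment size: the smallest size at which
#' the cumulative normalized weight reaches 0.5. By default intensities are
#' molar-corrected (weight = intensity / size), compensating for the
#' fact that longer fragments carry proportionally more label; set
#' `length_correction = FALSE` to weight by raw intensity.
#'
#' @param profile Data.frame (or 2-column matrix) with columns `size`
#'   (bp, strictly increasing) and `intensity` (non-negative).
#' @param length_correction Apply molar correction (default `TRUE`).
#' @param background Constant background intensity subtracted (clamped at 0)
#'   before weighting.
#' @return Weighted median telomere length in bp.
#' @examples
#' trf_weighted_median(data.frame(size = 3000, intensity = 7)) # 3000
#' @export
trf_weighted_median <- function(profile, length_correction = TRUE,
                                background = 0) {
  profile <- as.data.frame(profile)
  if (!all(c("size", "intensity") %in% names(profile))) {
    stopifnot(ncol(profile) >= 2L)
    names(profile)[1:2] <- c("size", "intensity")
  }
  size <- as.numeric(profile$size)
  intensity <- as.numeric(profile$intensity)
  stopifnot(length(size) >= 1L, all(!is.na(size)), all(!is.na(intensity)))
  if (any(diff(size) <= 0))
    stop("profile sizes must be strictly increasing", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  intensity <- pmax(intensity - background, 0)
  if (sum(intensity) <= 0)
    stop("profile has no intensity after background subtraction", call. = FALSE)
  w <- if (length_correction) intensity / size else intensity
  cum <- cumsum(w) / sum(w)
  size[which(cum >= 0.5)[1]]
}
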