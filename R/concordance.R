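#' Pair of aligned scaffold sequences with a repeat mask
#'
#' @param seq1,seq2 aligned sequences of equal length over
#'   `A/C/G/T/N/-`, as single strings or character vectors.
#' @param mask optional data frame of repeat intervals (`start`, `end`,
#'   0-based half-open, in alignment columns).
#' @return object of class `"alignment_pair"`.
#' @export
alignment_pair <- function(seq1, seq2, mask = NULL) {
  tochar <- function(s) {
    if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1]]
    toupper(as.character(s))
  }
  a <- tochar(seq1)
  b <- tochar(seq2)
  if (length(a) != length(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(a, b)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("invalid alignment characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(mask)) {
    stopifnot(all(c("start", "end") %in% names(mask)))
    if (any(mask$start < 0) || any(mask$end > length(a)) ||
        any(mask$end <= mask$start))
      stop("mask intervals out of bounds", call. = FALSE)
  }
  structure(list(seq1 = a, seq2 = b, mask = mask), class = "alignment_pair")
}

#' Read an aligned FASTA pair plus optional BED mask
#'
#' @param fasta path to an aligned FASTA file with exactly two records.
#' @param mask_bed optional BED file of repeat intervals (0-based
#'   half-open, coordinates in alignment columns).
#' @return an [alignment_pair()].
#' @export
read_alignment_pair <- function(fasta, mask_bed = NULL) {
  aln <- ape::read.dna(fasta, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  if (nrow(aln) != 2L)
    stop("alignment FASTA must contain exactly two records", call. = FALSE)
  mask <- if (!is.null(mask_bed)) read_bed(mask_bed) else NULL
  alignment_pair(aln[1, ], aln[2, ], mask)
}

#' Column status of an aligned pair under the masking rules
#'
#' Classifies every alignment column as `match`, `mismatch`, `masked`
#' or `gap`. A column is masked when it falls in a repeat interval,
#' contains an N, or is a mismatch within `gap_flank` alignment columns
#' of the nearest gap column (differences that close to gaps are mostly
#' alignment artefacts, not real variants).
#'
#' @param pair an [alignment_pair()].
#' @param gap_flank masking distance from gap columns, in columns.
#' @return character vector of per-column statuses.
#' @export
mask_alignment <- function(pair, gap_flank = 50) {
  stopifnot(inherits(pair, "alignment_pair"))
  a <- pair$seq1
  b <- pair$seq2
  n <- length(a)
  gap <- a == "-" | b == "-"
  has_n <- a == "N" | b == "N"
  repmask <- rep(FALSE, n)
  if (!is.null(pair$mask))
    for (i in seq_len(nrow(pair$mask)))
      repmask[(pair$mask$start[i] + 1L):pair$mask$end[i]] <- TRUE
  mm <- !gap & a != b
  near_gap <- rep(FALSE, n)
  g <- which(gap)
  if (length(g)) {
    mi <- which(mm)
    if (length(mi)) {
      lo <- findInterval(mi, g)                       # nearest gap at or before
      dl <- ifelse(lo >= 1L, mi - g[pmax(lo, 1L)], Inf)
      dr <- ifelse(lo < length(g), g[pmin(lo + 1L, length(g))] - mi, Inf)
      near_gap[mi] <- pmin(dl, dr) <= gap_flank
    }
  }
  ifelse(gap, "gap",
         ifelse(repmask | has_n | (mm & near_gap), "masked",
                ifelse(mm, "mismatch", "match")))
}

#' Concordance rate in non-overlapping windows
#'
#' Splits the alignment into windows of `window_bp` columns and reports
#' per window the fraction matches / (matches + mismatches); masked and
#' gap columns count toward neither numerator nor denominator, and a
#' window with no informative column is skipped.
#'
#' @param statuses per-column statuses from [mask_alignment()].
#' @param window_bp window size in alignment columns.
#' @return data frame: `start`, `end`, `matches`, `mismatches`,
#'   `concordance`.
#' @export
window_concordance <- function(statuses, window_bp = 10000) {
  check_scalar(window_bp, "window_bp", min = 1, integer = TRUE)
  n <- length(statuses)
  starts <- seq(1L, n, by = window_bp)
  out <- lapply(starts, function(s) {
    e <- min(s + window_bp - 1L, n)
    w <- statuses[s:e]
    m <- sum(w == "match")
    x <- sum(w == "mismatch")
    if (m + x == 0L) return(NULL)
    data.frame(start = s, end = e, matches = m, mismatches = x,
               concordance = m / (m + x))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      matches = integer(0), mismatches = integer(0),
                      concordance = numeric(0))
  out
}
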