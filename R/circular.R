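#' Circular distance between two genome positions
#'
#' Shortest distance between positions `a` and `b` on a circle of length `L`,
#' i.e. `min((a - b) mod L, (b - a) mod L)`. This is the metric underlying
#' every position calculation in the package (distances to ori/ter, residuals,
#' territory geometry).
#'
#' @param a,b Positions in `[0, L)` (vectorized).
#' @param L Circle (genome) length in bp; must be positive.
#' @return Distance(s) in bp, in `[0, floor(L/2)]` for integer inputs.
#' @examples
#' circ_dist(10, 90, 100)  # 20, via the wrap-around arc
#' @export
circ_dist <- function(a, b, L) {
  if (any(L <= 0)) {
    stop("invalid genome: length L must be positive", call. = FALSE)
  }
  d <- (a - b) %% L
  pmin(d, L - d)
}

#' Merge nearby replication-origin annotations
#'
#' Origin databases sometimes annotate a single chromosome with several
#' origin locations. Putative origins separated by at most `gap` bp are
#' treated as parts of one origin, represented by the circular midpoint of
#' the region they span; origins farther apart remain separate.
#'
#' @param positions Numeric vector of origin positions in `[0, L)`.
#' @param L Genome length in bp.
#' @param gap Maximum separation (bp) for two annotations to be merged.
#'   Default 3500.
#' @return Sorted numeric vector of merged origin positions. Merging is
#'   idempotent: applying it to its own output changes nothing.
#' @export
merge_oris <- function(positions, L, gap = 3500) {
  if (length(positions) == 0) return(numeric(0))
  if (any(positions < 0 | positions >= L)) {
    stop("origin positions must lie in [0, L)", call. = FALSE)
  }
  p <- sort(unique(as.numeric(positions)))
  n <- length(p)
  if (n == 1) return(p)
  # circular gap following each position
  gaps <- c(diff(p), (p[1] - p[n]) %% L)
  brk <- which(gaps > gap)
  # all annotations within `gap` of their neighbours: break at the widest arc
  if (length(brk) == 0) brk <- which.max(gaps)
  out <- numeric(0)
  start <- brk[length(brk)] %% n + 1    # first index after the last break
  idx <- ((start - 1 + seq_len(n) - 1) %% n) + 1
  first <- idx[1]
  for (k in seq_len(n)) {
    i <- idx[k]
    if (i %in% brk) {                    # cluster ends here
      span <- (p[i] - p[first]) %% L
      out <- c(out, floor((p[first] + span / 2) %% L))
      if (k < n) first <- idx[k + 1]
    }
  }
  sort(out)
}

#' Derive the replication terminus from the origin
#'
#' The terminus is placed half a genome length away from the origin,
#' reflecting the strong tendency of bacterial replichores to be of equal
#' size.
#'
#' @param ori Origin position in `[0, L)`.
#' @param L Genome length in bp.
#' @return Terminus position `(ori + floor(L/2)) mod L`.
#' @export
derive_ter <- function(ori, L) {
  (ori + L %/% 2) %% L
}

#' Construct a circular genome object
#'
#' The central domain type: a circular nucleotide sequence together with the
#' replication origin and terminus that frame all position calculations.
#'
#' @param id Genome identifier.
#' @param seq Nucleotide sequence (single string over A/C/G/T/N; lower case
#'   is accepted and normalized).
#' @param ori Origin position in `[0, L)`, 0-based, or `NA` if unknown.
#' @param ter Terminus position; if `NULL` and `ori` is known, it is derived
#'   as the antipodal position via [derive_ter()].
#' @param clade Optional clade label.
#' @return An object of class `circular_genome` with fields `id`, `seq`,
#'   `L`, `ori`, `ter`, `clade`.
#' @export
circular_genome <- function(id, seq, ori = NA, ter = NULL, clade = NULL) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L < 1) stop("invalid genome: empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  ori <- as.numeric(ori)
  if (!is.na(ori)) {
    if (ori < 0 || ori >= L) stop("ori must lie in [0, L)", call. = FALSE)
    if (is.null(ter)) ter <- derive_ter(ori, L)
    if (ter < 0 || ter >= L) stop("ter must lie in [0, L)", call. = FALSE)
  } else {
    ter <- if (is.null(ter)) NA_real_ else as.numeric(ter)
  }
  structure(
    list(id = as.character(id), seq = seq, L = L, ori = ori,
         ter = as.numeric(ter), clade = clade),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, ori=%s, ter=%s%s\n",
              x$id, x$L,
              ifelse(is.na(x$ori), "?", format(x$ori)),
              ifelse(is.na(x$ter), "?", format(x$ter)),
              if (!is.null(x$clade)) paste0(", clade=", x$clade) else ""))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' @param s Sequence string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", s))))
}

# Circular substring: `len` bases starting at 0-based position `from`,
# wrapping past the end of the sequence if needed.
substr_circ <- function(s, from, len) {
  L <- nchar(s)
  from <- from %% L
  if (len <= 0) return("")
  if (from + len <= L) {
    substr(s, from + 1, from + len)
  } else {
    paste0(substr(s, from + 1, L), substr(s, 1, from + len - L))
  }
}

# Midpoint of genes stored as 0-based half-open (start, end) intervals that
# may wrap the coordinate origin.
gene_midpoint <- function(start, end, L) {
  len <- (end - start) %% L
  (start + len %/% 2) %% L
}
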