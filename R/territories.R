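#' Split a multi-origin genome into ori- or ter-centered territories
#'
#' In archaea with several replication origins, termini are placed at the
#' circular midpoints of the arcs between adjacent origins (synchronously
#' firing origins with equal fork speed meet halfway). Ori-centered
#' territories are bounded by the flanking termini and then trimmed so both
#' replichore arms have equal length; ter-centered territories are bounded
#' by the flanking origins and left untrimmed, so they tile the genome
#' exactly once.
#'
#' @param g The [circular_genome()].
#' @param oris Numeric vector of at least two origin positions.
#' @param kind `"ori"` or `"ter"`.
#' @return `data.frame` with one row per territory: `genome_id`,
#'   `center_kind`, `center`, `start`, `end` (0-based half-open on the
#'   parent circle, possibly wrapping), `length`, `parent_L`, `seq`
#'   (linearized subsequence).
#' @export
split_territories <- function(g, oris, kind = c("ori", "ter")) {
  kind <- match.arg(kind)
  oris <- sort(unique(oris %% g$L))
  n <- length(oris)
  if (n < 2) {
    stop("single-origin genome: use the whole-genome pipeline instead",
         call. = FALSE)
  }
  nxt <- c(oris[-1], oris[1])
  arc <- (nxt - oris) %% g$L
  arc[arc == 0] <- g$L                 # only possible if n == 1, guarded above
  ters <- (oris + arc %/% 2) %% g$L

  if (kind == "ter") {
    start <- oris
    end <- nxt
    center <- ters
    len <- arc
  } else {
    prev_ter <- c(ters[n], ters[-n])
    d_left <- (oris - prev_ter) %% g$L
    d_right <- (ters - oris) %% g$L
    m <- pmin(d_left, d_right)
    start <- (oris - m) %% g$L
    end <- (oris + m) %% g$L
    center <- oris
    len <- 2 * m
  }
  seqs <- vapply(seq_len(n),
                 function(k) substr_circ(g$seq, start[k], len[k]),
                 character(1))
  data.frame(genome_id = g$id, center_kind = kind, center = center,
             start = start, end = end, length = len, parent_L = g$L,
             seq = seqs, stringsAsFactors = FALSE)
}

#' Pair homologous territories between two taxa
#'
#' Homologous territories are the cross pairs carrying the most MUM hits to
#' each other, under the constraint that their lengths differ by at most
#' `max_len_diff` bp. Pairs are selected greedily by descending MUM count
#' (ties by smallest index pair), each territory used at most once.
#'
#' @param t1s,t2s Territory tables from [split_territories()].
#' @param min_len Minimal MUM length for the counting alignments.
#' @param max_len_diff Maximal admissible length difference (default 10 kb).
#' @param mum_counter Optional `function(seq1, seq2)` returning a MUM count;
#'   defaults to `nrow(find_mums(...))`.
#' @return `data.frame` with `i`, `j` (row indices into `t1s`/`t2s`),
#'   `center1`, `center2`, `mum_count`; zero rows when no pair is
#'   admissible.
#' @export
match_territories <- function(t1s, t2s, min_len = 20, max_len_diff = 10000,
                              mum_counter = NULL) {
  if (is.null(mum_counter)) {
    mum_counter <- function(s1, s2) nrow(find_mums(s1, s2, min_len))
  }
  cand <- expand.grid(i = seq_len(nrow(t1s)), j = seq_len(nrow(t2s)))
  cand <- cand[abs(t1s$length[cand$i] - t2s$length[cand$j]) <= max_len_diff, ,
               drop = FALSE]
  if (nrow(cand) == 0) {
    message("no admissible territory pair within ", max_len_diff,
            " bp length difference")
    return(data.frame(i = integer(0), j = integer(0), center1 = numeric(0),
                      center2 = numeric(0), mum_count = integer(0)))
  }
  cand$mum_count <- mapply(function(i, j) mum_counter(t1s$seq[i], t2s$seq[j]),
                           cand$i, cand$j)
  cand <- cand[order(-cand$mum_count, cand$i, cand$j), , drop = FALSE]
  used1 <- logical(nrow(t1s))
  used2 <- logical(nrow(t2s))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used1[i] && !used2[j]) {
      keep[k] <- TRUE
      used1[i] <- TRUE
      used2[j] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  data.frame(i = sel$i, j = sel$j,
             center1 = t1s$center[sel$i], center2 = t2s$center[sel$j],
             mum_count = sel$mum_count, row.names = NULL)
}

#' Territory-level D statistic
#'
#' Runs the symmetry scan on a pair of linearized territories and measures
#' the distance of the symmetry maximum to the territory's central point or
#' to its counterpart half a territory away (the arc end points), as a
#' fraction of territory length. Like the genome-level D, the value is
#' bounded by 0.25.
#'
#' @param t1,t2 Single territory rows (from [split_territories()]).
#' @param g Grid resolution; `NULL` applies the small-genome refinement.
#' @param min_len Minimal MUM length.
#' @param relax Multiplier on the 40/20 eligibility thresholds (e.g. 0.5
#'   halves them for short territories); default 1 keeps the genome-level
#'   thresholds.
#' @param force Bypass eligibility.
#' @return One-row `data.frame`: `territory1`, `territory2`, `i_star`,
#'   `max_x`, `D`, `n_mums`.
#' @export
territory_d <- function(t1, t2, g = NULL, min_len = 20, relax = 1,
                        force = FALSE) {
  mums <- find_mums(t1$seq, t2$seq, min_len)
  pair <- filter_alignment(mums,
                           min_major = ceiling(40 * relax),
                           min_minor = ceiling(20 * relax))
  m <- symmetry_matrix(pair, t1$length, t2$length, g = g, force = force)
  len <- t1$length
  c_lin <- (t1$center - t1$start) %% t1$parent_L
  anti <- c(c_lin - len / 2, c_lin + len / 2)
  D <- min(abs(m$i_star - c(c_lin, anti))) / len
  data.frame(territory1 = paste0(t1$genome_id, ":", t1$center),
             territory2 = paste0(t2$genome_id, ":", t2$center),
             i_star = m$i_star, max_x = m$max_x, D = D,
             n_mums = nrow(mums), stringsAsFactors = FALSE)
}
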