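# Ori-distance of gene midpoints as a fraction of replichore size (L/2).
ori_dist_fraction <- function(genes, g) {
  mids <- gene_midpoint(genes$start, genes$end, g$L)
  circ_dist(mids, g$ori, g$L) / (g$L / 2)
}

#' Average rRNA distance to the origin (percent of replichore size)
#'
#' Mean circular distance of rRNA gene midpoints to ori, normalized by half
#' the genome length and expressed in percent: 0 means all rRNA at ori, 100
#' all rRNA at ter.
#'
#' @param genes Gene table (0-based half-open; `feature` column).
#' @param g The [circular_genome()] (must carry ori).
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when the
#'   genome has no rRNA annotation.
#' @export
rrna_ori_distance <- function(genes, g) {
  rr <- genes[genes$feature == "rRNA", , drop = FALSE]
  if (nrow(rr) == 0) {
    warning("no rRNA genes annotated; feature is missing, not zero")
    return(NA_real_)
  }
  mean(ori_dist_fraction(rr, g)) * 100
}

#' COG class J enrichment near the origin (Z-score)
#'
#' Compares the mean ori-distance of COG class J genes (translation,
#' ribosomal structure and biogenesis) to that of all COG-annotated genes.
#' Negative Z indicates J genes sit closer to the origin than COG-annotated
#' genes in general, the arrangement expected in fast-growing organisms.
#'
#' The analytic form is `Z = (mean_J - mean_all) / (sd_all / sqrt(n_J))`;
#' the permutation form compares `mean_J` to `B` seeded random subsets of
#' size `n_J` drawn from all COG-annotated genes.
#'
#' @param genes Gene table with a `cog` column (`NA` for unannotated genes).
#' @param g The [circular_genome()].
#' @param method `"analytic"` (deterministic, default) or `"permutation"`.
#' @param B Number of permutations.
#' @param seed Seed for the permutation draw.
#' @return Z-score, or `NA` (with a warning) when there are no J genes or
#'   no distance variance.
#' @export
cog_j_z <- function(genes, g, method = c("analytic", "permutation"),
                    B = 10000, seed = 1) {
  method <- match.arg(method)
  ann <- genes[!is.na(genes$cog), , drop = FALSE]
  if (nrow(ann) < 2) {
    warning("fewer than 2 COG-annotated genes; Z undefined")
    return(NA_real_)
  }
  d <- ori_dist_fraction(ann, g)
  is_j <- ann$cog == "J"
  n_j <- sum(is_j)
  if (n_j == 0) {
    warning("no COG class J genes; Z undefined")
    return(NA_real_)
  }
  mean_j <- mean(d[is_j])
  if (method == "analytic") {
    s <- stats::sd(d)
    if (s == 0) {
      warning("zero distance variance; Z undefined")
      return(NA_real_)
    }
    (mean_j - mean(d)) / (s / sqrt(n_j))
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(B),
                   function(b) mean(d[sample.int(length(d), n_j)]),
                   numeric(1))
    s <- stats::sd(perm)
    if (s == 0) {
      warning("zero permutation variance; Z undefined")
      return(NA_real_)
    }
    (mean_j - mean(perm)) / s
  }
}

#' Fraction of genes on the leading strand
#'
#' Classifies each gene as co-oriented with its replication fork (replichore
#' ori->ter clockwise: `+` strand co-oriented; the other replichore: `-`
#' co-oriented) and applies the majority rule: the strand with more genes is
#' taken to be the leading strand, so the returned fraction is always at
#' least 0.5.
#'
#' @param genes Gene table.
#' @param g The [circular_genome()].
#' @return Proportion in `[0.5, 1]`.
#' @export
leading_fraction <- function(genes, g) {
  if (nrow(genes) == 0) stop("no genes", call. = FALSE)
  mids <- gene_midpoint(genes$start, genes$end, g$L)
  rep1 <- ((mids - g$ori) %% g$L) < ((g$ter - g$ori) %% g$L)
  co <- (rep1 & genes$strand == "+") | (!rep1 & genes$strand == "-")
  p <- mean(co)
  max(p, 1 - p)
}

# Overlapping octamer counts of a linear sequence, indexed 1..4^8 in
# lexicographic (A<C<G<T) order; windows containing non-ACGT bases are
# skipped.
count_octamers <- function(s) {
  v <- encode_dna(s) - 1L            # A,C,G,T -> 0..3; other -> -1
  n <- length(v)
  if (n < 8) return(integer(4^8))
  bad <- v < 0L
  v[bad] <- 0L
  idx <- numeric(n - 7)
  for (k in 0:7) idx <- idx + v[(1 + k):(n - 7 + k)] * 4^(7 - k)
  nbad <- cumsum(c(0L, bad))
  ok <- (nbad[9:(n + 1)] - nbad[1:(n - 7)]) == 0
  tabulate(idx[ok] + 1, nbins = 4^8)
}

decode_octamer <- function(idx0) {
  letters4 <- c("A", "C", "G", "T")
  out <- character(8)
  for (k in 8:1) {
    out[k] <- letters4[idx0 %% 4 + 1]
    idx0 <- idx0 %/% 4
  }
  paste(out, collapse = "")
}

#' Most strand-biased octamer between the two replichores
#'
#' Counts every A/C/G/T octamer (overlapping occurrences) on the forward
#' strand of replichore 1 (ori to ter clockwise) and of replichore 2, and
#' returns the octamer with the largest raw count difference between the two
#' replichores; octamers containing a non-ACGT base never enter the tally.
#' The normalized bias `|c1 - c2| / (c1 + c2)` is reported alongside for
#' cross-genome comparability. Ties on the raw difference are broken by the
#' normalized bias, then alphabetically.
#'
#' @param g The [circular_genome()] (ori/ter required, L >= 16).
#' @return List with `octamer`, `count_rep1`, `count_rep2`, `diff_raw`, and
#'   `bias` (normalized), or `NA` fields (with a warning) when no valid
#'   octamer window exists.
#' @export
octamer_bias <- function(g) {
  if (g$L < 16) stop("genome too short for octamer analysis", call. = FALSE)
  len1 <- (g$ter - g$ori) %% g$L
  c1 <- count_octamers(substr_circ(g$seq, g$ori, len1))
  c2 <- count_octamers(substr_circ(g$seq, g$ter, g$L - len1))
  tot <- c1 + c2
  if (sum(tot) == 0) {
    warning("no valid octamer windows (ambiguous sequence); feature missing")
    return(list(octamer = NA_character_, count_rep1 = NA_integer_,
                count_rep2 = NA_integer_, diff_raw = NA_real_,
                bias = NA_real_))
  }
  d <- abs(c1 - c2)
  bias <- ifelse(tot > 0, d / tot, 0)
  cand <- which(d == max(d))
  cand <- cand[bias[cand] == max(bias[cand])]
  best <- cand[1]                     # lexicographically smallest octamer
  list(octamer = decode_octamer(best - 1),
       count_rep1 = c1[best], count_rep2 = c2[best],
       diff_raw = d[best], bias = bias[best])
}

#' GC skew profile and cumulative skew range
#'
#' Per-window skew `(G - C) / (G + C)` starting at the origin (0 where a
#' window has no G or C), the cumulative skew trace, and its range
#' `delta = max(trace) - min(trace)`. In genomes with pronounced
#' leading/lagging composition bias the trace peaks near the terminus, and
#' delta serves as a diagnostic for how sharply nucleotide skew marks the
#' replichore structure.
#'
#' @param g The [circular_genome()] (ori required).
#' @param window Window size in bp (>= 1); default 10 kb.
#' @return List with `skew` (per window), `cumulative`, `delta`, `window`.
#' @export
gc_skew_profile <- function(g, window = 10000) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  s <- substr_circ(g$seq, g$ori, g$L)
  v <- encode_dna(s)
  cg <- cumsum(v == 3L)               # G
  cc <- cumsum(v == 2L)               # C
  edges <- unique(c(seq(0, g$L, by = window), g$L))
  nG <- diff(c(0, cg[edges[-1]]))
  nC <- diff(c(0, cc[edges[-1]]))
  tot <- nG + nC
  skew <- ifelse(tot > 0, (nG - nC) / tot, 0)
  trace <- cumsum(skew)
  list(skew = skew, cumulative = trace,
       delta = max(trace) - min(trace), window = window)
}

#' Compute all architecture features for one genome
#'
#' @param genes Gene table for the genome.
#' @param g The [circular_genome()].
#' @param skew_window Window for [gc_skew_profile()].
#' @return One-row `data.frame`: `genome_id`, `rrna_dist_pct`, `cog_j_z`,
#'   `leading_fraction`, `octamer`, `octamer_bias_raw`, `octamer_bias_norm`,
#'   `delta_gc_skew`.
#' @export
genome_features <- function(genes, g, skew_window = 10000) {
  ob <- octamer_bias(g)
  data.frame(
    genome_id = g$id,
    rrna_dist_pct = suppressWarnings(rrna_ori_distance(genes, g)),
    cog_j_z = suppressWarnings(cog_j_z(genes, g)),
    leading_fraction = leading_fraction(genes, g),
    octamer = ob$octamer,
    octamer_bias_raw = ob$diff_raw,
    octamer_bias_norm = ob$bias,
    delta_gc_skew = gc_skew_profile(g, skew_window)$delta,
    stringsAsFactors = FALSE
  )
}

#' Correlate architecture features with median D across genomes
#'
#' Spearman rank correlation (two-sided) of each numeric feature against
#' per-genome median D, dropping genomes with a missing value pairwise.
#'
#' @param features Data frame with `genome_id` and feature columns.
#' @param medians Data frame with `genome_id` and `median_d`.
#' @param feature_cols Feature columns to test; defaults to the four
#'   ori-ter-linked covariates.
#' @return `data.frame` with `feature`, `n`, `rho`, `p`.
#' @export
feature_d_correlation <- function(features, medians,
                                  feature_cols = c("rrna_dist_pct",
                                                   "cog_j_z",
                                                   "leading_fraction",
                                                   "octamer_bias_norm")) {
  joined <- merge(features, medians, by = "genome_id")
  if (nrow(joined) < 4) {
    stop("insufficient data: need >= 4 genomes with features and median D",
         call. = FALSE)
  }
  rows <- lapply(feature_cols, function(fc) {
    ok <- stats::complete.cases(joined[[fc]], joined$median_d)
    if (sum(ok) < 4) {
      return(data.frame(feature = fc, n = sum(ok), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(joined[[fc]][ok], joined$median_d[ok],
                      method = "spearman", exact = FALSE)
    )
    data.frame(feature = fc, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
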