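#' Read a PHYLIP square distance matrix
#'
#' Whitespace-tokenized square format: a leading taxon count, then one row
#' per taxon (name followed by all n distances; rows may wrap over lines).
#' The matrix must have a zero diagonal and be symmetric within `tol`.
#'
#' @param path Path to the file.
#' @param tol Symmetry tolerance.
#' @return Numeric matrix with taxon ids as dimnames.
#' @export
read_phylip_square <- function(path, tol = 1e-8) {
  tokens <- scan(path, what = character(), quiet = TRUE)
  if (length(tokens) < 1) stop("empty distance file", call. = FALSE)
  n <- suppressWarnings(as.integer(tokens[1]))
  if (is.na(n) || n < 1) {
    stop("parse error: bad taxon count '", tokens[1], "'", call. = FALSE)
  }
  need <- 1 + n * (n + 1)
  if (length(tokens) != need) {
    stop("parse error: expected ", need, " tokens for ", n,
         " taxa, found ", length(tokens), call. = FALSE)
  }
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  pos <- 2
  for (r in seq_len(n)) {
    ids[r] <- tokens[pos]
    vals <- suppressWarnings(as.numeric(tokens[pos + seq_len(n)]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("parse error in row ", r, " ('", ids[r], "'): non-numeric '",
           tokens[pos + bad], "'", call. = FALSE)
    }
    m[r, ] <- vals
    pos <- pos + n + 1
  }
  if (any(abs(diag(m)) > tol)) {
    stop("parse error: nonzero self-distance for taxon '",
         ids[which(abs(diag(m)) > tol)[1]], "'", call. = FALSE)
  }
  if (any(abs(m - t(m)) > tol)) {
    stop("parse error: matrix asymmetric beyond tolerance ", tol,
         call. = FALSE)
  }
  if (any(m < 0)) stop("parse error: negative distance", call. = FALSE)
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a PHYLIP square distance matrix
#'
#' @param m Square numeric matrix with taxon ids as dimnames.
#' @param path Output path.
#' @export
write_phylip_square <- function(m, path) {
  n <- nrow(m)
  lines <- c(format(n),
             vapply(seq_len(n), function(r) {
               paste(c(rownames(m)[r], format(m[r, ], digits = 10)),
                     collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Distance-matched subsampling of genome pairs
#'
#' Renders D-score distributions comparable between clades by subsampling
#' each clade's genome pairs to match a common template of phylogenetic
#' (16S) distances. The template is binned into `n_bins` equal-width bins
#' over its range; within each clade, pairs are drawn per bin without
#' replacement so that the sampled bin counts are exactly `M` times the
#' template's bin counts, where `M` is the largest integer multiple the
#' clade can satisfy in every nonempty template bin. Pairs with distances
#' outside the template range are never sampled.
#'
#' @param pairs Data frame of pair records with columns `clade`, `distance`
#'   (and typically `focal`, `partner`, `D`).
#' @param template Numeric vector of template distances.
#' @param n_bins Number of equal-width bins (default 20).
#' @param seed Integer seed; the draw is reproducible per seed.
#' @return Subset of `pairs` (with a `bin` column); clades that cannot
#'   cover every nonempty template bin are returned empty with a warning.
#' @export
subsample_matched <- function(pairs, template, n_bins = 20, seed = 1) {
  if (length(template) == 0) stop("empty distance template", call. = FALSE)
  breaks <- seq(min(template), max(template), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) {
    breaks <- c(breaks[1], breaks[1] + 1e-9)
  }
  bin_of <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE)
    b[x < breaks[1] | x > breaks[length(breaks)]] <- NA_integer_
    b
  }
  tcount <- tabulate(bin_of(template), nbins = length(breaks) - 1)
  set.seed(seed)
  out <- list()
  for (cl in sort(unique(pairs$clade))) {
    sub <- pairs[pairs$clade == cl, , drop = FALSE]
    sub$bin <- bin_of(sub$distance)
    sub <- sub[!is.na(sub$bin), , drop = FALSE]
    ccount <- tabulate(sub$bin, nbins = length(tcount))
    need <- tcount > 0
    M <- if (any(need)) min(ccount[need] %/% tcount[need]) else 0
    if (M == 0) {
      warning("clade '", cl, "' cannot match the template in every bin; ",
              "returning no pairs for it")
      next
    }
    for (b in which(need)) {
      rows <- which(sub$bin == b)
      take <- sample(rows, M * tcount[b])
      out[[length(out) + 1]] <- sub[take, , drop = FALSE]
    }
  }
  if (length(out) == 0) {
    res <- pairs[0, , drop = FALSE]
    res$bin <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Table of D against phylogenetic distance
#'
#' Joins D scores to pairwise distances and returns records sorted by
#' distance, ready for plotting D as a function of divergence.
#'
#' @param scores Data frame of D scores (`focal`, `partner`, `D`).
#' @param dist_matrix Distance matrix (as from [read_phylip_square()]).
#' @return `data.frame` with `focal`, `partner`, `distance`, `D`, sorted by
#'   distance. Score rows whose ids are absent from the matrix are dropped
#'   with a warning.
#' @export
d_vs_distance_table <- function(scores, dist_matrix) {
  if (nrow(scores) == 0) stop("no D scores", call. = FALSE)
  ids <- rownames(dist_matrix)
  ok <- scores$focal %in% ids & scores$partner %in% ids
  if (any(!ok)) {
    warning(sum(!ok), " score row(s) with ids missing from the distance ",
            "matrix dropped")
  }
  s <- scores[ok, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(focal = character(0), partner = character(0),
                      distance = numeric(0), D = numeric(0)))
  }
  s$distance <- dist_matrix[cbind(s$focal, s$partner)]
  s <- s[order(s$distance), c("focal", "partner", "distance", "D")]
  rownames(s) <- NULL
  s
}

#' Compare per-clade median D with and without distance filtering
#'
#' Spearman correlation between per-clade median D computed on all pairs
#' and on the 16S-distance-matched subsample, quantifying how robust the
#' clade ranking is to divergence-level sampling.
#'
#' @param unfiltered,filtered Named numeric vectors of per-clade medians
#'   (names are clade labels; only shared clades are compared).
#' @return List with `rho`, `p`, `n`.
#' @export
clade_median_comparison <- function(unfiltered, filtered) {
  shared <- intersect(names(unfiltered), names(filtered))
  if (length(shared) < 4) {
    stop("insufficient data: need >= 4 clades with both medians",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(unfiltered[shared], filtered[shared],
                    method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
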