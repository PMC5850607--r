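#' Forward-arm residual of an alignment point
#'
#' The circular vertical (axis-2) deviation of point `p = (x, y)` from the
#' slope +1 line through `(i, j)`: homologous blocks that have not moved
#' relative to each other lie on this forward arm and have residual 0.
#'
#' @param p Numeric length-2 vector `(x, y)`.
#' @param center Numeric length-2 vector `(i, j)`.
#' @param L1,L2 Genome lengths for the two axes.
#' @return Residual in bp.
#' @export
residual_forward <- function(p, center, L1, L2) {
  circ_dist(p[2], (center[2] + (p[1] - center[1])) %% L2, L2)
}

#' Mirror an alignment point about the vertical axis through i
#'
#' Reflection `x -> (2i - x) mod L1` with `y` unchanged. Applied to a block
#' created by an inversion symmetric about position `i`, this restores
#' collinearity with the forward arm. The operation is an involution.
#'
#' @param p Numeric length-2 vector `(x, y)`.
#' @param i Axis position on genome 1.
#' @param L1 Genome-1 length.
#' @return Mirrored point `(x', y)`.
#' @export
mirror_point <- function(p, i, L1) {
  c((2 * i - p[1]) %% L1, p[2])
}

mum_midpoints <- function(mums, L1, L2) {
  list(px = (mums$x + (mums$len - 1) / 2) %% L1,
       py = (mums$y + (mums$len - 1) / 2) %% L2)
}

#' X-type symmetry score at a single point (reference implementation)
#'
#' Straightforward per-MUM evaluation of the symmetry score
#' `X = [ sum_fwd w (f_m - f) + sum_rev w (r - r_m) ] / sum w`,
#' where `f` (`r`) is the forward-arm residual of a forward (reverse)
#' MUM's midpoint, and `f_m` (`r_m`) is the residual of the same point
#' mirrored about the vertical axis through `i`. Residuals are weighted by
#' MUM length over the minimal MUM length and the score is normalized by
#' total weight so values are comparable across genome pairs.
#'
#' This scalar version is deliberately a plain loop; [symmetry_matrix()]
#' uses a compiled equivalent over the whole grid.
#'
#' @param mums MUM table (non-empty).
#' @param i,j Grid point (bp).
#' @param L1,L2 Genome lengths.
#' @return The symmetry score in bp (weight-normalized).
#' @export
x_score <- function(mums, i, j, L1, L2) {
  if (is.null(mums) || nrow(mums) == 0) {
    stop("undefined score: no MUMs", call. = FALSE)
  }
  mp <- mum_midpoints(mums, L1, L2)
  tot <- 0
  for (m in seq_len(nrow(mums))) {
    p <- c(mp$px[m], mp$py[m])
    f <- residual_forward(p, c(i, j), L1, L2)
    fm <- residual_forward(mirror_point(p, i, L1), c(i, j), L1, L2)
    w <- mums$weight[m]
    tot <- tot + if (mums$orient[m] == "forward") w * (fm - f) else w * (f - fm)
  }
  tot / sum(mums$weight)
}

# Grid resolution rule: 10 kb by default; small genomes refine to keep at
# least ~100 grid columns, with a 1 kb floor.
resolve_grid <- function(L1, L2, g = NULL) {
  refined <- FALSE
  if (is.null(g)) {
    g <- 10000
    Lmin <- min(L1, L2)
    if (Lmin < 100 * g) {
      g <- max(1000, floor(Lmin / 100))
      refined <- TRUE
    }
  }
  if (g < 1) stop("grid resolution must be >= 1 bp", call. = FALSE)
  list(g = g, refined = refined)
}

#' Compute the X-type symmetry matrix over the alignment plane
#'
#' Evaluates the symmetry score at every point of a regular grid covering
#' the `[0, L1) x [0, L2)` alignment plane and records the location of
#' maximal symmetry. The argmax tie-break is deterministic: smallest `i`,
#' then smallest `j`.
#'
#' @param pair An `alignment_pair` from [filter_alignment()], or a raw MUM
#'   table (in which case no eligibility gate is applied).
#' @param L1,L2 Genome lengths (bp).
#' @param g Grid resolution in bp. `NULL` (default) uses 10 kb, refined to
#'   `max(1000, L/100)` for genomes shorter than 1 Mb so the grid keeps at
#'   least ~100 columns; the refinement is flagged in the result.
#' @param force Evaluate even if the pair fails the eligibility filter.
#' @return A `symmetry_matrix` object: `X` (matrix, bp units), `igrid`,
#'   `jgrid`, `g`, `i_star`, `j_star`, `max_x`, total weight `W`, `refined`.
#' @export
symmetry_matrix <- function(pair, L1, L2, g = NULL, force = FALSE) {
  if (inherits(pair, "alignment_pair")) {
    if (!pair$eligible && !force) {
      stop("alignment pair fails the ", pair$min_major, "/", pair$min_minor,
           " MUM eligibility filter (", pair$n_forward, " forward, ",
           pair$n_reverse, " reverse); use force = TRUE to override",
           call. = FALSE)
    }
    mums <- pair$mums
  } else {
    mums <- pair
  }
  if (is.null(mums) || nrow(mums) == 0) {
    stop("undefined score: no MUMs", call. = FALSE)
  }
  res <- resolve_grid(L1, L2, g)
  g <- res$g
  igrid <- g * (seq_len(ceiling(L1 / g)) - 1)
  jgrid <- g * (seq_len(ceiling(L2 / g)) - 1)
  mp <- mum_midpoints(mums, L1, L2)
  sw <- ifelse(mums$orient == "forward", mums$weight, -mums$weight)
  W <- sum(mums$weight)
  X <- xmatrix_cpp(mp$px, mp$py, sw, igrid, jgrid, L1, L2) / W
  mx <- max(X)
  hits <- which(X == mx, arr.ind = TRUE)
  best <- hits[order(hits[, 1], hits[, 2])[1], , drop = FALSE]
  structure(
    list(X = X, igrid = igrid, jgrid = jgrid, g = g, L1 = L1, L2 = L2,
         i_star = igrid[best[1, 1]], j_star = jgrid[best[1, 2]],
         max_x = mx, W = W, n_mums = nrow(mums), refined = res$refined),
    class = "symmetry_matrix"
  )
}

#' @export
print.symmetry_matrix <- function(x, ...) {
  cat(sprintf(paste0("<symmetry_matrix> %d x %d grid at g=%d bp%s; ",
                     "max X=%.2f at (%d, %d); %d MUMs, W=%.1f\n"),
              nrow(x$X), ncol(x$X), x$g,
              if (x$refined) " (refined)" else "",
              x$max_x, x$i_star, x$j_star, x$n_mums, x$W))
  invisible(x)
}

#' Write a symmetry matrix as TSV
#'
#' Rows are genome-1 grid positions, columns genome-2 grid positions,
#' values the symmetry score in bp.
#'
#' @param m `symmetry_matrix` object.
#' @param path Output path.
#' @param comments Extra `#` header lines.
#' @export
write_symmetry_matrix <- function(m, path, comments = character(0)) {
  df <- as.data.frame(m$X)
  names(df) <- as.character(m$jgrid)
  df <- cbind(data.frame(i = m$igrid), df)
  write_tsv(df, path, c(comments,
                        sprintf("grid_bp: %d", m$g),
                        sprintf("refined: %s", m$refined)))
}

#' D statistic: distance of maximal symmetry to the ori-ter axis
#'
#' `D = min(dist(i*, ori), dist(i*, ter)) / L`, where `i*` is the focal-axis
#' position of the symmetry maximum. With the terminus antipodal to the
#' origin, `D` ranges from 0 (inversion history perfectly symmetric about
#' the ori-ter axis) to 0.25 (maximal departure, an axis a quarter genome
#' away).
#'
#' @param m `symmetry_matrix` with the focal genome on axis 1.
#' @param focal The focal [circular_genome()] (must carry ori and ter).
#' @param partner Optional partner genome id for bookkeeping.
#' @return One-row `data.frame`: `focal`, `partner`, `i_star`, `max_x`, `D`.
#' @export
d_score <- function(m, focal, partner = NA_character_) {
  if (is.na(focal$ori) || is.na(focal$ter)) {
    stop("focal genome '", focal$id, "' has no ori/ter coordinates",
         call. = FALSE)
  }
  D <- min(circ_dist(m$i_star, focal$ori, focal$L),
           circ_dist(m$i_star, focal$ter, focal$L)) / focal$L
  data.frame(focal = focal$id, partner = as.character(partner),
             i_star = m$i_star, max_x = m$max_x, D = D,
             stringsAsFactors = FALSE)
}

#' Median D for a focal genome across its pairwise comparisons
#'
#' @param focal_id Focal genome identifier.
#' @param scores Data frame of D scores (columns `focal`, `D`), typically
#'   rbind-ed [d_score()] rows.
#' @return The median D (even counts average the central pair).
#' @export
median_d <- function(focal_id, scores) {
  d <- scores$D[scores$focal == focal_id]
  if (length(d) == 0) {
    stop("no D scores for focal genome '", focal_id, "'", call. = FALSE)
  }
  stats::median(d)
}

#' Analytic upper bound of the D statistic
#'
#' For a terminus exactly antipodal to the origin, the farthest any point on
#' the circle can be from both landmarks is a quarter of the genome, so
#' `max_p min(dist(p, ori), dist(p, ter)) / L = 0.25` for every genome
#' length. This evaluates the bound by exhaustive enumeration of positions
#' on a quarter-unit lattice of the continuous circle (which contains the
#' achieving position `L/4` for every integer `L`).
#'
#' @param L Genome length.
#' @param step Enumeration step in bp (default 0.25).
#' @return The maximum of `min(dist to ori, dist to ter)/L` over the lattice.
#' @export
d_score_bound <- function(L, step = 0.25) {
  p <- seq(0, L - step, by = step)
  max(pmin(circ_dist(p, 0, L), circ_dist(p, L / 2, L)) / L)
}
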