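#' Simulation configuration for inversion divergence
#'
#' @param L Genome length in bp.
#' @param n_inversions Number of sequential inversion events.
#' @param mode Breakpoint model: `"random"` (both breakpoints uniform),
#'   `"symmetric"` (breakpoints equidistant from ori or ter), or `"quasi"`
#'   (symmetric with one breakpoint jittered).
#' @param jitter Maximal breakpoint offset in bp for `mode = "quasi"`;
#'   default 2% of the genome.
#' @param point_mutation_rate Per-bp substitution probability applied after
#'   all inversions (default 0.001), fragmenting exact matches the way
#'   sequence divergence does.
#' @param seed Integer seed; all randomness in [evolve_pair()] flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(L, n_inversions = 50,
                       mode = c("random", "symmetric", "quasi"),
                       jitter = round(0.02 * L),
                       point_mutation_rate = 0.001, seed = 1) {
  mode <- match.arg(mode)
  if (n_inversions < 0) stop("n_inversions must be >= 0", call. = FALSE)
  if (point_mutation_rate < 0 || point_mutation_rate >= 1) {
    stop("point_mutation_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(L = L, n_inversions = n_inversions, mode = mode,
                 jitter = jitter, point_mutation_rate = point_mutation_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random circular genome
#'
#' I.i.d. uniform A/C/G/T sequence with `ori = 0` and the terminus at the
#' antipode, reproducible per seed.
#'
#' @param L Genome length (>= 1).
#' @param seed Integer seed.
#' @return A [circular_genome()].
#' @export
make_genome <- function(L, seed = 1) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  circular_genome(id = sprintf("sim_L%d_s%d", L, as.integer(seed)),
                  seq = seq, ori = 0)
}

#' Construct an inversion event
#'
#' The inverted arc runs clockwise from breakpoint `a` to breakpoint `b`
#' (wrapping past the sequence end when `b <= a`).
#'
#' @param a,b Breakpoint positions in `[0, L)`, `a != b`.
#' @param mode,center,jitter Bookkeeping fields describing how the event was
#'   drawn.
#' @return An `inversion_event` list.
#' @export
inversion_event <- function(a, b, mode = "random", center = "none",
                            jitter = 0) {
  structure(list(a = a, b = b, mode = mode, center = center,
                 jitter = jitter),
            class = "inversion_event")
}

#' Apply one inversion to a genome
#'
#' Replaces the clockwise arc `[a, b)` by its reverse complement; length,
#' ori, and ter are unchanged. Applying the same event twice restores the
#' original sequence.
#'
#' @param g A [circular_genome()].
#' @param ev An [inversion_event()].
#' @return The rearranged genome.
#' @export
apply_inversion <- function(g, ev) {
  L <- g$L
  a <- ev$a %% L
  b <- ev$b %% L
  len <- (b - a) %% L
  if (len == 0) stop("degenerate inversion: a == b", call. = FALSE)
  s <- g$seq
  if (a < b) {
    inv <- revcomp(substr(s, a + 1, b))
    g$seq <- paste0(substr(s, 1, a), inv, substr(s, b + 1, L))
  } else {
    # arc wraps the coordinate origin: [a, L) then [0, b)
    inv <- revcomp(paste0(substr(s, a + 1, L), substr(s, 1, b)))
    head_len <- L - a
    g$seq <- paste0(substr(inv, head_len + 1, len),
                    substr(s, b + 1, a),
                    substr(inv, 1, head_len))
  }
  g
}

#' Draw one inversion event from the configured breakpoint model
#'
#' Uses the current RNG state (seed management belongs to [evolve_pair()]).
#' Random mode draws both breakpoints uniformly; symmetric mode picks ori or
#' ter with equal probability as the inversion center and a half-span
#' uniform on `(1, L/4)`, placing breakpoints equidistant from the center;
#' quasi mode additionally shifts one breakpoint by up to `jitter` bp.
#'
#' @param cfg A [sim_config()]. Centers assume the [make_genome()] frame
#'   (`ori = 0`, `ter = floor(L/2)`).
#' @return An [inversion_event()].
#' @export
sample_event <- function(cfg) {
  L <- cfg$L
  if (cfg$mode == "random") {
    repeat {
      ab <- sample.int(L, 2, replace = TRUE) - 1
      if (ab[1] != ab[2]) break
    }
    return(inversion_event(ab[1], ab[2], mode = "random"))
  }
  center_kind <- sample(c("ori", "ter"), 1)
  center <- if (center_kind == "ori") 0 else L %/% 2
  h <- round(stats::runif(1, 1, L / 4))
  a <- (center - h) %% L
  b <- (center + h) %% L
  if (cfg$mode == "quasi" && cfg$jitter > 0) {
    delta <- round(stats::runif(1, -cfg$jitter, cfg$jitter))
    if (sample(c(TRUE, FALSE), 1)) a <- (a + delta) %% L else b <- (b + delta) %% L
    if (a == b) b <- (b + 1) %% L
  }
  inversion_event(a, b, mode = cfg$mode, center = center_kind,
                  jitter = if (cfg$mode == "quasi") cfg$jitter else 0)
}

#' Evolve a genome pair by inversions and point substitutions
#'
#' Generates an ancestral genome, applies `n_inversions` sequentially drawn
#' events, then overlays i.i.d. point substitutions, returning both genomes
#' and the event log as ground truth. With a substitution rate of zero,
#' replaying the event log on genome 1 reproduces genome 2 exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `g1`, `g2` ([circular_genome()]s) and `events` (list of
#'   [inversion_event()]s).
#' @export
evolve_pair <- function(cfg) {
  g1 <- make_genome(cfg$L, cfg$seed)   # seeds the RNG for the whole run
  g2 <- g1
  g2$id <- paste0(g1$id, "_div")
  events <- vector("list", cfg$n_inversions)
  for (k in seq_len(cfg$n_inversions)) {
    ev <- sample_event(cfg)
    g2 <- apply_inversion(g2, ev)
    events[[k]] <- ev
  }
  if (cfg$point_mutation_rate > 0) {
    hit <- which(stats::runif(cfg$L) < cfg$point_mutation_rate)
    if (length(hit)) {
      v <- encode_dna(g2$seq)                       # 1..4
      v[hit] <- (v[hit] - 1 + sample.int(3, length(hit), replace = TRUE)) %% 4 + 1
      g2$seq <- paste(c("A", "C", "G", "T")[v], collapse = "")
    }
  }
  list(g1 = g1, g2 = g2, events = events)
}

#' Event log as a data frame
#'
#' @param events List of [inversion_event()]s.
#' @return `data.frame` with columns `a`, `b`, `mode`, `center`, `jitter`.
#' @export
event_log <- function(events) {
  data.frame(
    a = vapply(events, `[[`, numeric(1), "a"),
    b = vapply(events, `[[`, numeric(1), "b"),
    mode = vapply(events, `[[`, character(1), "mode"),
    center = vapply(events, `[[`, character(1), "center"),
    jitter = vapply(events, `[[`, numeric(1), "jitter"),
    stringsAsFactors = FALSE
  )
}

#' Generate an annotated gene layout with controlled ori-ter structure
#'
#' Ground-truth generator for the genome-architecture features: places genes
#' with a configurable leading-strand probability, optional clustering of
#' COG class J genes near the origin, and rRNA genes scattered around the
#' origin with configurable spread.
#'
#' @param L Genome length.
#' @param ori Origin position (terminus is the antipode).
#' @param params List overriding any of: `n_genes` (1000), `gene_length`
#'   (900 bp), `leading_prob` (0.8, probability that a gene is co-oriented
#'   with its replication fork), `n_rrna` (7), `rrna_spread` (0.1, sd of
#'   rRNA midpoint around ori as a fraction of L), `frac_cog_j` (0.1,
#'   fraction of CDS assigned COG class J), `j_spread` (`NULL` for J genes
#'   placed like any other gene, or an sd around ori as fraction of L),
#'   `frac_no_cog` (0.1, CDS without COG annotation).
#' @param seed Integer seed.
#' @return Gene `data.frame` (0-based half-open `start`/`end`, `strand`,
#'   `feature`, `cog`).
#' @export
make_annotated_layout <- function(L, ori = 0, params = list(), seed = 1) {
  p <- utils::modifyList(
    list(n_genes = 1000, gene_length = 900, leading_prob = 0.8,
         n_rrna = 7, rrna_spread = 0.1, frac_cog_j = 0.1, j_spread = NULL,
         frac_no_cog = 0.1),
    params
  )
  if (p$n_genes > L) {
    stop("layout error: cannot place ", p$n_genes, " genes on ", L, " bp",
         call. = FALSE)
  }
  set.seed(seed)
  ter <- derive_ter(ori, L)
  n_rrna <- min(p$n_rrna, p$n_genes)
  n_cds <- p$n_genes - n_rrna

  rrna_mid <- (ori + round(stats::rnorm(n_rrna, 0, p$rrna_spread * L))) %% L
  cds_mid <- sample.int(L, n_cds, replace = TRUE) - 1

  n_j <- round(p$frac_cog_j * n_cds)
  cog <- rep(NA_character_, n_cds)
  annotated <- seq_len(round((1 - p$frac_no_cog) * n_cds))
  other_classes <- c("C", "E", "K", "L", "M", "O", "P", "T")
  cog[annotated] <- sample(other_classes, length(annotated), replace = TRUE)
  j_idx <- annotated[seq_len(min(n_j, length(annotated)))]
  cog[j_idx] <- "J"
  if (!is.null(p$j_spread)) {
    cds_mid[j_idx] <- (ori + round(stats::rnorm(length(j_idx), 0,
                                                p$j_spread * L))) %% L
  }

  mids <- c(rrna_mid, cds_mid)
  feature <- c(rep("rRNA", n_rrna), rep("CDS", n_cds))
  cog <- c(rep(NA_character_, n_rrna), cog)

  # fork co-orientation: replichore 1 (ori -> ter clockwise) is co-oriented
  # on '+', replichore 2 on '-'
  rep1 <- ((mids - ori) %% L) < ((ter - ori) %% L)
  lead_strand <- ifelse(rep1, "+", "-")
  co <- stats::runif(p$n_genes) < p$leading_prob
  strand <- ifelse(co, lead_strand, chartr("+-", "-+", lead_strand))

  gl <- min(p$gene_length, L - 1)
  start <- (mids - gl %/% 2) %% L
  end <- (start + gl) %% L
  end[end == 0] <- L

  ord <- order(mids)
  data.frame(start = start, end = end, strand = strand, feature = feature,
             cog = cog, stringsAsFactors = FALSE)[ord, , drop = FALSE]
}

#' Write a simulated pair to disk (FASTAs, event log, ori table)
#'
#' @param pair Result of [evolve_pair()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_pair <- function(pair, prefix) {
  f1 <- paste0(prefix, "_1.fasta")
  f2 <- paste0(prefix, "_2.fasta")
  fe <- paste0(prefix, "_events.tsv")
  fo <- paste0(prefix, "_oris.tsv")
  write_fasta(pair$g1, f1)
  write_fasta(pair$g2, f2)
  write_tsv(event_log(pair$events), fe)
  write_tsv(data.frame(genome_id = c(pair$g1$id, pair$g2$id),
                       ori_pos = c(pair$g1$ori + 1, pair$g2$ori + 1)),
            fo)
  invisible(c(f1, f2, fe, fo))
}
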