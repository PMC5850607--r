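#' End-to-end symmetry pipeline for a genome pair
#'
#' Reads two FASTA genomes and an origin table, finds MUMs, applies the
#' eligibility filter, computes the symmetry matrix and the D score for the
#' focal genome, and writes `mums.tsv`, `matrix.tsv`, and `dscore.tsv` to
#' `outdir`. All outputs carry the run configuration as `#` header lines
#' and are byte-identical across reruns with the same inputs.
#'
#' @param fasta1,fasta2 Paths to single-record FASTA files (genome 1 is the
#'   focal axis unless `focal = 2`).
#' @param ori_table Path to the origin table TSV (`genome_id`, `ori_pos`
#'   1-based); multiple rows per genome are merged with [merge_oris()].
#' @param outdir Output directory (created if needed).
#' @param min_len Minimal MUM length.
#' @param g Grid resolution (`NULL` = default rule).
#' @param focal Which genome (1 or 2) the D score refers to.
#' @param largest Pass-through to [read_fasta()].
#' @param force Bypass the eligibility filter.
#' @param ori_gap Merging threshold for multi-part origins (bp).
#' @return Invisibly, a list with `pair`, `matrix`, `dscore`, and the
#'   output paths.
#' @export
run_pipeline <- function(fasta1, fasta2, ori_table, outdir,
                         min_len = 20, g = NULL, focal = 1,
                         largest = FALSE, force = FALSE, ori_gap = 3500) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g1 <- read_fasta(fasta1, largest = largest)
  g2 <- read_fasta(fasta2, largest = largest)
  oris <- read_ori_table(ori_table)
  for (gm in list(g1, g2)) {
    if (!any(oris$genome_id == gm$id)) {
      stop("no origin entry for genome '", gm$id, "' in ", ori_table,
           call. = FALSE)
    }
  }
  set_ori <- function(gm) {
    pos <- merge_oris(oris$ori[oris$genome_id == gm$id], gm$L, gap = ori_gap)
    if (length(pos) > 1) {
      stop("genome '", gm$id, "' has ", length(pos), " origins after ",
           "merging; use the territory workflow for multi-origin genomes",
           call. = FALSE)
    }
    gm$ori <- pos[1]
    gm$ter <- derive_ter(pos[1], gm$L)
    gm
  }
  g1 <- set_ori(g1)
  g2 <- set_ori(g2)
  if (focal == 2) {
    tmp <- g1; g1 <- g2; g2 <- tmp
  }

  mums <- find_mums(g1, g2, min_len = min_len)
  pair <- filter_alignment(mums, genome1 = g1$id, genome2 = g2$id)
  if (!pair$eligible && !force) {
    warning("pair ", g1$id, " / ", g2$id, " fails the ", pair$min_major,
            "/", pair$min_minor, " eligibility filter (",
            pair$n_forward, " forward, ", pair$n_reverse, " reverse)")
  }
  m <- symmetry_matrix(pair, g1$L, g2$L, g = g, force = TRUE)
  ds <- d_score(m, g1, partner = g2$id)

  cfg <- c(sprintf("focal: %s", g1$id),
           sprintf("partner: %s", g2$id),
           sprintf("min_mum_len: %d", min_len),
           sprintf("eligibility: %d/%d (%s)", pair$min_major,
                   pair$min_minor,
                   if (pair$eligible) "pass" else "FAIL"),
           sprintf("grid_bp: %d", m$g))
  p_mums <- file.path(outdir, "mums.tsv")
  p_mat <- file.path(outdir, "matrix.tsv")
  p_ds <- file.path(outdir, "dscore.tsv")
  write_mums(mums, p_mums, g1$id, g2$id, comments = cfg)
  write_symmetry_matrix(m, p_mat, comments = cfg)
  write_tsv(data.frame(focal_id = ds$focal, partner_id = ds$partner,
                       i_star = ds$i_star + 1, max_X = ds$max_x, D = ds$D),
            p_ds, comments = cfg)
  invisible(list(pair = pair, matrix = m, dscore = ds,
                 paths = c(mums = p_mums, matrix = p_mat, dscore = p_ds)))
}
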