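mk_genes <- function(mids, L, strand = "+", feature = "CDS", cog = NA) {
  n <- length(mids)
  data.frame(start = mids %% L, end = (mids + 1) %% L + ifelse((mids + 1) %% L == 0, L, 0),
             strand = rep(strand, length.out = n),
             feature = rep(feature, length.out = n),
             cog = rep(cog, length.out = n), stringsAsFactors = FALSE)
}

test_that("rRNA ori distance is a percent of replichore size", {
  L <- 100000
  g <- circular_genome("g", strrep("A", L), ori = 0)
  expect_equal(rrna_ori_distance(mk_genes(c(0, 0, 0), L, feature = "rRNA"), g), 0)
  expect_equal(rrna_ori_distance(mk_genes(L / 2, L, feature = "rRNA"), g), 100)
  expect_equal(rrna_ori_distance(mk_genes(c(L / 8, L - L / 8), L,
                                          feature = "rRNA"), g), 25)
  expect_warning(v <- rrna_ori_distance(mk_genes(10, L), g), "no rRNA")
  expect_true(is.na(v))
})

test_that("COG J Z-score recovers planted ori-proximity and its null", {
  L <- 200000
  g <- circular_genome("g", strrep("A", L), ori = 0)
  # null: J genes placed like every other gene
  zs <- sapply(1:50, function(s) {
    genes <- make_annotated_layout(L, 0, params = list(j_spread = NULL),
                                   seed = 1000 + s)
    cog_j_z(genes, g)
  })
  expect_true(all(abs(zs) < 3.5))
  expect_lt(abs(mean(zs)), 0.5)
  # planted: J genes clustered near ori
  genes <- make_annotated_layout(L, 0, params = list(j_spread = 0.05),
                                 seed = 2)
  expect_lt(cog_j_z(genes, g), -3)

  # permutation mode agrees with the analytic form at large n_J (small
  # J fraction, so the without-replacement correction stays minor)
  genes_big <- make_annotated_layout(L, 0,
                                     params = list(n_genes = 2000,
                                                   frac_cog_j = 0.05,
                                                   j_spread = 0.15),
                                     seed = 3)
  za <- cog_j_z(genes_big, g)
  zp <- cog_j_z(genes_big, g, method = "permutation", B = 4000, seed = 7)
  expect_equal(sign(za), sign(zp))
  expect_lt(abs(za - zp) / abs(za), 0.2)

  expect_warning(vj <- cog_j_z(mk_genes(c(1, 2, 3), L, cog = "K"), g), "no COG")
  expect_true(is.na(vj))
})

test_that("leading fraction applies fork co-orientation and the majority rule", {
  L <- 100000
  g <- circular_genome("g", strrep("A", L), ori = 0)
  # replichore 1 genes on '+', replichore 2 genes on '-': all co-oriented
  genes <- rbind(mk_genes(seq(1000, 49000, by = 1000), L, strand = "+"),
                 mk_genes(seq(51000, 99000, by = 1000), L, strand = "-"))
  expect_equal(leading_fraction(genes, g), 1.0)
  # flip half of them: exactly balanced
  half <- genes
  flip <- seq(1, nrow(half), by = 2)
  half$strand[flip] <- chartr("+-", "-+", half$strand[flip])
  expect_equal(leading_fraction(half, g), 0.5)
  # planted probability is recovered within binomial error
  lay <- make_annotated_layout(L, 0, params = list(leading_prob = 0.8,
                                                   n_genes = 1000), seed = 21)
  expect_lt(abs(leading_fraction(lay, g) - 0.8), 0.04)
})

test_that("octamer tallies conserve window counts and match a naive count", {
  set.seed(83)
  L <- 4000
  g <- circular_genome("g", random_dna(L), ori = 0)
  len1 <- (g$ter - g$ori) %% L
  arc1 <- substr(g$seq, 1, len1)
  arc2 <- substr(g$seq, len1 + 1, L)
  c1 <- invsym:::count_octamers(arc1)
  c2 <- invsym:::count_octamers(arc2)
  expect_equal(sum(c1 + c2), (nchar(arc1) - 7) + (nchar(arc2) - 7))
  # naive substring tally as oracle on one arc
  octs <- substring(arc1, 1:(nchar(arc1) - 7), 8:nchar(arc1))
  tab <- table(octs)
  for (o in sample(names(tab), 25)) {
    idx <- sum((match(strsplit(o, "")[[1]], c("A", "C", "G", "T")) - 1) *
                 4^(7:0)) + 1
    expect_equal(c1[idx], unname(tab[o]))
  }
})

test_that("the planted most-biased octamer is recovered", {
  set.seed(89)
  motif <- "GGGGGAAA"
  base <- random_dna(200000)
  # plant 100 copies on replichore 1 at spaced positions
  pos <- seq(1000, 99000, length.out = 100)
  v <- strsplit(base, "")[[1]]
  for (p in pos) v[p:(p + 7)] <- strsplit(motif, "")[[1]]
  g <- circular_genome("g", paste(v, collapse = ""), ori = 0)
  ob <- octamer_bias(g)
  expect_equal(ob$octamer, motif)
  expect_gte(ob$diff_raw, 90)
  expect_true(ob$bias > 0.9 && ob$bias <= 1)

  gn <- circular_genome("n", strrep("N", 1000), ori = 0)
  expect_warning(obn <- octamer_bias(gn), "missing")
  expect_true(is.na(obn$octamer))
})

test_that("GC skew trace marks the replichore structure", {
  L <- 20000
  g0 <- circular_genome("a", strrep("A", L), ori = 0)
  pa <- gc_skew_profile(g0, window = 1000)
  expect_true(all(pa$skew == 0))
  expect_equal(pa$delta, 0)

  # G-rich first replichore, C-rich second: trace peaks at ter
  s <- paste0(strrep("GGAT", L / 8), strrep("CCAT", L / 8))
  g1 <- circular_genome("b", s, ori = 0)
  p1 <- gc_skew_profile(g1, window = 1000)
  expect_gt(p1$delta, 0)
  expect_equal(which.max(p1$cumulative), 10)  # window ending at ter

  # complementing the sequence negates the per-window skew
  g2 <- circular_genome("c", chartr("ACGT", "TGCA", s), ori = 0)
  p2 <- gc_skew_profile(g2, window = 1000)
  expect_equal(p2$skew, -p1$skew)
})

test_that("feature-D correlations behave at the monotone extremes", {
  feats <- data.frame(genome_id = letters[1:6],
                      rrna_dist_pct = c(10, 20, 30, 40, 50, 60),
                      cog_j_z = c(3, 2, 1, 0, -1, -2),
                      leading_fraction = c(0.5, 0.55, 0.6, 0.7, 0.8, 0.9),
                      octamer_bias_norm = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  med <- data.frame(genome_id = letters[1:6],
                    median_d = c(0.01, 0.05, 0.08, 0.12, 0.2, 0.24))
  ct <- feature_d_correlation(feats, med)
  expect_equal(ct$rho[ct$feature == "rrna_dist_pct"], 1)
  expect_equal(ct$rho[ct$feature == "cog_j_z"], -1)
  expect_equal(ct$rho[ct$feature == "octamer_bias_norm"], -1)
  expect_error(feature_d_correlation(feats[1:3, ], med), "insufficient")
})

test_that("label permutation yields uniform correlation p-values", {
  set.seed(97)
  feats <- data.frame(genome_id = sprintf("g%02d", 1:20),
                      rrna_dist_pct = runif(20, 0, 100))
  ps <- replicate(400, {
    med <- data.frame(genome_id = feats$genome_id,
                      median_d = sample(runif(20, 0, 0.25)))
    feature_d_correlation(feats, med, feature_cols = "rrna_dist_pct")$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
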