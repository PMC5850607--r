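test_that("forward residual is the circular vertical deviation from the arm", {
  i <- 40; j <- 70; L1 <- 200; L2 <- 100
  expect_equal(residual_forward(c(i + 13, (j + 13) %% L2), c(i, j), L1, L2), 0)
  expect_equal(residual_forward(c(i, j + 30), c(i, j), L1, L2), 30)
  # modular line evaluation across the wrap
  expect_equal(residual_forward(c(10 + 10, 5), c(10, 95), L1, 100), 0)
})

test_that("mirroring is an involution fixing the axis", {
  expect_equal(mirror_point(c(42, 7), 42, 100), c(42, 7))
  p <- c(33, 80)
  expect_equal(mirror_point(mirror_point(p, 17, 100), 17, 100), p)
  expect_equal(mirror_point(c(10, 40), 0, 100), c(90, 40))
})

test_that("x_score matches hand-computed two-term configurations", {
  L1 <- L2 <- 1000
  i <- 200; j <- 300
  ml <- 20
  # one forward MUM on the forward arm (f = 0), one reverse MUM whose
  # mirror lands on the forward arm (r_m = 0); equal weights
  fwd_mid <- c(i + 100, j + 100)          # on the +1 line through (i, j)
  rev_mid <- c(i - 50, j + 50)            # mirrors to (i + 50, j + 50)
  mums <- data.frame(
    x = c(fwd_mid[1], rev_mid[1]) - (ml - 1) / 2,
    y = c(fwd_mid[2], rev_mid[2]) - (ml - 1) / 2,
    len = ml, orient = c("forward", "reverse"), weight = 1,
    stringsAsFactors = FALSE
  )
  attr(mums, "min_len") <- ml
  # f = 0; f_m: mirror of (300, 400) is (100, 400), arm value at x=100 is
  # j - 100 = 200, so f_m = circ_dist(400, 200) = 200.
  # r: arm value at x=150 is 250, r = circ_dist(350, 250) = 100; r_m = 0.
  expect_equal(x_score(mums, i, j, L1, L2), (200 + 100) / 2)
  expect_equal(x_score(mums, i, j, L1, L2),
               oracle_x_score(mums, i, j, L1, L2))
  # single forward MUM centred exactly on the axis point scores zero
  single <- mums[1, , drop = FALSE]
  single$x <- i - (ml - 1) / 2
  single$y <- j - (ml - 1) / 2
  attr(single, "min_len") <- ml
  expect_equal(x_score(single, i, j, L1, L2), 0)
  expect_error(x_score(mums[0, ], i, j, L1, L2), "no MUMs")
})

test_that("compiled symmetry matrix equals the naive per-MUM loop", {
  set.seed(53)
  for (rep in 1:6) {
    L1 <- sample(500:2000, 1)
    L2 <- sample(500:2000, 1)
    mums <- random_mum_table(sample(5:40, 1), L1, L2)
    g <- max(25, round(min(L1, L2) / 20))
    m <- symmetry_matrix(mums, L1, L2, g = g)
    for (probe in 1:10) {
      a <- sample(length(m$igrid), 1)
      b <- sample(length(m$jgrid), 1)
      naive <- oracle_x_score(mums, m$igrid[a], m$jgrid[b], L1, L2)
      expect_equal(m$X[a, b], naive, tolerance = 1e-9)
    }
  }
})

test_that("symmetry matrix has the contracted shape and finite values", {
  set.seed(59)
  s <- random_dna(400)
  mm <- find_mums(s, s, min_len = 20)
  m <- symmetry_matrix(mm, 400, 400, g = 100)
  expect_equal(dim(m$X), c(4, 4))
  expect_true(all(is.finite(m$X)))
  expect_equal(m$igrid, c(0, 100, 200, 300))
})

test_that("duplicating every MUM leaves the matrix unchanged", {
  set.seed(61)
  mums <- random_mum_table(25, 3000, 3000)
  doubled <- rbind(mums, mums)
  attr(doubled, "min_len") <- attr(mums, "min_len")
  m1 <- symmetry_matrix(mums, 3000, 3000, g = 150)
  m2 <- symmetry_matrix(doubled, 3000, 3000, g = 150)
  expect_equal(m1$X, m2$X, tolerance = 1e-12)
  expect_equal(m1$i_star, m2$i_star)
})

test_that("rotating both genomes shifts the argmax and preserves max X", {
  set.seed(67)
  L <- 2000; g <- 100; delta <- 700   # delta a multiple of g
  mums <- random_mum_table(30, L, L)
  rot <- mums
  rot$x <- (mums$x + delta) %% L
  rot$y <- (mums$y + delta) %% L
  attr(rot, "min_len") <- attr(mums, "min_len")
  m0 <- symmetry_matrix(mums, L, L, g = g)
  m1 <- symmetry_matrix(rot, L, L, g = g)
  expect_equal(m1$max_x, m0$max_x, tolerance = 1e-9)
  # the score is exactly invariant under the antipodal shift
  # (i, j) -> (i + L/2, j + L/2) (an X axis is a full diameter), so the
  # argmax is equivariant up to that two-fold degeneracy
  shifted <- c((m0$i_star + delta) %% L, (m0$j_star + delta) %% L)
  anti <- (shifted + L / 2) %% L
  expect_true(identical(c(m1$i_star, m1$j_star), shifted) ||
                identical(c(m1$i_star, m1$j_star), anti))
})

test_that("ineligible pairs are refused unless forced", {
  mums <- random_mum_table(10, 1000, 1000)
  pair <- filter_alignment(mums)
  expect_false(pair$eligible)
  expect_error(symmetry_matrix(pair, 1000, 1000, g = 100), "eligibility")
  expect_s3_class(symmetry_matrix(pair, 1000, 1000, g = 100, force = TRUE),
                  "symmetry_matrix")
})

test_that("D score measures distance to the nearer replication landmark", {
  g <- circular_genome("f", strrep("ACGT", 2500), ori = 1000)  # L = 10000
  fake <- function(i_star) {
    structure(list(i_star = i_star, max_x = 1), class = "symmetry_matrix")
  }
  expect_equal(d_score(fake(g$ori), g)$D, 0)
  expect_equal(d_score(fake((g$ori + 2500) %% g$L), g)$D, 0.25)
  expect_equal(d_score(fake((g$ter + 1000) %% g$L), g)$D, 0.1)
})

test_that("D is bounded by a quarter genome for antipodal landmarks", {
  # even lengths: ter is exactly antipodal and the bound is sharp; odd
  # lengths floor the ter position, which can add at most 1/(4L)
  for (L in c(10, 100, 1000)) {
    g <- circular_genome("b", random_dna(L), ori = 0)
    d_all <- sapply(0:(L - 1), function(p) {
      min(circ_dist(p, g$ori, L), circ_dist(p, g$ter, L)) / L
    })
    expect_true(all(d_all >= 0 & d_all <= 0.25))
  }
  for (L in c(11, 97)) {
    g <- circular_genome("b", random_dna(L), ori = 0)
    d_all <- sapply(0:(L - 1), function(p) {
      min(circ_dist(p, g$ori, L), circ_dist(p, g$ter, L)) / L
    })
    expect_true(all(d_all >= 0 & d_all <= 0.25 + 1 / (4 * L)))
  }
})

test_that("median D follows the even-count convention", {
  sc <- data.frame(focal = c("a", "a", "a", "b"), D = c(0, 0.1, 0.2, 0.9))
  expect_equal(median_d("a", sc), 0.1)
  sc2 <- data.frame(focal = "a", D = c(0, 0.25))
  expect_equal(median_d("a", sc2), 0.125)
  expect_equal(median_d("a", data.frame(focal = "a", D = 0.1)), 0.1)
  expect_error(median_d("zzz", sc), "no D scores")
})

test_that("simulated symmetric inversions put the argmax on the ori-ter axis", {
  cfg <- sim_config(L = 200000, n_inversions = 40, mode = "symmetric",
                    point_mutation_rate = 0.001, seed = 71)
  pr <- evolve_pair(cfg)
  mm <- find_mums(pr$g1, pr$g2)
  m <- symmetry_matrix(filter_alignment(mm), pr$g1$L, pr$g2$L)
  near_axis <- min(circ_dist(m$i_star, pr$g1$ori, pr$g1$L),
                   circ_dist(m$i_star, pr$g1$ter, pr$g1$L))
  expect_lte(near_axis, m$g)  # within one grid cell of ori or ter
})
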