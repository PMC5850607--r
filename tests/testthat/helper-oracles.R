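# Independent oracles, deliberately written against the definitions rather
# than the package's code paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Count all (overlapping) occurrences of `pat` in `s`.
count_occurrences <- function(s, pat) {
  n <- nchar(s)
  k <- nchar(pat)
  if (k > n) return(0L)
  sv <- strsplit(s, "")[[1]]
  pv <- strsplit(pat, "")[[1]]
  pos <- which(sv[seq_len(n - k + 1)] == pv[1])
  for (t in seq_len(k - 1)) {
    if (length(pos) == 0) break
    pos <- pos[sv[pos + t] == pv[t + 1]]
  }
  length(pos)
}

# Brute-force MUM oracle: enumerate shared maximal substrings by seeding on
# shared min_len-mers and extending, then filter to matches whose substring
# occurs exactly once in each sequence. One orientation.
oracle_mums_one <- function(s1, s2, min_len) {
  n1 <- nchar(s1)
  n2 <- nchar(s2)
  if (n1 < min_len || n2 < min_len) {
    return(data.frame(x = integer(0), y = integer(0), len = integer(0)))
  }
  v1 <- strsplit(s1, "")[[1]]
  v2 <- strsplit(s2, "")[[1]]
  kmers1 <- vapply(seq_len(n1 - min_len + 1),
                   function(i) substr(s1, i, i + min_len - 1), character(1))
  kmers2 <- vapply(seq_len(n2 - min_len + 1),
                   function(i) substr(s2, i, i + min_len - 1), character(1))
  ok1 <- !grepl("[^ACGT]", kmers1)
  ok2 <- !grepl("[^ACGT]", kmers2)
  idx2 <- split(which(ok2), kmers2[ok2])
  seen <- new.env(hash = TRUE)
  out <- list()
  for (i in which(ok1)) {
    js <- idx2[[kmers1[i]]]
    if (is.null(js)) next
    for (j in js) {
      # extend left
      x <- i; y <- j
      while (x > 1 && y > 1 && v1[x - 1] == v2[y - 1] &&
             v1[x - 1] %in% c("A", "C", "G", "T")) {
        x <- x - 1; y <- y - 1
      }
      # extend right
      ex <- x + min_len - 1; ey <- y + min_len - 1
      # recompute right end from the seed ends
      ex <- i + min_len - 1; ey <- j + min_len - 1
      while (ex < n1 && ey < n2 && v1[ex + 1] == v2[ey + 1] &&
             v1[ex + 1] %in% c("A", "C", "G", "T")) {
        ex <- ex + 1; ey <- ey + 1
      }
      key <- paste(x, y, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1]] <- c(x, y, ex - x + 1)
    }
  }
  if (length(out) == 0) {
    return(data.frame(x = integer(0), y = integer(0), len = integer(0)))
  }
  m <- unique(do.call(rbind, out))
  keep <- vapply(seq_len(nrow(m)), function(r) {
    pat <- substr(s1, m[r, 1], m[r, 1] + m[r, 3] - 1)
    count_occurrences(s1, pat) == 1 && count_occurrences(s2, pat) == 1
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  data.frame(x = m[, 1] - 1, y = m[, 2] - 1, len = m[, 3])
}

# Full two-orientation oracle in the package's coordinate convention.
oracle_mums <- function(s1, s2, min_len) {
  fwd <- oracle_mums_one(s1, s2, min_len)
  fwd$orient <- rep("forward", nrow(fwd))
  rc <- oracle_mums_one(s1, oracle_revcomp(s2), min_len)
  rc$y <- nchar(s2) - rc$y - rc$len
  rc$orient <- rep("reverse", nrow(rc))
  out <- rbind(fwd, rc)
  out[order(out$orient, out$x, out$y), , drop = FALSE]
}

mum_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$x, df$y, df$len, df$orient, sep = "/"))
}

# Naive symmetry score, self-contained modular arithmetic.
oracle_x_score <- function(mums, i, j, L1, L2) {
  cd <- function(a, b, L) {
    d <- (a - b) %% L
    min(d, L - d)
  }
  tot <- 0
  for (m in seq_len(nrow(mums))) {
    px <- (mums$x[m] + (mums$len[m] - 1) / 2) %% L1
    py <- (mums$y[m] + (mums$len[m] - 1) / 2) %% L2
    f <- cd(py, (j + (px - i)) %% L2, L2)
    pxm <- (2 * i - px) %% L1
    fm <- cd(py, (j + (pxm - i)) %% L2, L2)
    w <- mums$len[m] / attr(mums, "min_len")
    tot <- tot + if (mums$orient[m] == "forward") w * (fm - f) else w * (f - fm)
  }
  tot / sum(mums$len / attr(mums, "min_len"))
}

# Random MUM table for property tests (not tied to real sequences).
random_mum_table <- function(n, L1, L2, min_len = 20) {
  df <- data.frame(
    x = sample.int(L1, n, replace = TRUE) - 1,
    y = sample.int(L2, n, replace = TRUE) - 1,
    len = sample(min_len:(min_len * 10), n, replace = TRUE),
    orient = sample(c("forward", "reverse"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  df$weight <- df$len / min_len
  attr(df, "min_len") <- min_len
  df
}
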