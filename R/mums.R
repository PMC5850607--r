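# Integer coding used by the C++ finder: A=1, C=2, G=3, T=4, anything else
# (N and other ambiguity codes) 0; zeros are recoded to unique sentinels in
# C++ so that an ambiguous base can never be part of a match.
encode_dna <- function(seq) {
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L
  map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L
  map[utf8ToInt("T")] <- 4L
  map[utf8ToInt(seq)]
}

as_genome_seq <- function(g) {
  if (inherits(g, "circular_genome")) g$seq else toupper(as.character(g))
}

#' Find maximal unique matches (MUMs) between two genomes
#'
#' Enumerates every exact match of length at least `min_len` that occurs
#' exactly once in each genome and cannot be extended in either direction,
#' in both forward and reverse-complement orientation. Matching is linear
#' (matches do not wrap the sequence ends), mirroring how whole-genome
#' aligners treat the deposited linear FASTA records, and matches containing
#' ambiguous bases are excluded.
#'
#' Reverse matches are reported with `y` giving the forward-strand start of
#' the matched segment in genome 2, so that dot-plot geometry is
#' orientation-agnostic.
#'
#' @param g1,g2 [circular_genome()] objects or plain sequence strings.
#' @param min_len Minimal MUM length in bp (default 20, the conventional
#'   threshold; 100 is a useful stricter setting for robustness checks).
#' @return `data.frame` with columns `x`, `y` (0-based starts), `len`,
#'   `orient` (`"forward"`/`"reverse"`), and `weight` (`len / min_len`).
#' @export
find_mums <- function(g1, g2, min_len = 20) {
  if (min_len < 1) stop("min_len must be >= 1", call. = FALSE)
  s1 <- as_genome_seq(g1)
  s2 <- as_genome_seq(g2)
  if (nchar(s1) == 0 || nchar(s2) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  e1 <- encode_dna(s1)
  e2 <- encode_dna(s2)
  e2rc <- rev(ifelse(e2 == 0L, 0L, 5L - e2))
  res <- find_mums_cpp(e1, e2, e2rc, as.integer(min_len))
  out <- data.frame(
    x = res$x, y = res$y, len = res$len,
    orient = ifelse(res$forward, "forward", "reverse"),
    stringsAsFactors = FALSE
  )
  out$weight <- out$len / min_len
  out <- out[order(out$orient, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_len") <- min_len
  out
}

#' Verify MUM sequence identity against the genomes
#'
#' Checks, for every reported match, that the genome-1 segment equals the
#' genome-2 segment (forward) or its reverse complement (reverse).
#'
#' @param mums MUM table from [find_mums()] or [parse_mummer()].
#' @param g1,g2 The two genomes (objects or strings).
#' @return Logical vector, one entry per MUM.
#' @export
verify_mums <- function(mums, g1, g2) {
  s1 <- as_genome_seq(g1)
  s2 <- as_genome_seq(g2)
  vapply(seq_len(nrow(mums)), function(m) {
    a <- substr(s1, mums$x[m] + 1, mums$x[m] + mums$len[m])
    b <- substr(s2, mums$y[m] + 1, mums$y[m] + mums$len[m])
    if (mums$orient[m] == "forward") a == b else a == revcomp(b)
  }, logical(1))
}

#' Parse MUMmer (`mummer -mum -b -c`) text output
#'
#' Expects the three-column dialect: a `>` header per query sequence, with a
#' second header suffixed `Reverse` introducing reverse-complement matches;
#' data lines of reference position, query position, and match length, all
#' 1-based. With `-c`, reverse query positions are already reported relative
#' to the forward strand, which is the convention this package uses
#' internally (0-based).
#'
#' @param input Path to a file, or a character vector of lines.
#' @param min_len Minimal MUM length used to derive weights.
#' @return MUM `data.frame` as from [find_mums()].
#' @export
parse_mummer <- function(input, min_len = 20) {
  lines <- if (length(input) == 1 && file.exists(input)) {
    readLines(input)
  } else {
    as.character(input)
  }
  orient <- NA_character_
  x <- integer(0); y <- integer(0); len <- integer(0); ori <- character(0)
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      orient <- if (grepl("Reverse\\s*$", line)) "reverse" else "forward"
      next
    }
    if (is.na(orient)) {
      stop("parse error at line ", k, ": data before any '>' header",
           call. = FALSE)
    }
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) != 3) {
      stop("parse error at line ", k, ": expected 3 fields, got ",
           length(f), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      stop("parse error at line ", k, ": non-numeric field '",
           f[which(is.na(v))[1]], "'", call. = FALSE)
    }
    x <- c(x, v[1] - 1)
    y <- c(y, v[2] - 1)
    len <- c(len, v[3])
    ori <- c(ori, orient)
  }
  out <- data.frame(x = x, y = y, len = len, orient = ori,
                    stringsAsFactors = FALSE)
  out$weight <- out$len / min_len
  attr(out, "min_len") <- min_len
  out
}

#' Serialize a MUM table in the MUMmer text dialect
#'
#' Canonical writer matching [parse_mummer()]: a forward section and, when
#' reverse matches are present, a `Reverse` section, with 1-based
#' coordinates.
#'
#' @param mums MUM table.
#' @param query_id Query sequence name for the section headers.
#' @return Character vector of lines.
#' @export
format_mummer <- function(mums, query_id = "seq2") {
  fmt <- function(df) sprintf("%d %d %d", df$x + 1, df$y + 1, df$len)
  fwd <- mums[mums$orient == "forward", , drop = FALSE]
  rev_ <- mums[mums$orient == "reverse", , drop = FALSE]
  out <- c(paste(">", query_id), fmt(fwd))
  if (nrow(rev_)) out <- c(out, paste(">", query_id, "Reverse"), fmt(rev_))
  out
}

#' Write a MUM table as TSV (1-based coordinates)
#'
#' @param mums MUM table.
#' @param path Output path.
#' @param genome1,genome2 Genome identifiers recorded in each row.
#' @param comments Extra `#` header lines.
#' @export
write_mums <- function(mums, path, genome1 = "genome1", genome2 = "genome2",
                       comments = character(0)) {
  df <- data.frame(genome1 = genome1, genome2 = genome2,
                   x = mums$x + 1, y = mums$y + 1,
                   len = mums$len, orient = mums$orient,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comments)
}

#' Apply the minimum-homology eligibility filter to an alignment
#'
#' A genome pair is retained for symmetry analysis only when it has at least
#' `min_major` MUMs in one orientation and at least `min_minor` in the
#' other (defaults 40 and 20), so that both arms of a putative X pattern are
#' supported by matches.
#'
#' @param mums MUM table.
#' @param min_major Required MUM count in the better-populated orientation.
#' @param min_minor Required MUM count in the other orientation.
#' @param genome1,genome2 Optional genome identifiers.
#' @return An `alignment_pair` object: list with `mums`, `n_forward`,
#'   `n_reverse`, `eligible`, and the thresholds used.
#' @export
filter_alignment <- function(mums, min_major = 40, min_minor = 20,
                             genome1 = NULL, genome2 = NULL) {
  n_forward <- sum(mums$orient == "forward")
  n_reverse <- sum(mums$orient == "reverse")
  eligible <- max(n_forward, n_reverse) >= min_major &&
    min(n_forward, n_reverse) >= min_minor
  structure(
    list(mums = mums, n_forward = n_forward, n_reverse = n_reverse,
         eligible = eligible, min_major = min_major, min_minor = min_minor,
         genome1 = genome1, genome2 = genome2),
    class = "alignment_pair"
  )
}

#' @export
print.alignment_pair <- function(x, ...) {
  cat(sprintf("<alignment_pair> %d forward / %d reverse MUMs; %s (>=%d/%d)\n",
              x$n_forward, x$n_reverse,
              if (x$eligible) "eligible" else "NOT eligible",
              x$min_major, x$min_minor))
  invisible(x)
}
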