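#' Read a circular genome from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param largest If the file holds several records (e.g. chromosome plus
#'   plasmids), keep only the largest one. With `largest = FALSE` (default)
#'   a multi-record file is an error, since silently picking a record is a
#'   common source of mistakes with synthetic fixtures.
#' @param ori Optional origin position (0-based) to attach.
#' @param clade Optional clade label.
#' @return A [circular_genome()].
#' @export
read_fasta <- function(path, largest = FALSE, ori = NA, clade = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
  if (length(ss) > 1) {
    if (!largest) {
      stop(path, " holds ", length(ss),
           " records; set largest = TRUE to keep the largest chromosome",
           call. = FALSE)
    }
    ss <- ss[which.max(Biostrings::width(ss))]
  }
  id <- sub("\\s.*$", "", names(ss)[1])
  circular_genome(id = id, seq = as.character(ss[[1]]), ori = ori,
                  clade = clade)
}

#' Write a circular genome to a FASTA file
#'
#' @param g A [circular_genome()].
#' @param path Output path.
#' @export
write_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$seq)
  names(ss) <- g$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Shared line-oriented TSV reader with per-line validation so that malformed
# records are reported with their line number. Lines starting with '#' are
# header comments.
read_tsv_checked <- function(path, columns, numeric_cols = character(0)) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(columns)),
                                  columns), stringsAsFactors = FALSE)
    for (cc in numeric_cols) out[[cc]] <- numeric(0)
    return(out)
  }
  # optional header row naming the expected columns
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- identical(tolower(first[seq_along(columns)]),
                          tolower(columns))
  if (has_header) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(lines))
  for (k in seq_along(parts)) {
    f <- parts[[k]]
    if (length(f) < length(columns)) {
      stop("parse error at line ", lineno[k], " of ", path, ": expected ",
           length(columns), " tab-separated fields, got ", length(f),
           call. = FALSE)
    }
    rows[[k]] <- f[seq_along(columns)]
  }
  m <- do.call(rbind, rows)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- columns
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("parse error at line ", lineno[bad], " of ", path,
           ": non-numeric value '", out[[cc]][bad], "' in column ", cc,
           call. = FALSE)
    }
    out[[cc]] <- v
  }
  out
}

#' Read an origin table
#'
#' A DoriC-style table with columns `genome_id` and `ori_pos` (1-based in
#' the file); several rows per genome describe a multi-part or multi-origin
#' chromosome. Positions are converted to the package's internal 0-based
#' convention.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `genome_id`, `ori` (0-based).
#' @export
read_ori_table <- function(path) {
  tab <- read_tsv_checked(path, c("genome_id", "ori_pos"), "ori_pos")
  data.frame(genome_id = tab$genome_id, ori = tab$ori_pos - 1,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation table
#'
#' Columns `genome_id`, `start`, `end`, `strand`, `feature`, `cog`, with
#' `start`/`end` 1-based inclusive in the file. Internally genes are stored
#' 0-based, half-open; an interval with `end < start` wraps the coordinate
#' origin. `cog` may be empty (`-` or blank) for unannotated genes.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `genome_id`, `start`, `end` (0-based
#'   half-open), `strand`, `feature`, `cog` (`NA` when absent).
#' @export
read_annotations <- function(path) {
  tab <- read_tsv_checked(
    path, c("genome_id", "start", "end", "strand", "feature", "cog"),
    c("start", "end")
  )
  bad <- which(!(tab$strand %in% c("+", "-")))
  if (length(bad)) {
    stop("parse error in ", path, ": invalid strand '", tab$strand[bad[1]],
         "' (expected + or -)", call. = FALSE)
  }
  cog <- tab$cog
  cog[cog %in% c("", "-", "NA", ".")] <- NA_character_
  data.frame(genome_id = tab$genome_id,
             start = tab$start - 1,
             end = tab$end,          # 1-based inclusive end == 0-based open end
             strand = tab$strand,
             feature = tab$feature,
             cog = cog,
             stringsAsFactors = FALSE)
}

#' Write a data frame as a TSV with '#' comment headers
#'
#' All of the package's tabular outputs use this format: zero or more lines
#' starting with `#` (typically echoing the run configuration), a header
#' row, then tab-separated records.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comments Character vector of comment lines (written as `# <line>`).
#' @export
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a TSV written by [write_tsv()]
#'
#' @param path Path to the TSV file.
#' @param numeric_cols Columns to convert to numeric.
#' @return Data frame.
#' @export
read_tsv <- function(path, numeric_cols = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) return(data.frame())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  out <- read_tsv_checked(path, header,
                          numeric_cols = intersect(numeric_cols %||% character(0),
                                                   header))
  out
}

#' Read a clade map
#'
#' Two columns: `genome_id`, `clade`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `genome_id`, `clade`.
#' @export
read_clade_map <- function(path) {
  read_tsv_checked(path, c("genome_id", "clade"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
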