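#' Construct a stranded-fragment table
#'
#' The package-wide container for Okazaki fragments and single-base
#' ribonucleotide 5'-end reads: a `data.table` with columns `chrom`,
#' `start`, `end` (0-based half-open) and `strand` (`"+"` = Watson,
#' `"-"` = Crick).  Crick-mapped Okazaki fragments mark rightward-moving
#' forks, Watson-mapped ones leftward-moving forks.
#'
#' @param chrom,start,end,strand Vectors of equal length; `strand` accepts
#'   `"+"`/`"-"` or `"Watson"`/`"Crick"` (case-insensitive).
#' @param genome Optional `genome` object; when given, coordinates are
#'   validated against it.
#' @return A `data.table(chrom, start, end, strand)`.
#' @export
fragments <- function(chrom, start, end, strand, genome = NULL) {
  fr <- data.table::data.table(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = .norm_strand(strand)
  )
  validate_fragments(fr, genome)
}

.norm_strand <- function(strand) {
  s <- as.character(strand)
  low <- tolower(s)
  s[low %in% c("watson", "w")] <- "+"
  s[low %in% c("crick", "c")] <- "-"
  bad <- !(s %in% c("+", "-"))
  if (any(bad))
    stop("strand must be +/Watson or -/Crick; offending value: ",
         s[which(bad)[1L]])
  s
}

validate_fragments <- function(fr, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(fr)))
  if (any(fr$start < 0) || any(fr$start >= fr$end))
    stop("fragment with start < 0 or start >= end")
  if (!is.null(genome)) {
    .check_chroms(fr$chrom, genome, "fragment")
    if (any(fr$end > unclass(genome)[fr$chrom]))
      stop("fragment extends past its chromosome end")
  }
  fr
}

#' Load aligned fragments from BED6 or BEDPE
#'
#' BED6 files contribute one fragment per record with the strand from
#' column 6.  BEDPE files (10 columns) contribute the outer span
#' `min(start1, start2)..max(end1, end2)` of each pair; the strand is taken
#' from the mate selected by `mate_strand` (the library's mate orientation
#' is protocol-dependent, so it is a parameter, not a guess).
#'
#' @param path BED6 or BEDPE file; the format is detected from the column
#'   count (>= 10 columns with both strand columns present = BEDPE).
#' @param genome A `genome` object for coordinate validation.
#' @param mate_strand For BEDPE, which mate's strand labels the fragment
#'   (1 or 2); default 1.
#' @return A stranded-fragment `data.table` (see [fragments()]).
#' @export
load_fragments <- function(path, genome, mate_strand = 1L) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(tab) >= 10L) {
    strand_col <- if (mate_strand == 1L) tab[[9L]] else tab[[10L]]
    if (any(tab[[1L]] != tab[[4L]]))
      stop("BEDPE mates on different chromosomes are not supported")
    fr <- fragments(
      chrom = tab[[1L]],
      start = pmin(as.numeric(tab[[2L]]), as.numeric(tab[[5L]])),
      end = pmax(as.numeric(tab[[3L]]), as.numeric(tab[[6L]])),
      strand = strand_col, genome = genome
    )
  } else if (ncol(tab) >= 6L) {
    fr <- fragments(tab[[1L]], tab[[2L]], tab[[3L]], tab[[6L]],
                    genome = genome)
  } else {
    stop("fragment file must be BED6 (strand in column 6) or BEDPE: ", path)
  }
  fr
}

#' Remove PCR duplicates
#'
#' Keeps at most one fragment per identical (chrom, start, end, strand)
#' tuple, preserving the relative order of the survivors.  Idempotent; no
#' UMI support.
#'
#' @param frags A stranded-fragment table.
#' @return The deduplicated table.
#' @export
deduplicate <- function(frags) {
  frags[!duplicated(frags, by = c("chrom", "start", "end", "strand"))]
}

#' Fragment midpoints
#'
#' Integer midpoint `floor((start + end) / 2)` used for all binning and
#' flank assignment: each fragment contributes exactly one count, so count
#' conservation is exact and no fragment is split across a window boundary.
#'
#' @param frags A stranded-fragment table.
#' @return Numeric vector of midpoints.
#' @export
fragment_midpoints <- function(frags) floor((frags$start + frags$end) / 2)

#' Strand-specific binned coverage
#'
#' Counts fragment midpoints into fixed-width bins, separately for the
#' Watson and Crick strands, per chromosome.
#'
#' @param frags A stranded-fragment table.
#' @param genome A `genome` object (defines the bin grids).
#' @param bin_width Bin width in bp (>= 1).
#' @return A `coverage_track`: list with `bin_width`, `chrom_lengths`,
#'   `counts` (per chromosome, a matrix with columns `watson`, `crick`)
#'   and `total` (number of counted fragments).
#' @export
coverage <- function(frags, genome, bin_width) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  validate_fragments(frags, genome)
  lens <- unclass(genome)
  nbin <- ceiling(lens / bin_width)
  mids <- fragment_midpoints(frags)
  counts <- lapply(names(lens), function(ch) {
    m <- matrix(0, nrow = nbin[[ch]], ncol = 2L,
                dimnames = list(NULL, c("watson", "crick")))
    sel <- frags$chrom == ch
    if (any(sel)) {
      idx <- floor(mids[sel] / bin_width) + 1
      for (s in c("+", "-")) {
        t <- tabulate(idx[frags$strand[sel] == s], nbins = nbin[[ch]])
        m[, if (s == "+") "watson" else "crick"] <- t
      }
    }
    m
  })
  names(counts) <- names(lens)
  structure(list(bin_width = bin_width, chrom_lengths = lens,
                 counts = counts, total = sum(vapply(counts, sum, 0))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> bin ", x$bin_width, " bp, ",
      length(x$counts), " chromosomes, ",
      format(x$total, big.mark = ","), " fragments\n", sep = "")
  invisible(x)
}

#' Write a coverage track as a per-strand bedGraph-style TSV
#'
#' Columns: chrom, bin_start, bin_end, watson, crick.  A single commented
#' header line states the coordinate convention.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# strand-specific midpoint coverage; 0-based half-open bins; bin_width=",
                    track$bin_width, " bp"), con)
  for (ch in names(track$counts)) {
    m <- track$counts[[ch]]
    n <- nrow(m)
    if (n == 0L) next
    starts <- (seq_len(n) - 1) * track$bin_width
    ends <- pmin(starts + track$bin_width, track$chrom_lengths[[ch]])
    utils::write.table(
      data.frame(ch, starts, ends, m[, "watson"], m[, "crick"]),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write fragments as BED6
#'
#' @param frags A stranded-fragment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  bed <- data.frame(frags$chrom, format(frags$start, scientific = FALSE, trim = TRUE),
                    format(frags$end, scientific = FALSE, trim = TRUE),
                    ".", 0L, frags$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
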