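#' Load a genome from a chromosome-sizes table
#'
#' Reads a two-column TSV (`chrom<TAB>length`) of the kind produced by
#' `samtools faidx` / UCSC `chrom.sizes`, and returns a `genome` object:
#' the coordinate frame every other function in the package validates
#' against.  All coordinates in this package are 0-based half-open
#' (BED convention).
#'
#' @param path Path to a two-column TSV with chromosome name and length (bp).
#' @param exclude Character vector of chromosome names excluded from
#'   genome-wide totals (default `"chrXII"`, the rDNA-bearing chromosome of
#'   S. cerevisiae, whose repetitive array distorts read counts).  Names not
#'   present in the file are dropped from the exclusion set silently, so the
#'   default is harmless for non-yeast genomes.
#' @return A `genome` object: named integer vector of chromosome lengths
#'   with an `exclude` attribute.
#' @export
load_genome <- function(path, exclude = "chrXII") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  if (ncol(tab) != 2L)
    stop("chrom.sizes file must have exactly two columns (name, length): ", path)
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(len) || any(len != floor(len)))
    stop("malformed chromosome length in ", path)
  genome(stats::setNames(len, tab[[1L]]), exclude = exclude)
}

#' Construct a genome object from named lengths
#'
#' @param lengths Named numeric vector, chromosome name -> length (bp, > 0).
#' @param exclude Chromosomes excluded from genome-wide totals; silently
#'   intersected with the available names.
#' @return A `genome` object.
#' @export
genome <- function(lengths, exclude = character()) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(lengths <= 0))
    stop("non-positive chromosome length for: ",
         paste(nm[lengths <= 0], collapse = ", "))
  g <- structure(as.numeric(lengths), names = nm, class = "genome")
  attr(g, "exclude") <- intersect(exclude, nm)
  g
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x), " chromosomes, ",
      format(sum(unclass(x)), big.mark = ","), " bp\n", sep = "")
  ex <- attr(x, "exclude")
  if (length(ex)) cat("  excluded from totals: ", paste(ex, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Chromosomes excluded from genome-wide totals
#' @param genome A `genome` object.
#' @return Character vector of excluded chromosome names.
#' @export
excluded_chroms <- function(genome) attr(genome, "exclude") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_chroms <- function(chrom, genome, what = "record") {
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stop(what, " on chromosome absent from genome: ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Load replication origins from a BED file
#'
#' BED3+ intervals; the fourth column, when present, supplies origin ids,
#' otherwise ids `origin_0001`... are assigned.  Origins are returned sorted
#' by (chromosome, midpoint), with the chromosome order taken from the
#' genome.  Midpoint is `floor((start + end) / 2)`.
#'
#' @param path BED file (0-based half-open intervals).
#' @param genome A `genome` object; records on unknown chromosomes or
#'   exceeding the chromosome length are errors.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `mid`, `id`.
#' @export
load_origins <- function(path, genome) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(tab) < 3L) stop("origin BED needs at least 3 columns: ", path)
  ids <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else NA_character_
  ids[!is.na(ids) & ids == ""] <- NA_character_
  ori <- data.table::data.table(
    chrom = as.character(tab[[1L]]),
    start = as.numeric(tab[[2L]]),
    end   = as.numeric(tab[[3L]]),
    id    = ids
  )
  origins(ori, genome)
}

#' Construct and validate an origin table
#'
#' @param x A data.frame with columns `chrom`, `start`, `end` and optionally
#'   `id` (auto-assigned when absent or NA).
#' @param genome A `genome` object used for validation and chromosome order.
#' @return A `data.table` sorted by (chromosome, midpoint) with columns
#'   `chrom`, `start`, `end`, `mid`, `id`.
#' @export
origins <- function(x, genome) {
  ori <- data.table::as.data.table(x)[, c("chrom", "start", "end"),
                                      with = FALSE]
  ori[, `:=`(start = as.numeric(start), end = as.numeric(end))]
  ori$id <- if ("id" %in% names(x)) as.character(x[["id"]]) else NA_character_
  .check_chroms(ori$chrom, genome, "origin")
  bad <- ori$start < 0 | ori$start >= ori$end |
    ori$end > unclass(genome)[ori$chrom]
  if (any(bad))
    stop("origin interval outside its chromosome or empty (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  ori[, mid := floor((start + end) / 2)]
  ord <- order(match(ori$chrom, names(genome)), ori$mid)
  ori <- ori[ord]
  need_id <- is.na(ori$id)
  if (any(need_id))
    ori[need_id, id := sprintf("origin_%04d", which(need_id))]
  if (anyDuplicated(ori$id)) stop("duplicate origin id")
  data.table::setcolorder(ori, c("chrom", "start", "end", "mid", "id"))
  ori[]
}
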