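#' Partition ribonucleotide reads at restriction sites
#'
#' A ribonucleotide "location" is the single 5'-end base of a HydEn-seq
#' read.  Reads whose base falls inside any site interval (half-open
#' membership) are removed from the ribonucleotide pool and collected into
#' the loading-control (SbfI) pool; everything else is kept.
#'
#' @param ribo_reads Stranded-fragment table of 1-bp records.
#' @param sbfi_sites BED-style `data.frame(chrom, start, end)` of site
#'   intervals (a `pos` column is accepted as a 1-bp site).
#' @return List with `clean` (reads outside sites), `site_reads` (reads
#'   inside sites) and `site_read_count`.
#' @export
filter_site_reads <- function(ribo_reads, sbfi_sites) {
  sites <- data.table::copy(data.table::as.data.table(sbfi_sites))
  if (!"start" %in% names(sites) && "pos" %in% names(sites))
    sites[, `:=`(start = as.numeric(pos), end = as.numeric(pos) + 1)]
  if (!"end" %in% names(sites)) sites[, end := start + 1]
  inside <- logical(nrow(ribo_reads))
  pos <- ribo_reads$start
  for (ch in unique(sites$chrom)) {
    s <- sites[chrom == ch][order(start)]
    sel <- which(ribo_reads$chrom == ch)
    if (!length(sel)) next
    i <- findInterval(pos[sel], s$start)
    inside[sel] <- i >= 1L & pos[sel] < s$end[pmax(i, 1L)]
  }
  list(clean = ribo_reads[!inside],
       site_reads = ribo_reads[inside],
       site_read_count = sum(inside))
}

#' SbfI-normalized total ribonucleotide density
#'
#' Sums ribonucleotide reads on both strands over all chromosomes except
#' the excluded ones (default: the rDNA-bearing chromosome) and divides by
#' the loading-control reads at restriction sites under the same
#' exclusions.  Being a ratio of counts from the same library, the density
#' is invariant to sequencing depth.
#'
#' @param ribo_clean Site-filtered ribonucleotide reads (from
#'   [filter_site_reads()]).
#' @param site_reads The site-read records from the same call (so the
#'   exclusions can be applied to the denominator too); alternatively a
#'   single pre-excluded count.
#' @param exclude Chromosome names excluded from both numerator and
#'   denominator; pass `excluded_chroms(genome)` for the genome default.
#' @return A `hyden_summary` list: `density`, `ribo_total`, `sbfi_total`,
#'   `excluded`, `per_chrom` (counts per chromosome per strand, with an
#'   `excluded` flag), `status` (`"ok"` or `"undefined"`).
#' @export
normalized_total <- function(ribo_clean, site_reads, exclude = "chrXII") {
  per <- ribo_clean[, list(n_reads = .N), by = list(chrom, strand)]
  per[, excluded := chrom %in% exclude]
  num <- sum(per$n_reads[!per$excluded])
  den <- if (is.numeric(site_reads) && length(site_reads) == 1L) {
    site_reads
  } else {
    sum(!(site_reads$chrom %in% exclude))
  }
  structure(list(
    density = if (den > 0) num / den else NA_real_,
    ribo_total = num, sbfi_total = den,
    excluded = exclude, per_chrom = per[order(chrom, strand)],
    status = if (den > 0) "ok" else "undefined"
  ), class = "hyden_summary")
}

#' @export
print.hyden_summary <- function(x, ...) {
  cat("<hyden_summary> ribo =", x$ribo_total, " sbfi =", x$sbfi_total,
      " density =", format(x$density, digits = 4),
      if (x$status != "ok") " [undefined]", "\n")
  if (length(x$excluded))
    cat("  excluded chromosomes:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Origin-anchored ribonucleotide strand-bias profile
#'
#' The same pooled aggregation as [strand_bias_profile()] applied to 1-bp
#' ribonucleotide records: Crick reads divided by total reads per
#' relative-position bin around origins.  With leading-strand-dominated
#' incorporation (Pol epsilon variant) the profile mirrors the Okazaki
#' profile: fraction of Crick ~1 left of efficient origins, ~0 right.
#'
#' @param ribo_clean Site-filtered ribonucleotide reads.
#' @param origins Origin table.
#' @param halfwidth,bin Grid parameters as in [strand_bias_profile()].
#' @param invert_strand Flip read strands first (HydEn-seq end-mapping
#'   dialects differ in which strand a 5' end is reported on).
#' @return A `strand_bias_profile`.
#' @export
ribo_strand_bias_profile <- function(ribo_clean, origins, halfwidth = 10000,
                                     bin = 100, invert_strand = FALSE) {
  if (invert_strand) {
    ribo_clean <- data.table::copy(ribo_clean)
    ribo_clean[, strand := ifelse(strand == "+", "-", "+")]
  }
  strand_bias_profile(ribo_clean, origins, halfwidth = halfwidth, bin = bin)
}

#' Polarity-matched comparison of ribonucleotide and Okazaki delta profiles
#'
#' Compares the condition-induced change in ribonucleotide strand bias with
#' the change in Okazaki-fragment strand bias, after matching polarities:
#' with `polarity = "flip_okazaki_strand"` the Okazaki delta is re-expressed
#' on Watson fractions (the convention for a leading-strand Pol epsilon
#' tracer, whose bias is opposite to the Okazaki bias); with `"same"` it is
#' kept on Crick fractions (lagging-strand Pol alpha tracer).  The summary
#' reports whether the ribonucleotide change is smaller in magnitude than
#' the Okazaki change — the decision criterion for concluding that no other
#' polymerase takes over lagging-strand synthesis.
#'
#' @param ribo_delta Delta profile of ribonucleotide Crick fractions
#'   (condition A - condition B), from [delta_profile()].
#' @param okz_delta Delta profile of Okazaki Crick fractions on the same
#'   grid.
#' @param polarity `"flip_okazaki_strand"` or `"same"`.
#' @return List with `table` (per-bin `rel_bin_start`, `ribo_delta`,
#'   `okz_delta_polarized`), `max_abs_ribo`, `max_abs_okz`,
#'   `magnitude_difference` (ribo - okz), `sign_agreement` (fraction of
#'   bins where the two deltas share a sign) and `takeover_excluded`
#'   (TRUE when the ribo change is smaller than the Okazaki change).
#' @export
polarity_matched_delta <- function(ribo_delta, okz_delta,
                                   polarity = c("flip_okazaki_strand",
                                                "same")) {
  polarity <- match.arg(polarity)
  .check_same_grid(ribo_delta, okz_delta)
  okz <- if (polarity == "flip_okazaki_strand") -okz_delta$delta
         else okz_delta$delta
  tab <- data.table::data.table(
    rel_bin_start = ribo_delta$rel_bin_start,
    ribo_delta = ribo_delta$delta,
    okz_delta_polarized = okz)
  ok <- !is.na(tab$ribo_delta) & !is.na(tab$okz_delta_polarized)
  mar <- max(abs(tab$ribo_delta[ok]))
  mao <- max(abs(tab$okz_delta_polarized[ok]))
  nz <- ok & tab$ribo_delta != 0 & tab$okz_delta_polarized != 0
  list(table = tab,
       max_abs_ribo = mar, max_abs_okz = mao,
       magnitude_difference = mar - mao,
       sign_agreement = if (any(nz))
         mean(sign(tab$ribo_delta[nz]) == sign(tab$okz_delta_polarized[nz]))
       else NA_real_,
       polarity = polarity,
       takeover_excluded = mar < mao)
}

#' Write a HydEn-seq summary as TSV
#' @param summary A `hyden_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hyden_tsv <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# HydEn-seq totals; density = ribo/sbfi = %s/%s = %s (excluded: %s) status=%s",
    summary$ribo_total, summary$sbfi_total,
    format(summary$density, digits = 6),
    paste(summary$excluded, collapse = ","), summary$status), con)
  utils::write.table(summary$per_chrom, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
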