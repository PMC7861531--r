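#' Select early-firing origins from an earliest-timepoint OEM table
#'
#' Early origins are defined operationally: at the earliest sequenced
#' timepoint only early, efficient origins show a strand-bias signal, so a
#' criterion on that timepoint's OEM selects them.  Deterministic given
#' inputs; ties broken by origin order.
#'
#' @param tab OEM table from the earliest timepoint.
#' @param origins The origin table the OEMs were computed over.
#' @param min_oem Select origins with defined OEM >= this threshold
#'   (default criterion, 0.4).
#' @param top_n Alternative criterion: the `top_n` origins by OEM
#'   (overrides `min_oem` when non-NULL).
#' @return The selected subset of `origins`, in origin order.
#' @export
select_early_origins <- function(tab, origins, min_oem = 0.4, top_n = NULL) {
  stopifnot(nrow(tab) == nrow(origins), all(tab$id == origins$id))
  o <- tab$oem
  keep <- if (!is.null(top_n)) {
    ord <- order(-o, seq_along(o), na.last = TRUE)
    seq_along(o) %in% ord[seq_len(min(top_n, sum(!is.na(o))))]
  } else {
    !is.na(o) & o >= min_oem
  }
  if (!any(keep)) stop("early-origin criterion selects zero origins")
  origins[keep]
}

#' Normalized meta-coverage around origins
#'
#' Pools binned fragment-midpoint counts across origins by relative
#' position and normalizes by the single maximum raw value over the whole
#' range, so complete replication of the +/- `halfwidth` windows gives a
#' flat line at 1.0.  `mode = "total"` counts both strands everywhere;
#' `mode = "stranded"` counts Watson fragments only in
#' `[-halfwidth, -gap)` and Crick fragments only in `[+gap, +halfwidth)`
#' (default gap 1 kb), reading out the progression of leftward and
#' rightward forks emanating from the origins.
#'
#' @param frags Stranded-fragment table.
#' @param origins Origin table (typically from [select_early_origins()]).
#' @param mode `"total"` or `"stranded"`.
#' @param halfwidth Window half-width in bp (default 20 kb).
#' @param bin Bin width in bp (default 100); must divide `halfwidth`.
#' @param gap Stranded-mode exclusion half-width around the origin (bp).
#' @return A `meta_coverage_profile` `data.table(rel_bin_start, raw,
#'   normalized)` with attributes `mode`, `halfwidth`, `bin`, `gap`,
#'   `norm_constant`, `n_origins`.
#' @export
meta_coverage <- function(frags, origins, mode = c("total", "stranded"),
                          halfwidth = 20000, bin = 100, gap = 1000) {
  mode <- match.arg(mode)
  rc <- .rel_counts(frags, origins, halfwidth, bin)
  raw <- if (mode == "total") {
    rc$watson + rc$crick
  } else {
    ctr <- rc$rel_bin_start + bin / 2
    ifelse(ctr < -gap, rc$watson, ifelse(ctr >= gap, rc$crick, 0))
  }
  mx <- max(raw)
  if (mx <= 0) stop("meta-coverage has zero counts everywhere; normalization undefined")
  prof <- data.table::data.table(rel_bin_start = rc$rel_bin_start,
                                 raw = raw, normalized = raw / mx)
  data.table::setattr(prof, "mode", mode)
  data.table::setattr(prof, "halfwidth", halfwidth)
  data.table::setattr(prof, "bin", bin)
  data.table::setattr(prof, "gap", gap)
  data.table::setattr(prof, "norm_constant", mx)
  data.table::setattr(prof, "n_origins", nrow(origins))
  data.table::setattr(prof, "class", c("meta_coverage_profile", class(prof)))
  prof
}

#' Fork-front position from a normalized meta-coverage profile
#'
#' Walks outward from the origin on each arm and reports the distance at
#' which the normalized profile first drops below `level`, linearly
#' interpolated between bin centers.  `Inf` means the profile never
#' crosses the level on that side (front beyond the profiled range).
#' Purely a reporting convention for quantifying fork progression.
#'
#' @param profile A `meta_coverage_profile`.
#' @param level Threshold in (0, 1), default 0.5.
#' @return `c(left = bp, right = bp)` distances from the origin (positive
#'   on both sides; `Inf` = beyond range).
#' @export
front_position <- function(profile, level = 0.5) {
  stopifnot(level > 0, level < 1)
  bin <- attr(profile, "bin")
  gap <- if (identical(attr(profile, "mode"), "stranded"))
    attr(profile, "gap") else 0
  ctr <- profile$rel_bin_start + bin / 2
  arm <- function(side) {
    sel <- if (side > 0) ctr >= gap else ctr < -gap
    x <- abs(ctr[sel]); y <- profile$normalized[sel]
    o <- order(x); x <- x[o]; y <- y[o]
    below <- which(y < level)
    if (!length(below)) return(Inf)
    i <- below[1L]
    if (i == 1L) return(x[1L])
    x[i - 1L] + (x[i] - x[i - 1L]) * (y[i - 1L] - level) / (y[i - 1L] - y[i])
  }
  c(left = arm(-1), right = arm(+1))
}

# depth-normalized concatenated total-coverage vector of a track
.track_vector <- function(track) {
  v <- unlist(lapply(track$counts, function(m) m[, "watson"] + m[, "crick"]),
              use.names = FALSE)
  if (sum(v) <= 0) stop("coverage track is empty")
  v / sum(v)
}

#' Match timepoints between two conditions by coverage similarity
#'
#' For each timepoint of condition A, finds the condition-B timepoint whose
#' depth-normalized total-coverage vector is most similar.  The default
#' dissimilarity is 1 - Spearman correlation over bins (invariant to depth
#' and monotone distortions); `metric = "l1"` uses the L1 distance between
#' depth-normalized vectors.
#'
#' @param tracks_a,tracks_b Lists of `coverage_track`s sharing genome and
#'   bin width.
#' @param metric `"spearman"` (default) or `"l1"`.
#' @return `data.table(index_a, index_b, dissimilarity)` with the full
#'   dissimilarity matrix as attribute `matrix`.
#' @export
match_timepoints <- function(tracks_a, tracks_b,
                             metric = c("spearman", "l1")) {
  metric <- match.arg(metric)
  va <- lapply(tracks_a, .track_vector)
  vb <- lapply(tracks_b, .track_vector)
  nb <- unique(c(vapply(va, length, 0L), vapply(vb, length, 0L)))
  if (length(nb) != 1L)
    stop("coverage tracks are on different bin grids")
  bw <- unique(c(vapply(tracks_a, function(t) t$bin_width, 0),
                 vapply(tracks_b, function(t) t$bin_width, 0)))
  if (length(bw) != 1L)
    stop("coverage tracks are on different bin grids")
  dis <- matrix(NA_real_, length(va), length(vb))
  for (i in seq_along(va)) for (j in seq_along(vb)) {
    dis[i, j] <- if (metric == "spearman")
      1 - stats::cor(va[[i]], vb[[j]], method = "spearman")
    else sum(abs(va[[i]] - vb[[j]]))
  }
  best <- apply(dis, 1L, which.min)
  out <- data.table::data.table(
    index_a = seq_along(va), index_b = best,
    dissimilarity = dis[cbind(seq_along(va), best)])
  data.table::setattr(out, "matrix", dis)
  data.table::setattr(out, "metric", metric)
  out
}

#' Write a meta-coverage profile as TSV
#' @param prof A `meta_coverage_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_coverage_tsv <- function(prof, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# meta-coverage mode=%s bin=%s bp halfwidth=%s bp; normalized to global max (=%s raw counts)",
    attr(prof, "mode"), attr(prof, "bin"), attr(prof, "halfwidth"),
    attr(prof, "norm_constant")), con)
  utils::write.table(prof, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
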