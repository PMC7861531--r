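#' Origin efficiency metric from flank counts
#'
#' OEM = W_L / (W_L + C_L) - W_R / (W_R + C_R), the difference between the
#' Watson fraction of the left flank and of the right flank.  It estimates
#' the fraction of cells in which the origin fires productively: a fully
#' efficient divergent origin gives 1, no bias gives 0.  Undefined (NA)
#' when either flank is empty; undefined values are excluded from
#' summaries, never imputed.
#'
#' @param w_l,c_l,w_r,c_r Non-negative Watson/Crick counts in the left and
#'   right flank (vectorized).
#' @return OEM in \[-1, 1\], or NA where a flank has no reads.
#' @export
oem <- function(w_l, c_l, w_r, c_r) {
  if (any(c(w_l, c_l, w_r, c_r) < 0)) stop("negative flank count")
  lden <- w_l + c_l
  rden <- w_r + c_r
  out <- ifelse(lden > 0 & rden > 0,
                w_l / pmax(lden, 1e-300) - w_r / pmax(rden, 1e-300),
                NA_real_)
  as.numeric(out)
}

# Sorted per-(chrom, strand) midpoint index for O(log n) range counts.
.mid_index <- function(frags) {
  mids <- fragment_midpoints(frags)
  idx <- list()
  for (ch in unique(frags$chrom)) {
    sel <- frags$chrom == ch
    idx[[ch]] <- list(
      watson = sort(mids[sel & frags$strand == "+"]),
      crick = sort(mids[sel & frags$strand == "-"]),
      both = sort(mids[sel]))
  }
  idx
}

# number of values of sorted `v` in [lo, hi)  (integer midpoints)
.count_in <- function(v, lo, hi) {
  findInterval(hi - 1, v) - findInterval(lo - 1, v)
}

#' Count stranded fragments in origin flanks
#'
#' A fragment is assigned by its midpoint: left flank is the half-open
#' window `[mid - flank, mid)`, right flank `[mid, mid + flank)` — a
#' midpoint exactly on the origin midpoint counts in the right flank.
#' Flanks are truncated at chromosome ends.
#'
#' @param frags Stranded-fragment table.
#' @param origin A single-row origin (or anything with `chrom` and `mid`).
#' @param flank Flank width in bp (> 0), default 10 kb.
#' @return Named numeric vector `c(W_L, C_L, W_R, C_R)`.
#' @export
count_flanks <- function(frags, origin, flank = 10000) {
  stopifnot(flank > 0)
  idx <- .mid_index(frags)[[origin$chrom[1L]]]
  m <- origin$mid[1L]
  if (is.null(idx)) return(c(W_L = 0, C_L = 0, W_R = 0, C_R = 0))
  c(W_L = .count_in(idx$watson, m - flank, m),
    C_L = .count_in(idx$crick, m - flank, m),
    W_R = .count_in(idx$watson, m, m + flank),
    C_R = .count_in(idx$crick, m, m + flank))
}

#' Per-origin OEM table
#'
#' One record per origin (in origin order) with the four flank counts and
#' the OEM; the summary attribute reports mean, min and max over defined
#' OEMs and the number of origins used.
#'
#' @param frags Stranded-fragment table.
#' @param origins Origin table.
#' @param flank Flank width in bp, default 10 kb.
#' @return `data.table(id, chrom, mid, W_L, C_L, W_R, C_R, oem)` with a
#'   `summary` attribute (`mean`, `min`, `max`, `n_defined`, `n_origins`).
#' @export
oem_table <- function(frags, origins, flank = 10000) {
  stopifnot(nrow(origins) > 0)
  idx <- .mid_index(frags)
  n <- nrow(origins)
  wl <- cl <- wr <- cr <- numeric(n)
  for (i in seq_len(n)) {
    ix <- idx[[origins$chrom[i]]]
    if (is.null(ix)) next
    m <- origins$mid[i]
    wl[i] <- .count_in(ix$watson, m - flank, m)
    cl[i] <- .count_in(ix$crick, m - flank, m)
    wr[i] <- .count_in(ix$watson, m, m + flank)
    cr[i] <- .count_in(ix$crick, m, m + flank)
  }
  tab <- data.table::data.table(
    id = origins$id, chrom = origins$chrom, mid = origins$mid,
    W_L = wl, C_L = cl, W_R = wr, C_R = cr,
    oem = oem(wl, cl, wr, cr))
  ok <- !is.na(tab$oem)
  attr(tab, "summary") <- list(
    mean = if (any(ok)) mean(tab$oem[ok]) else NA_real_,
    min = if (any(ok)) min(tab$oem[ok]) else NA_real_,
    max = if (any(ok)) max(tab$oem[ok]) else NA_real_,
    n_defined = sum(ok), n_origins = n)
  tab
}

#' Monte-Carlo standard error of per-origin OEM from pooled simulated cells
#'
#' Fragments from one cell share the cell's fork-direction pattern, so the
#' effective sample size of a flank fraction is the number of contributing
#' cells, not fragments.  The SE of each flank's Watson fraction is
#' estimated binomially with a design-effect inflation equal to the mean
#' number of fragments per contributing cell (conservative: full
#' within-cell correlation), using an add-one continuity correction so the
#' SE stays positive at fractions of exactly 0 or 1; flank SEs combine in
#' quadrature.
#'
#' @param frags Pooled simulated fragments with a `cell` column (from
#'   [simulate_pool()]); without one, fragments are treated as independent.
#' @param origins Origin table.
#' @param flank Flank width in bp.
#' @return Numeric vector of per-origin OEM standard errors (NA where a
#'   flank is empty).
#' @export
oem_se <- function(frags, origins, flank = 10000) {
  mids <- fragment_midpoints(frags)
  has_cell <- "cell" %in% names(frags)
  n <- nrow(origins)
  out <- rep(NA_real_, n)
  for (ch in unique(origins$chrom)) {
    sel <- which(frags$chrom == ch)
    ord <- sel[order(mids[sel])]
    mv <- mids[ord]
    sv <- frags$strand[ord]
    cv <- if (has_cell) frags$cell[ord] else seq_along(ord)
    for (i in which(origins$chrom == ch)) {
      m <- origins$mid[i]
      flank_var <- function(lo, hi) {
        a <- findInterval(lo - 1, mv) + 1
        b <- findInterval(hi - 1, mv)
        if (b < a) return(NA_real_)
        nn <- b - a + 1
        w <- sum(sv[a:b] == "+")
        mbar <- nn / length(unique(cv[a:b]))
        f <- (w + 1) / (nn + 2)
        f * (1 - f) / nn * mbar
      }
      vl <- flank_var(m - flank, m)
      vr <- flank_var(m, m + flank)
      out[i] <- sqrt(vl + vr)
    }
  }
  out
}

#' Paired comparison of two OEM tables
#'
#' Two-sided paired t-test on per-origin OEM differences (A - B) over the
#' shared origin list; pairs with an undefined OEM on either side are
#' dropped and the number of pairs actually used is reported.  One global
#' comparison is made, so no multiple-testing correction applies.
#'
#' @param table_a,table_b OEM tables over the same origins (matched by id).
#' @return List with `mean_diff`, `t`, `p_value`, `n_pairs`.
#' @export
compare_conditions <- function(table_a, table_b) {
  m <- merge(table_a[, list(id, oem_a = oem)],
             table_b[, list(id, oem_b = oem)], by = "id")
  d <- m$oem_a - m$oem_b
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("fewer than 2 origin pairs with defined OEM")
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # degenerate: identical differences; t-test undefined, report directly
    return(list(mean_diff = mean(d), t = if (mean(d) == 0) 0 else Inf,
                p_value = if (mean(d) == 0) 1 else 0,
                n_pairs = length(d)))
  }
  tt <- stats::t.test(d)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       p_value = tt$p.value, n_pairs = length(d))
}

.profile_grid <- function(halfwidth, bin) {
  if (halfwidth %% bin != 0) stop("bin must divide halfwidth")
  seq(-halfwidth, halfwidth - bin, by = bin)
}

# pooled per-relative-bin Watson/Crick counts around origin midpoints;
# optional strand gating windows used by meta_coverage's stranded mode
.rel_counts <- function(frags, origins, halfwidth, bin) {
  starts <- .profile_grid(halfwidth, bin)
  nb <- length(starts)
  crick <- watson <- numeric(nb)
  mids <- fragment_midpoints(frags)
  for (ch in unique(origins$chrom)) {
    sel <- frags$chrom == ch
    if (!any(sel)) next
    ord <- order(mids[sel])
    mv <- mids[sel][ord]
    sv <- frags$strand[sel][ord]
    for (m in origins$mid[origins$chrom == ch]) {
      lo <- findInterval(m - halfwidth - 1, mv) + 1
      hi <- findInterval(m + halfwidth - 1, mv)
      if (hi < lo) next
      rel <- mv[lo:hi] - m
      bidx <- floor(rel / bin) + halfwidth / bin + 1
      isc <- sv[lo:hi] == "-"
      crick <- crick + tabulate(bidx[isc], nbins = nb)
      watson <- watson + tabulate(bidx[!isc], nbins = nb)
    }
  }
  data.table::data.table(rel_bin_start = starts, watson = watson,
                         crick = crick)
}

#' Origin-anchored strand-bias profile
#'
#' Pools fragment counts across origins into bins of relative position
#' (fragment midpoint minus origin midpoint) and reports the fraction of
#' reads on the Crick strand per bin, computed on the pooled counts (not
#' averaged per origin).  For an efficient origin the fraction is ~0 left
#' of the origin and ~1 right of it.
#'
#' @param frags Stranded-fragment table (Okazaki fragments or 1-bp ribo
#'   records).
#' @param origins Origin table.
#' @param halfwidth Window half-width in bp (default 10 kb).
#' @param bin Bin width in bp; must divide `halfwidth`.
#' @param per_origin_mean If TRUE, average per-origin fractions instead of
#'   pooling counts (non-default alternative).
#' @return A `strand_bias_profile` `data.table(rel_bin_start, crick, total,
#'   fraction_crick)` with attributes `halfwidth`, `bin`, `n_origins`.
#' @export
strand_bias_profile <- function(frags, origins, halfwidth = 10000,
                                bin = 100, per_origin_mean = FALSE) {
  if (!per_origin_mean) {
    rc <- .rel_counts(frags, origins, halfwidth, bin)
    prof <- data.table::data.table(
      rel_bin_start = rc$rel_bin_start,
      crick = rc$crick, total = rc$watson + rc$crick)
    prof[, fraction_crick := ifelse(total > 0, crick / pmax(total, 1), NA_real_)]
  } else {
    fr <- lapply(seq_len(nrow(origins)), function(i) {
      p <- strand_bias_profile(frags, origins[i], halfwidth, bin)
      p$fraction_crick
    })
    fmat <- do.call(cbind, fr)
    prof <- data.table::data.table(
      rel_bin_start = .profile_grid(halfwidth, bin),
      crick = NA_real_, total = NA_real_,
      fraction_crick = rowMeans(fmat, na.rm = TRUE))
  }
  data.table::setattr(prof, "halfwidth", halfwidth)
  data.table::setattr(prof, "bin", bin)
  data.table::setattr(prof, "n_origins", nrow(origins))
  data.table::setattr(prof, "class",
                      c("strand_bias_profile", class(prof)))
  prof
}

.check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$rel_bin_start != b$rel_bin_start))
    stop("profiles are on different bin grids")
}

#' Difference between two strand-bias profiles
#'
#' Per-bin `fraction_crick(A) - fraction_crick(B)` on identical grids;
#' NA where either input is undefined.
#'
#' @param profile_a,profile_b Profiles from [strand_bias_profile()] (or
#'   [ribo_strand_bias_profile()]) on the same grid.
#' @return `data.table(rel_bin_start, delta)` with the grid attributes.
#' @export
delta_profile <- function(profile_a, profile_b) {
  .check_same_grid(profile_a, profile_b)
  d <- data.table::data.table(
    rel_bin_start = profile_a$rel_bin_start,
    delta = profile_a$fraction_crick - profile_b$fraction_crick)
  data.table::setattr(d, "halfwidth", attr(profile_a, "halfwidth"))
  data.table::setattr(d, "bin", attr(profile_a, "bin"))
  d
}

#' Write an OEM table (with summary) as TSV
#' @param tab An OEM table from [oem_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oem_tsv <- function(tab, path) {
  s <- attr(tab, "summary")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# per-origin OEM; flanks 0-based half-open; mean=%.6g min=%.6g max=%.6g n_defined=%d/%d",
    s$mean, s$min, s$max, s$n_defined, s$n_origins), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a strand-bias or delta profile as TSV
#' @param prof A profile table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(prof, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin-anchored profile; rel_bin_start in bp (0-based, bin=%s bp, halfwidth=%s bp)",
                     attr(prof, "bin"), attr(prof, "halfwidth")), con)
  utils::write.table(prof, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
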