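#' Expected OEM by analytic integration over firing configurations
#'
#' Computes, independently of the read-level pipeline, the expected OEM of
#' every origin at a sample time: the per-base probability that a locus has
#' been replicated by a rightward vs leftward fork is obtained by combining,
#' across origins, the arrival-time distributions of their forks (firing
#' times discretized on a fixed grid; origins are independent, so the
#' distribution of the minimum arrival is a product of survival functions —
#' an exact enumeration over fire/not-fire patterns without the 2^k cost).
#' Expected Watson/Crick mass in each +/- `flank` window is the integral of
#' those probabilities over the window (every replicated base contributes
#' equal lagging-strand read mass), combined by
#' OEM = W_L / (W_L + C_L) - W_R / (W_R + C_R).
#'
#' Ties between convergent forks are resolved toward the leftmost source
#' origin (i.e. rightward), matching [simulate_cell()].
#'
#' @param model An [sphase_model()].
#' @param genome A `genome` object.
#' @param origins Origin table.
#' @param sample_time Minutes into S phase.
#' @param flank Flank width (bp) on each side of the origin midpoint;
#'   default 10 kb.  Flanks are truncated at chromosome ends.
#' @param time_step Firing-time discretization grid (min).
#' @param pos_step Spatial integration stride (bp).
#' @param max_origins Guard on the number of origins per chromosome; above
#'   this the caller is instructed to chunk chromosome-wise.
#' @return A `data.table(id, chrom, mid, oem_expected, wl, cl, wr, cr)`
#'   where the last four columns are expected per-base direction masses.
#' @export
expected_oem_oracle <- function(model, genome, origins, sample_time,
                                flank = 10000, time_step = 0.2,
                                pos_step = 50, max_origins = 64) {
  eff <- .model_effective(model, nrow(origins))
  g <- seq(0, sample_time, by = time_step)
  lens <- unclass(genome)
  res <- vector("list", nrow(origins))
  for (ch in unique(origins$chrom)) {
    sel <- which(origins$chrom == ch)
    if (length(sel) > max_origins)
      stop("more than ", max_origins, " origins on ", ch,
           "; run the oracle chromosome-wise in chunks")
    xs <- origins$mid[sel]
    p <- eff$p[sel]; mu <- eff$mu[sel]; sg <- eff$sigma[sel]
    for (jj in seq_along(sel)) {
      o <- sel[jj]
      m <- xs[jj]
      lpos <- .seq_guard(max(0, m - flank), m - 1, pos_step)
      rpos <- .seq_guard(m, min(lens[[ch]] - 1, m + flank - 1), pos_step)
      lr <- .dir_prob(lpos, xs, p, mu, sg, eff$v, g)
      rr <- .dir_prob(rpos, xs, p, mu, sg, eff$v, g)
      wl <- sum(lr$left); cl <- sum(lr$right)
      wr <- sum(rr$left); cr <- sum(rr$right)
      oemv <- if (wl + cl <= 0 || wr + cr <= 0) NA_real_
              else wl / (wl + cl) - wr / (wr + cr)
      res[[o]] <- data.table::data.table(
        id = origins$id[o], chrom = ch, mid = m,
        oem_expected = oemv, wl = wl, cl = cl, wr = wr, cr = cr)
    }
  }
  data.table::rbindlist(res)
}

#' Expected replicated fraction of the genome
#'
#' Analytic mean, over cells, of the fraction of the genome replicated by
#' `sample_time`, computed from the same arrival-time machinery as
#' [expected_oem_oracle()].  Used to pick matched replicated-fraction
#' checkpoints when comparing conditions whose S phases progress at
#' different speeds.
#'
#' @inheritParams expected_oem_oracle
#' @param pos_step Spatial stride (bp) for the genome-wide average.
#' @return Scalar in \[0, 1\].
#' @export
expected_replicated_fraction <- function(model, genome, origins, sample_time,
                                         time_step = 0.5, pos_step = 5000) {
  eff <- .model_effective(model, nrow(origins))
  g <- seq(0, sample_time, by = time_step)
  lens <- unclass(genome)
  tot <- 0; npos <- 0
  for (ch in names(lens)) {
    sel <- which(origins$chrom == ch)
    pos <- .seq_guard(0, lens[[ch]] - 1, pos_step)
    npos <- npos + length(pos)
    if (!length(sel)) next
    pr <- .dir_prob(pos, origins$mid[sel], eff$p[sel], eff$mu[sel],
                    eff$sigma[sel], eff$v, g)
    tot <- tot + sum(pr$right + pr$left)
  }
  tot / npos
}

#' Sample time at which a model reaches a target replicated fraction
#'
#' Monotone bisection on [expected_replicated_fraction()].
#'
#' @inheritParams expected_replicated_fraction
#' @param target Replicated fraction in (0, 1).
#' @param interval Search interval for the time (min).
#' @return Sample time (min).
#' @export
time_at_replicated_fraction <- function(model, genome, origins, target,
                                        interval = c(1, 200), ...) {
  f <- function(t) expected_replicated_fraction(model, genome, origins, t,
                                                ...) - target
  stats::uniroot(f, interval, tol = 0.1)$root
}

.seq_guard <- function(lo, hi, by) {
  if (hi < lo) numeric(0) else seq(lo, hi, by = by)
}

# truncated-at-0 normal CDF, elementwise in t
.ptrunc_norm0 <- function(t, mu, sigma) {
  if (sigma == 0) return(as.numeric(t >= max(mu, 0)))
  p0 <- stats::pnorm(0, mu, sigma)
  pmax(0, (stats::pnorm(t, mu, sigma) - p0) / (1 - p0))
}

# P(replicated rightward) and P(replicated leftward) at each position by
# sample time (the last grid point).  For positions `pos` (vector) and all
# origins on the chromosome: accumulate log-survival of the best rightward
# arrival A (sources at or left of the position) and best leftward arrival
# B (sources strictly right) on the time grid g, then
#   P(right) = sum_j P(A in cell j) * P(B >= cell j)   (ties -> rightward)
#   P(left)  = sum_j P(B in cell j) * P(A >  cell j).
.dir_prob <- function(pos, xs, p, mu, sigma, v, g) {
  G <- length(g); P <- length(pos)
  if (P == 0L) return(list(right = numeric(0), left = numeric(0)))
  logSA <- matrix(0, G, P)
  logSB <- matrix(0, G, P)
  for (i in seq_along(xs)) {
    if (p[i] <= 0) next
    d <- abs(pos - xs[i]) / v                    # travel time to each pos
    tt <- outer(g, d, "-")                       # firing-time threshold
    Fi <- .ptrunc_norm0(tt, mu[i], sigma[i])
    dim(Fi) <- dim(tt)
    ls <- log1p(-p[i] * Fi)
    right_src <- xs[i] <= pos                    # column mask
    logSA[, right_src] <- logSA[, right_src] + ls[, right_src, drop = FALSE]
    logSB[, !right_src] <- logSB[, !right_src] + ls[, !right_src, drop = FALSE]
  }
  PA <- 1 - exp(logSA)                           # P(A <= g_j), G x P
  PB <- 1 - exp(logSB)
  pA <- rbind(PA[1, , drop = FALSE], diff(PA))   # P(A in cell j)
  pB <- rbind(PB[1, , drop = FALSE], diff(PB))
  SBprev <- rbind(matrix(0, 1, P), PB[-G, , drop = FALSE])  # P(B <= g_{j-1})
  right <- colSums(pA * (1 - SBprev))
  left <- colSums(pB * (1 - PA))
  list(right = right, left = left)
}
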