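#' Stochastic S-phase model
#'
#' Ground-truth generative model for nascent-strand sequencing.  Each cell
#' draws, independently per origin, whether the origin fires (probability =
#' competence, optionally scaled by a depletion factor) and when (truncated
#' normal at 0).  Fired origins launch two constant-speed forks; a locus is
#' replicated by whichever fork arrives first (passive replication), forks
#' terminate exactly where convergent forks meet.  Okazaki fragments tile
#' the nascent lagging strand (Crick behind rightward forks, Watson behind
#' leftward forks); ribonucleotides are incorporated by polymerase at
#' strand-specific rates; restriction-site (SbfI) reads provide a
#' depth-independent loading control.
#'
#' @param competence Per-origin firing probability in a cell, in \[0, 1\]
#'   (recycled to the number of origins at simulation time).
#' @param t_mean,t_sd Mean (min, >= 0) and spread (min, >= 0) of each
#'   origin's firing-time law, a normal truncated at 0.  `t_sd = 0` gives a
#'   deterministic firing time.
#' @param fork_speed Fork speed v in bp/min (> 0).  Default 1500 bp/min,
#'   the order of magnitude measured for S. cerevisiae replication forks.
#' @param frag_len_mean,frag_len_sd Okazaki fragment length law (bp);
#'   default mean 165 bp (nucleosome periodicity), sd 30 bp.
#' @param frag_rate Fragments sampled per replicated lagging-strand kb per
#'   cell (sequencing depth knob).
#' @param r_pole,r_pola,r_pold Ribonucleotide incorporation rates (events
#'   per nascent kb) for Pol epsilon (leading strand), Pol alpha (Okazaki
#'   5'-proximal) and Pol delta (uniform on lagging strand).  Defaults
#'   emulate a ribonucleotide-hypersensitive Pol epsilon variant
#'   (pol2-M644G-like) on an RNase-H2-null background, where leading-strand
#'   incorporation dominates.
#' @param reroute Fraction of lagging-strand synthesis performed by Pol
#'   epsilon instead of Pol delta (0 = normal division of labour).  When
#'   > 0, Pol epsilon events also appear on the lagging strand at rate
#'   `reroute * r_pole` and the Pol delta rate is scaled by `1 - reroute`.
#' @param sbfi_sites `data.frame(chrom, pos)` of restriction-site positions
#'   (0-based), or NULL.
#' @param depletion Depletion factor d in (0, 1\] multiplying every
#'   competence and, when `deplete_speed`, the fork speed (the default:
#'   polymerase depletion both lowers firing and slows forks).
#' @param deplete_speed,deplete_competence Logicals decoupling which
#'   parameters the depletion factor touches.
#' @param seed Base seed; per-cell substreams are derived deterministically
#'   from (seed, cell index), so any cell can be regenerated in isolation.
#' @return An `sphase_model` list.
#' @export
sphase_model <- function(competence = 0.6, t_mean = 15, t_sd = 5,
                         fork_speed = 1500,
                         frag_len_mean = 165, frag_len_sd = 30,
                         frag_rate = 0.05,
                         r_pole = 2, r_pola = 0.05, r_pold = 0.1,
                         reroute = 0,
                         sbfi_sites = NULL,
                         depletion = 1,
                         deplete_speed = TRUE, deplete_competence = TRUE,
                         seed = 1L) {
  stopifnot(all(competence >= 0 & competence <= 1),
            all(t_mean >= 0), all(t_sd >= 0),
            fork_speed > 0, frag_len_mean > 0, frag_len_sd >= 0,
            frag_rate >= 0, r_pole >= 0, r_pola >= 0, r_pold >= 0,
            reroute >= 0, reroute <= 1,
            depletion > 0, depletion <= 1)
  structure(list(
    competence = competence, t_mean = t_mean, t_sd = t_sd,
    fork_speed = fork_speed,
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    frag_rate = frag_rate,
    r_pole = r_pole, r_pola = r_pola, r_pold = r_pold,
    reroute = reroute,
    sbfi_sites = sbfi_sites,
    depletion = depletion,
    deplete_speed = deplete_speed, deplete_competence = deplete_competence,
    seed = as.integer(seed)
  ), class = "sphase_model")
}

#' Apply a depletion factor to a model
#'
#' @param model An `sphase_model`.
#' @param d Depletion factor in (0, 1].
#' @param speed,competence Which parameters d multiplies.
#' @return The modified model.
#' @export
deplete <- function(model, d, speed = TRUE, competence = TRUE) {
  stopifnot(d > 0, d <= 1)
  model$depletion <- d
  model$deplete_speed <- speed
  model$deplete_competence <- competence
  model
}

# effective (post-depletion) per-origin competence and fork speed
.model_effective <- function(model, n_origins) {
  p <- rep_len(model$competence, n_origins)
  mu <- rep_len(model$t_mean, n_origins)
  sg <- rep_len(model$t_sd, n_origins)
  v <- model$fork_speed
  if (model$depletion < 1) {
    if (model$deplete_competence) p <- p * model$depletion
    if (model$deplete_speed) v <- v * model$depletion
  }
  list(p = p, mu = mu, sigma = sg, v = v)
}

# truncated-at-0 normal firing times
.rtrunc_norm0 <- function(n, mu, sigma) {
  out <- pmax(mu, 0)
  pos <- sigma > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mu[pos], sigma[pos])
    out[pos] <- stats::qnorm(stats::runif(sum(pos), lo, 1), mu[pos], sigma[pos])
  }
  out
}

# deterministic per-cell substream seed, < 2^31
.cell_seed <- function(seed, cell) {
  as.integer(((as.numeric(seed) %% 2147483647) * 69621 + cell * 48271) %%
               2147483629) + 1L
}

# Replicated intervals on one chromosome given fired-origin positions xs
# (sorted) and firing times ts.  Rightward arrival at x from origin i
# (x_i <= x) is t_i + (x - x_i)/v = a_i + x/v with a_i = t_i - x_i/v;
# leftward arrival is b_i - x/v with b_i = t_i + x_i/v.  Within each
# segment between adjacent fired origins the best a (prefix min) and best
# b (suffix min) are constant, so replicated spans and the collision point
# x* = v (B - A) / 2 are closed-form.  Direction at integer base x is
# rightward iff the rightward arrival is <= the leftward one (tie broken
# toward the leftmost, i.e. the left-hand, source origin).
.chrom_intervals <- function(xs, ts, idx, v, t_s, L) {
  k <- length(xs)
  if (k == 0L)
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("start", "end", "dir", "origin"))))
  a <- ts - xs / v
  b <- ts + xs / v
  prefA <- cummin(a)
  sufB <- rev(cummin(rev(b)))
  # index of the prefix/suffix argmin, for source-origin annotation
  prefI <- seq_len(k); sufI <- seq_len(k)
  for (i in seq_len(k)[-1]) if (a[i] >= prefA[i - 1]) prefI[i] <- prefI[i - 1]
  for (i in rev(seq_len(k))[-1]) if (b[i] >= sufB[i + 1]) sufI[i] <- sufI[i + 1]
  rows <- vector("list", 2L * (k + 1L))
  nr <- 0L
  for (j in 0:k) {
    lo <- if (j == 0L) 0 else xs[j]
    hi <- if (j == k) L else xs[j + 1L]
    A <- if (j >= 1L) prefA[j] else Inf
    B <- if (j < k) sufB[j + 1L] else Inf
    xstar <- v * (B - A) / 2            # right wins at x <= xstar
    if (is.finite(A)) {
      re <- floor(min(hi - 1, v * (t_s - A), xstar))
      if (re >= lo) {
        nr <- nr + 1L
        rows[[nr]] <- c(lo, re + 1, 1, idx[prefI[j]])
      }
    }
    if (is.finite(B)) {
      ls <- max(lo, ceiling(v * (B - t_s)),
                if (is.finite(xstar)) floor(xstar) + 1 else -Inf)
      if (ls <= hi - 1) {
        nr <- nr + 1L
        rows[[nr]] <- c(ls, hi, -1, idx[sufI[j + 1L]])
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  if (is.null(out))
    out <- matrix(numeric(0), ncol = 4)
  dimnames(out) <- list(NULL, c("start", "end", "dir", "origin"))
  out
}

#' Simulate one cell's replication state
#'
#' Draws firing and firing times for every origin and returns the
#' replicated intervals of each chromosome at `sample_time`, annotated
#' with fork direction (+1 rightward, -1 leftward) and source origin.
#' A locus x is replicated iff `min_i [t_i + |x - x_i| / v] <= sample_time`
#' over fired origins i; its direction is rightward iff the arg-min origin
#' lies at or left of x (ties toward the leftmost source).  Chromosomes
#' without origins stay unreplicated.
#'
#' @param model An [sphase_model()].
#' @param genome A `genome` object.
#' @param origins Origin table (see [origins()]).
#' @param sample_time Minutes into S phase (>= 0).
#' @param seed Optional seed for this cell (e.g. from the model's per-cell
#'   substream); NULL uses the current RNG state.
#' @return A `cell_state`: list with `intervals` (per chromosome a matrix
#'   with columns start, end, dir, origin), `fired`, `t_fire`.
#' @export
simulate_cell <- function(model, genome, origins, sample_time, seed = NULL) {
  stopifnot(sample_time >= 0)
  if (!is.null(seed)) set.seed(seed)
  eff <- .model_effective(model, nrow(origins))
  n <- nrow(origins)
  fired <- stats::runif(n) < eff$p
  t_fire <- .rtrunc_norm0(n, eff$mu, eff$sigma)
  t_fire[!fired] <- NA_real_
  lens <- unclass(genome)
  ints <- vector("list", length(lens))
  names(ints) <- names(lens)
  for (ch in unique(origins$chrom)) {
    sel <- which(origins$chrom == ch & fired)
    ints[[ch]] <- .chrom_intervals(origins$mid[sel], t_fire[sel], sel,
                                   eff$v, sample_time, lens[[ch]])
  }
  empty <- matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("start", "end", "dir", "origin")))
  for (ch in names(ints)) if (is.null(ints[[ch]])) ints[[ch]] <- empty
  structure(list(intervals = ints, fired = fired, t_fire = t_fire,
                 sample_time = sample_time, fork_speed = eff$v,
                 chrom_lengths = lens),
            class = "cell_state")
}

# flatten a state's intervals to one matrix plus chromosome labels
.state_flat <- function(state) {
  chs <- names(state$intervals)
  mats <- state$intervals
  nr <- vapply(mats, nrow, 0L)
  list(chrom = rep(chs, nr), m = do.call(rbind, mats))
}

# low-level fragment emission; returns list of columns, not a data.table,
# so the per-cell loop stays cheap
.emit_okz <- function(state, model) {
  fl <- .state_flat(state)
  m <- fl$m
  if (is.null(m) || nrow(m) == 0L)
    return(list(chrom = character(0), start = numeric(0),
                end = numeric(0), strand = character(0)))
  len <- m[, "end"] - m[, "start"]
  nfr <- stats::rpois(nrow(m), model$frag_rate * len / 1000)
  i <- rep.int(seq_len(nrow(m)), nfr)
  if (!length(i))
    return(list(chrom = character(0), start = numeric(0),
                end = numeric(0), strand = character(0)))
  # place fragments by midpoint, uniform within the interval: keeps the
  # midpoint density exactly uniform (clipping spans to the interval would
  # pile midpoints up against direction boundaries); spans are clipped at
  # chromosome ends only
  mid_u <- floor(stats::runif(length(i), m[i, "start"], m[i, "end"]))
  fl_len <- pmax(1, round(stats::rnorm(length(i), model$frag_len_mean,
                                       model$frag_len_sd)))
  cl <- state$chrom_lengths[fl$chrom[i]]
  s <- pmax(0, mid_u - fl_len %/% 2)
  e <- pmin(cl, mid_u - fl_len %/% 2 + fl_len)
  list(chrom = fl$chrom[i], start = s, end = e,
       strand = ifelse(m[i, "dir"] > 0, "-", "+"))
}

#' Emit Okazaki fragments from a replication state
#'
#' Fragments are placed uniformly within replicated intervals at
#' `frag_rate` per lagging-strand kb, lengths drawn from the fragment
#' length law and clipped to the interval.  Strand is Crick (`"-"`) behind
#' rightward forks and Watson (`"+"`) behind leftward forks.
#'
#' @param state A `cell_state` from [simulate_cell()].
#' @param model The [sphase_model()].
#' @param seed Optional seed.
#' @return A stranded-fragment `data.table`.
#' @export
emit_okazaki_fragments <- function(state, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.table::as.data.table(.emit_okz(state, model))
}

# exponential offset (mean 15 bp) of Pol alpha events from the Okazaki
# fragment 5' end; the 5' end of a Crick fragment is its right edge
.emit_ribo <- function(state, model) {
  fl <- .state_flat(state)
  m <- fl$m
  out <- list(chrom = character(0), start = numeric(0), strand = character(0),
              pol = character(0))
  if (is.null(m) || nrow(m) == 0L) return(out)
  len <- m[, "end"] - m[, "start"]
  right <- m[, "dir"] > 0
  lead_strand <- ifelse(right, "+", "-")
  lag_strand <- ifelse(right, "-", "+")
  add <- function(rate_vec, strand_vec, pol, positions_fn) {
    n <- stats::rpois(nrow(m), rate_vec * len / 1000)
    i <- rep.int(seq_len(nrow(m)), n)
    if (!length(i)) return(NULL)
    list(chrom = fl$chrom[i], start = positions_fn(i),
         strand = strand_vec[i], pol = rep(pol, length(i)))
  }
  unif_pos <- function(i) floor(stats::runif(length(i), m[i, "start"], m[i, "end"]))
  alpha_pos <- function(i) {
    tl <- model$frag_len_mean
    ntile <- pmax(1, ceiling((m[i, "end"] - m[i, "start"]) / tl))
    tile <- floor(stats::runif(length(i), 0, ntile))
    off <- floor(stats::rexp(length(i), 1 / 15))
    p <- ifelse(right[i],
                m[i, "start"] + (tile + 1) * tl - 1 - off,
                m[i, "start"] + tile * tl + off)
    pmin(pmax(p, m[i, "start"]), m[i, "end"] - 1)
  }
  parts <- list(
    add(rep(model$r_pole, nrow(m)), lead_strand, "eps_lead", unif_pos),
    add(rep((1 - model$reroute) * model$r_pold, nrow(m)), lag_strand,
        "delta", unif_pos),
    if (model$reroute > 0)
      add(rep(model$reroute * model$r_pole, nrow(m)), lag_strand,
          "eps_lag", unif_pos),
    add(rep(model$r_pola, nrow(m)), lag_strand, "alpha", alpha_pos)
  )
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(out)
  list(chrom = unlist(lapply(parts, `[[`, "chrom")),
       start = unlist(lapply(parts, `[[`, "start")),
       strand = unlist(lapply(parts, `[[`, "strand")),
       pol = unlist(lapply(parts, `[[`, "pol")))
}

#' Emit ribonucleotide 5'-end reads from a replication state
#'
#' Pol epsilon events fall on the nascent leading strand (Watson behind
#' rightward forks, Crick behind leftward) at rate `r_pole` per nascent kb;
#' Pol delta events uniformly on the lagging strand at rate
#' `(1 - reroute) * r_pold`; Pol alpha events near Okazaki-fragment 5' ends
#' at rate `r_pola`; with `reroute > 0`, rerouted Pol epsilon events on the
#' lagging strand at rate `reroute * r_pole`.  All records are single-base.
#'
#' @inheritParams emit_okazaki_fragments
#' @return A stranded-fragment `data.table` with 1-bp records and a `pol`
#'   column labelling the emitting polymerase context.
#' @export
emit_ribo_reads <- function(state, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- .emit_ribo(state, model)
  data.table::data.table(chrom = r$chrom, start = r$start, end = r$start + 1,
                         strand = r$strand, pol = r$pol)
}

#' Emit restriction-site (SbfI) loading-control reads
#'
#' Poisson(`depth`) single-base reads per configured site, random strand.
#'
#' @param model An [sphase_model()] with non-empty `sbfi_sites`.
#' @param depth Expected reads per site (> 0).
#' @param seed Optional seed.
#' @return A stranded-fragment `data.table` of 1-bp records at site
#'   positions.
#' @export
emit_sbfi_reads <- function(model, depth, seed = NULL) {
  sites <- model$sbfi_sites
  if (is.null(sites) || nrow(sites) == 0L)
    stop("no SbfI sites configured in the model")
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(nrow(sites), depth)
  i <- rep.int(seq_len(nrow(sites)), n)
  data.table::data.table(
    chrom = as.character(sites$chrom)[i],
    start = as.numeric(sites$pos)[i],
    end = as.numeric(sites$pos)[i] + 1,
    strand = sample(c("+", "-"), length(i), replace = TRUE))
}

#' Simulate a pooled Okazaki-fragment library over many cells
#'
#' Runs [simulate_cell()] for `n_cells` cells (each on its own
#' deterministic substream derived from `seed`) at one sample time and
#' pools the emitted fragments, tracking per-origin fired fractions and
#' the mean replicated fraction of the genome — the ground truth the OEM
#' pipeline is benchmarked against.
#'
#' @inheritParams simulate_cell
#' @param n_cells Number of cells to pool.
#' @param seed Base seed (default: the model's).
#' @param ribo Also emit ribonucleotide reads per cell.
#' @return List with `fragments` (with a `cell` column), `ribo` (or NULL),
#'   `fired_fraction` (per origin), `replicated_fraction` (mean over
#'   cells), `n_cells`, `sample_time`.
#' @export
simulate_pool <- function(model, genome, origins, sample_time,
                          n_cells = 1000, seed = model$seed, ribo = FALSE) {
  fired_n <- numeric(nrow(origins))
  repl_bp <- 0
  frg <- vector("list", n_cells)
  rib <- if (ribo) vector("list", n_cells) else NULL
  glen <- sum(unclass(genome))
  for (cell in seq_len(n_cells)) {
    st <- simulate_cell(model, genome, origins, sample_time,
                        seed = .cell_seed(seed, cell))
    fired_n <- fired_n + st$fired
    repl_bp <- repl_bp + sum(vapply(
      st$intervals, function(m) sum(m[, "end"] - m[, "start"]), 0))
    f <- .emit_okz(st, model)
    f$cell <- rep.int(cell, length(f$start))
    frg[[cell]] <- f
    if (ribo) {
      r <- .emit_ribo(st, model)
      r$cell <- rep.int(cell, length(r$start))
      rib[[cell]] <- r
    }
  }
  bindcols <- function(lst, cols) {
    out <- lapply(cols, function(cn) unlist(lapply(lst, `[[`, cn),
                                            use.names = FALSE))
    names(out) <- cols
    dt <- data.table::as.data.table(out)
    dt$end <- if ("end" %in% cols) dt$end else dt$start + 1
    dt
  }
  fr <- bindcols(frg, c("chrom", "start", "end", "strand", "cell"))
  ri <- if (ribo) bindcols(rib, c("chrom", "start", "strand", "pol", "cell"))
  list(fragments = fr, ribo = ri,
       fired_fraction = fired_n / n_cells,
       replicated_fraction = repl_bp / (n_cells * glen),
       n_cells = n_cells, sample_time = sample_time)
}
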