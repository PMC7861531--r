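# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no data files.

toy_genome <- function(lens = c(chrA = 100000, chrB = 80000),
                       exclude = character()) {
  genome(lens, exclude = exclude)
}

# n random fragments on a genome (uniform positions, lengths ~ U(50, 300))
rand_frags <- function(n, g = toy_genome(), seed = 1) {
  set.seed(seed)
  lens <- unclass(g)
  ch <- sample(names(lens), n, replace = TRUE)
  len <- sample(50:300, n, replace = TRUE)
  start <- floor(runif(n, 0, lens[ch] - len))
  fragments(ch, start, start + len,
            sample(c("+", "-"), n, replace = TRUE), genome = g)
}

# a one-chromosome world with k origins at given midpoints
sim_world <- function(mids, chrom_len = max(mids) + 50000, ...) {
  g <- genome(c(chrSim = chrom_len))
  ori <- origins(data.frame(chrom = "chrSim", start = mids - 500,
                            end = mids + 500), g)
  list(genome = g, origins = ori, model = sphase_model(...))
}

# brute-force per-fragment flank tally (independent of count_flanks)
bf_flanks <- function(frags, origin, flank) {
  m <- fragment_midpoints(frags)
  sel <- frags$chrom == origin$chrom[1]
  rel <- m[sel] - origin$mid[1]
  s <- frags$strand[sel]
  c(W_L = sum(rel >= -flank & rel < 0 & s == "+"),
    C_L = sum(rel >= -flank & rel < 0 & s == "-"),
    W_R = sum(rel >= 0 & rel < flank & s == "+"),
    C_R = sum(rel >= 0 & rel < flank & s == "-"))
}

# brute-force per-base direction scan (independent of .chrom_intervals):
# arrival from fired origin i at x is t_i + |x - x_i| / v; min wins,
# ties toward the leftmost origin; direction +1 if that origin is at or
# left of x, else -1; 0 = unreplicated.
bf_direction_map <- function(mids, t_fire, v, t_s, L) {
  dir <- integer(L)
  for (x in 0:(L - 1)) {
    arr <- t_fire + abs(x - mids) / v
    best <- min(arr)
    if (best > t_s) next
    src <- mids[which(arr == best)[1L]]   # leftmost arg-min (mids sorted)
    dir[x + 1L] <- if (src <= x) 1L else -1L
  }
  dir
}

# expand a cell_state's intervals into a per-base direction vector
state_direction_map <- function(state, chrom, L) {
  dir <- integer(L)
  m <- state$intervals[[chrom]]
  for (i in seq_len(nrow(m)))
    dir[(m[i, "start"] + 1):(m[i, "end"])] <- m[i, "dir"]
  dir
}

# deterministic fragment lattice tiling both strands uniformly
lattice_frags <- function(g, step = 50, len = 20) {
  lens <- unclass(g)
  parts <- lapply(names(lens), function(ch) {
    s <- seq(0, lens[[ch]] - len - 1, by = step)
    data.table::data.table(chrom = ch, start = rep(s, 2),
                           end = rep(s + len, 2),
                           strand = rep(c("+", "-"), each = length(s)))
  })
  data.table::rbindlist(parts)
}

write_bed6 <- function(frags, path = tempfile(fileext = ".bed")) {
  write_fragments_bed(frags, path)
  path
}
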