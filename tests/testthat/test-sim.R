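test_that("simulate_cell matches the first-passage closed forms", {
  w <- sim_world(50000, chrom_len = 100000, competence = 1, t_mean = 0,
                 t_sd = 0, fork_speed = 1000)
  st <- simulate_cell(w$model, w$genome, w$origins, 10, seed = 1)
  m <- st$intervals$chrSim
  # leftward on the left half, rightward on the right half; the boundary
  # base at exactly v*t is replicated (arrival <= sample time)
  expect_equal(m[m[, "dir"] == -1, c("start", "end")],
               c(start = 40000, end = 50000))
  expect_equal(m[m[, "dir"] == 1, c("start", "end")],
               c(start = 50000, end = 60001))

  # two synchronous origins: collision exactly at the midpoint, tie
  # resolved toward the leftmost source (rightward at 50000)
  w2 <- sim_world(c(40000, 60000), chrom_len = 100000, competence = 1,
                  t_mean = 0, t_sd = 0, fork_speed = 1000)
  st2 <- simulate_cell(w2$model, w2$genome, w2$origins, 30, seed = 1)
  dmap <- state_direction_map(st2, "chrSim", 100000)
  expect_equal(dmap[50000 + 1], 1L)   # base 50000: rightward
  expect_equal(dmap[50001 + 1], -1L)  # base 50001: leftward from origin 2
})

test_that("replication state equals an exhaustive per-base arg-min scan", {
  L <- 50000
  mids <- c(5000, 14000, 22000, 33000, 45000)
  for (seed in 1:3) {
    w <- sim_world(mids, chrom_len = L, competence = 0.7,
                   t_mean = c(2, 10, 5, 15, 3), t_sd = 3, fork_speed = 800)
    st <- simulate_cell(w$model, w$genome, w$origins, 20, seed = seed)
    fired <- which(st$fired)
    skip_if(length(fired) == 0)  # nothing replicated; trivially consistent
    bf <- bf_direction_map(mids[fired], st$t_fire[fired], 800, 20, L)
    expect_equal(state_direction_map(st, "chrSim", L), bf,
                 info = paste("seed", seed))
  }
})

test_that("chromosomes without origins stay unreplicated", {
  g <- genome(c(chrA = 50000, chrB = 50000))
  ori <- origins(data.frame(chrom = "chrA", start = 24500, end = 25500), g)
  m <- sphase_model(competence = 1, t_mean = 0, t_sd = 0)
  st <- simulate_cell(m, g, ori, 30, seed = 1)
  expect_equal(nrow(st$intervals$chrB), 0L)
  expect_gt(nrow(st$intervals$chrA), 0L)
})

test_that("okazaki emission: strand convention, rate and length recovery", {
  w <- sim_world(50000, chrom_len = 100000, competence = 1, t_mean = 0,
                 t_sd = 0, fork_speed = 1000, frag_rate = 0.5)
  st <- simulate_cell(w$model, w$genome, w$origins, 10, seed = 1)
  fr <- emit_okazaki_fragments(st, w$model, seed = 2)
  # wholly rightward interval emits only Crick; leftward only Watson
  expect_true(all(fr$strand[fr$start >= 50000] == "-"))
  expect_true(all(fr$strand[fr$end <= 50000] == "+"))
  # direction partition: simulator never emits Watson from rightward regions
  expect_false(any(fr$strand == "+" & fr$start >= 50000))

  # expected count = rate x replicated lagging length, within 3 SE (Poisson)
  pool <- simulate_pool(w$model, w$genome, w$origins, 10, n_cells = 1000,
                        seed = 3)
  lag_bp <- 1000 * 20001                       # per cell, deterministic model
  expected <- 0.5 * lag_bp / 1000
  expect_lt(abs(nrow(pool$fragments) - expected) / sqrt(expected), 3)
  # empirical mean fragment length within 2% of the configured mean
  # (interval clipping shortens a negligible share at these lengths)
  expect_lt(abs(mean(pool$fragments$end - pool$fragments$start) - 165) / 165,
            0.02)
})

test_that("ribo emission follows the polymerase placement rules", {
  w <- sim_world(50000, chrom_len = 100000, competence = 1, t_mean = 0,
                 t_sd = 0, fork_speed = 1000,
                 r_pole = 1, r_pola = 0, r_pold = 0)
  st <- simulate_cell(w$model, w$genome, w$origins, 10, seed = 1)
  rr <- emit_ribo_reads(st, w$model, seed = 2)
  # leading-strand convention: Watson where the fork moves rightward
  expect_true(all(rr$strand[rr$start >= 50000] == "+"))
  expect_true(all(rr$strand[rr$start < 50000] == "-"))
  expect_true(all(rr$end == rr$start + 1))

  # all rates zero -> empty output
  m0 <- sphase_model(competence = 1, t_mean = 0, t_sd = 0,
                     r_pole = 0, r_pola = 0, r_pold = 0)
  expect_equal(nrow(emit_ribo_reads(st, m0, seed = 3)), 0L)

  # per-strand totals match rate x strand length within 3 SE over cells
  w2 <- sim_world(50000, chrom_len = 100000, competence = 1, t_mean = 0,
                  t_sd = 0, fork_speed = 1000,
                  r_pole = 0.5, r_pola = 0.2, r_pold = 0.3)
  pool <- simulate_pool(w2$model, w2$genome, w2$origins, 10, n_cells = 500,
                        seed = 4, ribo = TRUE)
  repl_bp <- 500 * 20001
  for (spec in list(c("eps_lead", 0.5), c("alpha", 0.2), c("delta", 0.3))) {
    n <- sum(pool$ribo$pol == spec[1])
    ex <- as.numeric(spec[2]) * repl_bp / 1000
    expect_lt(abs(n - ex) / sqrt(ex), 3)
  }
})

test_that("pol alpha events sit near okazaki 5' ends", {
  # rightward region: Crick fragments, 5' end at the tile's right edge;
  # offsets are exponential(mean 15 bp), so positions mod tile length
  # should pile up just below the tile boundary
  w <- sim_world(50000, chrom_len = 200000, competence = 1, t_mean = 0,
                 t_sd = 0, fork_speed = 2000, frag_len_mean = 165,
                 r_pole = 0, r_pola = 2, r_pold = 0)
  st <- simulate_cell(w$model, w$genome, w$origins, 30, seed = 1)
  rr <- emit_ribo_reads(st, w$model, seed = 2)
  right <- rr[rr$start >= 50000]
  off_from_5p <- 164 - ((right$start - 50000) %% 165)
  expect_gt(mean(off_from_5p <= 30), 0.8)
})

test_that("sbfi emission hits configured sites at the configured depth", {
  sites <- data.frame(chrom = "chrSim", pos = seq(10000, 100000, by = 10000))
  m <- sphase_model(sbfi_sites = sites)
  rd <- emit_sbfi_reads(m, 100, seed = 1)
  expect_true(all(rd$start %in% sites$pos))
  expect_lt(abs(nrow(rd) - 1000) / sqrt(1000), 3)
  rd2 <- emit_sbfi_reads(m, 200, seed = 2)
  expect_lt(abs(nrow(rd2) - 2000) / sqrt(2000), 3)
  expect_error(emit_sbfi_reads(sphase_model(), 100), "no SbfI sites")
})

test_that("pooled simulation is deterministic and per-cell reproducible", {
  w <- sim_world(c(30000, 70000), chrom_len = 100000, competence = 0.6,
                 t_mean = 10, t_sd = 4)
  a <- simulate_pool(w$model, w$genome, w$origins, 20, n_cells = 50, seed = 5)
  b <- simulate_pool(w$model, w$genome, w$origins, 20, n_cells = 50, seed = 5)
  expect_identical(a$fragments, b$fragments)
  d <- simulate_pool(w$model, w$genome, w$origins, 20, n_cells = 50, seed = 6)
  expect_false(identical(a$fragments, d$fragments))
})

test_that("oem oracle: closed forms", {
  # isolated fully-competent origin -> OEM exactly 1 once flanks are covered
  w <- sim_world(50000, chrom_len = 100000, competence = 1, t_mean = 0,
                 t_sd = 0, fork_speed = 1000)
  orc <- expected_oem_oracle(w$model, w$genome, w$origins, 15)
  expect_equal(orc$oem_expected, 1)

  # competence-p origin between two always-firing synchronous equidistant
  # neighbours, sampled after completion -> OEM = 2p - 1 (non-firing cells
  # contribute fully convergent flanks)
  for (p in c(0.2, 0.5, 0.8)) {
    w <- sim_world(c(10000, 40000, 70000), chrom_len = 80000,
                   competence = c(1, p, 1), t_mean = 0, t_sd = 0,
                   fork_speed = 1000)
    orc <- expected_oem_oracle(w$model, w$genome, w$origins, 100)
    # agreement limited by the oracle's spatial/temporal discretization
    expect_lt(abs(orc$oem_expected[2] - (2 * p - 1)), 0.01)
  }
})

test_that("oem oracle matches a Monte-Carlo estimate within 3 SE", {
  w <- sim_world(c(40000, 90000, 140000), chrom_len = 180000,
                 competence = c(0.8, 0.4, 0.7), t_mean = c(8, 15, 10),
                 t_sd = 4, fork_speed = 1500, frag_rate = 0.05)
  n_cells <- 20000
  pool <- simulate_pool(w$model, w$genome, w$origins, 60, n_cells = n_cells,
                        seed = 11)
  tab <- oem_table(pool$fragments, w$origins)
  orc <- expected_oem_oracle(w$model, w$genome, w$origins, 60)
  se <- oem_se(pool$fragments, w$origins)
  z <- (tab$oem - orc$oem_expected) / se
  expect_true(all(abs(z) < 3), info = paste(round(z, 2), collapse = " "))
})

test_that("oracle OEM is monotone non-increasing in sample time", {
  w <- sim_world(c(30000, 80000, 130000), chrom_len = 160000,
                 competence = c(1, 0.5, 1), t_mean = 0, t_sd = 0,
                 fork_speed = 1000)
  times <- c(12, 20, 30, 40, 60, 90)
  oems <- vapply(times, function(t)
    expected_oem_oracle(w$model, w$genome, w$origins, t)$oem_expected[2], 0)
  expect_true(all(diff(oems) <= 1e-9))
})

test_that("enumeration guard points at chromosome-wise chunking", {
  g <- genome(c(chrA = 10000000))
  mids <- seq(50000, 9950000, length.out = 70)
  ori <- origins(data.frame(chrom = "chrA", start = mids - 100,
                            end = mids + 100), g)
  m <- sphase_model()
  expect_error(expected_oem_oracle(m, g, ori, 10), "chromosome-wise")
})
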