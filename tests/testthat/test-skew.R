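# GC-skew profiles, origin prediction, inversions and scenario ranking.

test_that("windowed skew arithmetic and degenerate windows", {
  s <- strrep("GGGGCC", 100)  # every window has skew (4-2)/6
  prof <- gc_skew(genome_record("g", s, topology = "linear"),
                  window = 120, step = 60)
  expect_true(all(abs(prof$skew - 1 / 3) < 1e-12))
  expect_false(any(prof$degenerate))

  at <- strrep("AT", 200)
  prof <- gc_skew(genome_record("g", at, topology = "linear"),
                  window = 100, step = 100)
  expect_true(all(prof$degenerate))
  expect_true(all(prof$skew == 0))
  expect_error(gc_skew(at, window = 1000), "window larger")
})

test_that("cumulative skew endpoint equals G minus C, any window choice", {
  g <- simulate_skewed_genome(length = 30000, seed = 2)
  v <- strsplit(g$seq, "")[[1]]
  gc_diff <- sum(v == "G") - sum(v == "C")
  for (w in c(500, 1000, 3000)) {
    prof <- gc_skew(g, window = w, step = w %/% 2)
    expect_equal(prof$cumulative[length(prof$cumulative)], gc_diff)
  }
})

test_that("reverse complement negates and reverses the skew profile", {
  g <- rdna(20000, seed = 3)
  p1 <- gc_skew(genome_record("g", g, topology = "linear"),
                window = 1000, step = 1000)
  p2 <- gc_skew(genome_record("g", revcomp_chr(g), topology = "linear"),
                window = 1000, step = 1000)
  expect_equal(p2$skew, -rev(p1$skew))
})

test_that("origin and terminus land at the planted skew flip", {
  for (seed in 1:5) {
    L <- 80000
    flip <- 37000
    g <- simulate_skewed_genome(length = L, terminus = flip, skew = 0.12,
                                seed = seed)
    prof <- gc_skew(g, window = 2000, step = 400)
    oc <- predict_origin(prof)
    expect_true(oc$confident)
    # origin at position 0 (mod L), terminus at the flip, within one window
    d_or <- min(oc$origin, L - oc$origin)
    expect_lte(d_or, 2000)
    expect_lte(abs(oc$terminus - flip), 2000)
  }
})

test_that("an A/T-only genome yields no confident origin call", {
  prof <- gc_skew(genome_record("g", strrep("AT", 30000)), window = 1000,
                  step = 1000)
  oc <- predict_origin(prof)
  expect_false(oc$confident)
  expect_true(is.na(oc$origin))
})

test_that("origin/terminus calls are equivariant under genome rotation", {
  g <- simulate_skewed_genome(length = 60000, terminus = 30000, skew = 0.12,
                              seed = 6)
  r <- 17000
  rot <- paste0(substr(g$seq, r + 1, 60000), substr(g$seq, 1, r))
  oc1 <- predict_origin(gc_skew(g, 2000, 500))
  oc2 <- predict_origin(gc_skew(genome_record("r", rot), 2000, 500))
  circ_d <- function(a, b, L) min((a - b) %% L, (b - a) %% L)
  expect_lte(circ_d(oc2$origin, (oc1$origin - r) %% 60000, 60000), 2000)
  expect_lte(circ_d(oc2$terminus, (oc1$terminus - r) %% 60000, 60000), 2000)
})

test_that("dnaA proximity overrides the global minimum when appropriate", {
  # two-arm genome plus a second, shallower local minimum near 'dnaA'
  g <- simulate_skewed_genome(length = 80000, terminus = 40000, skew = 0.1,
                              seed = 7)
  prof <- gc_skew(g, window = 2000, step = 500)
  oc0 <- predict_origin(prof)
  ocd <- predict_origin(prof, dnaA_pos = oc0$origin)
  expect_equal(ocd$origin, oc0$origin)
})

test_that("symmetry score: ideal arms high, planted inversion lower, rotation invariant", {
  g <- simulate_skewed_genome(length = 100000, terminus = 50000, skew = 0.12,
                              seed = 4)
  prof <- gc_skew(g, 2000, 400)
  oc <- predict_origin(prof)
  s0 <- symmetry_score(prof, oc$origin, oc$terminus)
  expect_gte(s0, 0.99)

  gi <- apply_inversion(g, 20000, 45000)  # straddles one arm
  pi_ <- gc_skew(gi, 2000, 400)
  # same replication axis: the inversion breaks one arm's monotonicity
  si <- symmetry_score(pi_, oc$origin, oc$terminus)
  expect_lt(si, s0)

  r <- 31000
  rot <- genome_record("r", paste0(substr(g$seq, r + 1, 100000),
                                   substr(g$seq, 1, r)))
  pr <- gc_skew(rot, 2000, 400)
  ocr <- predict_origin(pr)
  sr <- symmetry_score(pr, ocr$origin, ocr$terminus)
  expect_lt(abs(sr - s0), 0.02)

  expect_error(symmetry_score(prof, 100, 200), "arm shorter")
})

test_that("apply_inversion is an involution preserving content and features", {
  g <- small_ancestor()
  L <- nchar(g$seq)
  g1 <- apply_inversion(g, 10000, 40000)
  g2 <- apply_inversion(g1, 10000, 40000)
  expect_identical(g2$seq, g$seq)
  expect_equal(nchar(g1$seq), L)
  t0 <- table(strsplit(g$seq, "")[[1]])
  t1 <- table(strsplit(g1$seq, "")[[1]])
  # single-strand composition changes under inversion (that is what moves
  # GC skew); the duplex content A+T and G+C is preserved
  expect_equal(t1[["A"]] + t1[["T"]], t0[["A"]] + t0[["T"]])
  expect_equal(t1[["G"]] + t1[["C"]], t0[["G"]] + t0[["C"]])
  expect_equal(nrow(g1$features), nrow(g$features))
  inside <- g$features$start >= 10000 & g$features$end <= 40000
  f_in <- g$features[inside, ]
  g1_tags <- g1$features[match(f_in$locus_tag, g1$features$locus_tag), ]
  expect_true(all(g1_tags$strand != f_in$strand))
  expect_equal(g1_tags$end - g1_tags$start, f_in$end - f_in$start)
  # straddling features are flagged broken
  strad <- g$features$start < 10000 & g$features$end > 10000
  if (any(strad)) {
    tags <- g$features$locus_tag[strad]
    expect_true(all(g1$features$broken[g1$features$locus_tag %in% tags]))
  }
})

test_that("planted repeat-mediated inversion ranks first, deterministically", {
  g <- simulate_skewed_genome(
    length = 80000, terminus = 40000, skew = 0.1, seed = 13,
    repeat_positions = list(c(15000, 55000), c(62000, 72000)))
  gi <- apply_inversion(g, 15750, 55750)
  reps <- maximal_repeats(gi, min_len = 500)
  rk1 <- rank_rearrangements(gi, reps, reference_genome = g,
                             window = 2000, step = 400)
  expect_gte(nrow(rk1), 2)
  expect_lte(abs(rk1$b1[1] - 15750), 1500)
  expect_lte(abs(rk1$b2[1] - 55750), 1500)
  rk2 <- rank_rearrangements(gi, reps, reference_genome = g,
                             window = 2000, step = 400)
  expect_identical(rk1, rk2)
  # an already symmetric genome scores no candidate above the baseline
  rk0 <- rank_rearrangements(g, maximal_repeats(g, min_len = 500),
                             window = 2000, step = 400)
  expect_true(all(rk0$score <= 0.02))
  expect_equal(nrow(rank_rearrangements(g, maximal_repeats(rdna(30000, 1)))),
               0)
})
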