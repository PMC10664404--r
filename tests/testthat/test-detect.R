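# Repeat detection: coverage counting, smoothing/thresholding, region
# segmentation and unit splitting, checked against brute-force oracles and
# planted truth.

test_that("coverage vector counts query and subject intervals of each hit", {
  expect_equal(coverage_vector(data.frame(q_start = integer(), q_end = integer(),
                                          s_start = integer(), s_end = integer()),
                               10),
               rep(0L, 10))
  h <- data.frame(q_start = 0L, q_end = 4L, s_start = 4L, s_end = 8L)
  expect_equal(coverage_vector(h, 12), c(rep(1L, 8), rep(0L, 4)))
  expect_equal(coverage_vector(rbind(h, h), 12), c(rep(2L, 8), rep(0L, 4)))
  expect_error(coverage_vector(data.frame(q_start = 0L, q_end = 20L,
                                          s_start = 0L, s_end = 4L), 10),
               "outside")
})

test_that("sum of coverage equals total aligned interval length", {
  g <- circular_genome("p", {
    set.seed(9)
    x <- random_genome(300)
    paste0(random_genome(400), x, random_genome(500), x,
           revcomp(x), random_genome(300))
  })
  hits <- self_align(g)
  expect_gt(nrow(hits), 0)
  y <- coverage_vector(hits, g$length)
  expect_equal(sum(y), sum(hits$q_end - hits$q_start + hits$s_end - hits$s_start))
})

test_that("smoothing matches a brute-force circular mean and tau follows the formula", {
  set.seed(4)
  y <- rpois(3000, 0.3)
  p <- detection_params(region_window = 100)
  prof <- smooth_threshold(y, p)
  expect_equal(prof$ys, brute_circular_mean(y, 100), tolerance = 1e-12)
  expect_equal(prof$tau, mean(prof$ys) / 2.5)

  yc <- rep(5L, 1000)
  prof <- smooth_threshold(yc, detection_params(region_window = 100))
  expect_true(all(abs(prof$ys - 5) < 1e-9))
  expect_equal(prof$tau, 5 / 2.5)

  prof_aff <- smooth_threshold(yc, detection_params(region_window = 100,
                                                    tau_mode = "affine"))
  expect_equal(prof_aff$tau, 5 * 2.5 - 1)

  expect_error(smooth_threshold(rep(1L, 50), detection_params(region_window = 100)),
               "window")
})

test_that("a single coverage block becomes one region with boundaries near the crossings", {
  y <- integer(10000)
  y[101:300] <- 5L
  prof <- smooth_threshold(y, detection_params())
  expect_equal(prof$tau, (5 * 200 / 10000) / 2.5)
  reg <- detect_regions(prof, "g")
  # with circular smoothing the low threshold lets the run wrap the origin;
  # it is then reported split at the linearization point and flagged
  if (nrow(reg) == 2) {
    expect_true(all(reg$wrapped))
    start_eff <- reg$start[2] - 10000  # signed circular coordinate
    end_eff <- reg$end[1]
  } else {
    expect_equal(nrow(reg), 1)
    start_eff <- reg$start
    end_eff <- reg$end
  }
  expect_lt(abs(start_eff - 100), 251)
  expect_lt(abs(end_eff - 300), 251)
  expect_true(start_eff < 100 && end_eff > 300)

  # nothing above threshold: empty region set
  flat <- smooth_threshold(rep(2L, 2000), detection_params(region_window = 100))
  flat$ys <- flat$ys * 0
  expect_equal(nrow(detect_regions(flat)), 0)
})

test_that("halving the threshold never loses a region", {
  sim <- simulate_genome(sim_config(genome_length = 60000, n_regions = 8,
                                    seed = 11))
  hits <- self_align(sim$genome)
  y <- coverage_vector(hits, sim$genome$length)
  reg1 <- detect_regions(smooth_threshold(y, detection_params()))
  reg2 <- detect_regions(smooth_threshold(y, detection_params(sensitivity = 5)))
  # every region found at sensitivity 2.5 is contained in one at sensitivity 5
  ok <- vapply(seq_len(nrow(reg1)), function(i)
    any(reg2$start <= reg1$start[i] & reg1$end[i] <= reg2$end), logical(1))
  expect_true(all(ok))
  expect_gte(sum(reg2$end - reg2$start), sum(reg1$end - reg1$start))
})

test_that("self-alignment recovers planted direct and inverted copies", {
  set.seed(21)
  x <- random_genome(300)
  z <- random_genome(2000)
  g <- circular_genome("d", paste0(random_genome(500), x, z, x, random_genome(500)))
  hits <- self_align(g)
  direct <- hits[hits$strand == "+", ]
  expect_gte(nrow(direct), 1)
  i <- which.max(direct$q_end - direct$q_start)
  expect_lt(abs(direct$q_start[i] - 500), 6)
  expect_lt(abs(direct$q_end[i] - 800), 6)
  expect_lt(abs(direct$s_start[i] - 2800), 6)
  expect_lt(abs(direct$s_end[i] - 3100), 6)

  g2 <- circular_genome("i", paste0(random_genome(500), x, z, revcomp(x),
                                    random_genome(500)))
  hits2 <- self_align(g2)
  inv <- hits2[hits2$strand == "-", ]
  expect_gte(nrow(inv), 1)
  j <- which.max(inv$q_end - inv$q_start)
  expect_lt(abs(inv$q_start[j] - 500), 6)
  expect_lt(abs(inv$s_end[j] - 3100), 6)

  # a repeat-free random genome yields no hits at all
  g3 <- circular_genome("free", random_genome(5000, seed = 33))
  expect_equal(nrow(self_align(g3)), 0)
})

test_that("duplicating a repeat-free genome makes every position repeat-covered", {
  half <- random_genome(3000, seed = 13)
  g <- circular_genome("dup", paste0(half, half))
  hits <- self_align(g)
  y <- coverage_vector(hits, g$length)
  expect_true(all(y >= 1))
})

test_that("internal aligner agrees with an independent locator on planted copies", {
  # oracle route: locate the planted copies by Biostrings local alignment of
  # the copy sequence against the genome, then require the aligner's hits to
  # match those intervals with reciprocal overlap >= 0.9
  set.seed(8)
  x <- gvrepeats:::mutate_seq(random_genome(400), 0.02)
  g <- paste0(random_genome(1500), x, random_genome(1500),
              gvrepeats:::mutate_seq(x, 0.02), random_genome(600))
  hits <- self_align(circular_genome("o", g))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(g, x, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  first <- c(Biostrings::start(Biostrings::pattern(aln)) - 1,
             Biostrings::end(Biostrings::pattern(aln)))
  expected <- rbind(first, c(3400, 3800))
  best <- hits[which.max(hits$q_end - hits$q_start), ]
  for (k in 1:2) {
    ov <- min(best[[c("q_end", "s_end")[k]]], expected[k, 2]) -
      max(best[[c("q_start", "s_start")[k]]], expected[k, 1])
    expect_gte(ov / (expected[k, 2] - expected[k, 1]), 0.9)
    expect_gte(ov / (best[[c("q_end", "s_end")[k]]] -
                       best[[c("q_start", "s_start")[k]]]), 0.9)
  }
})

test_that("unit boundaries sit at smoothed-derivative maxima above the cutoff", {
  # after sliding-mean smoothing, the first-difference derivative of a step
  # of height h peaks at h/window, so the cutoff of 10 (window 20) delimits
  # steps of height >= 200; use steps of 240
  y <- integer(10000)
  y[101:200] <- 240L
  y[201:300] <- 480L
  y[301:400] <- 240L
  prof <- smooth_threshold(y, detection_params())
  reg <- data.frame(start = 80L, end = 420L)
  units <- split_units(prof, reg, detection_params())
  expect_equal(nrow(units), 3)
  expect_true(all(abs(units$start - c(100, 200, 300)) <= 10))
  expect_true(all(abs(units$end - c(200, 300, 400)) <= 10))

  # flat coverage inside the region: a single unit spanning it
  yf <- integer(5000)
  yf[1001:2000] <- 20L
  proff <- smooth_threshold(yf, detection_params())
  regf <- data.frame(start = 1200L, end = 1800L)
  unitf <- split_units(proff, regf, detection_params())
  expect_equal(nrow(unitf), 1)
  expect_equal(unitf$start, 1200)
  expect_equal(unitf$end, 1800)
})

test_that("detected units nest in their regions, ordered and disjoint", {
  # the coverage steps that delimit individual elements scale with repeat
  # copy number, so exact per-region unit counts are checked at full scale
  # in the acceptance suite; here the structural invariants are checked
  cfg <- sim_config(genome_length = 60000, n_regions = 6,
                    units_per_region_range = c(3, 3), seed = 19)
  sim <- simulate_genome(cfg)
  scan <- detect_repeats(sim$genome)
  expect_equal(nrow(scan$regions), 6)
  for (i in seq_len(nrow(scan$regions))) {
    u <- scan$units[scan$units$region_id == i, ]
    expect_gte(nrow(u), 1)
    expect_true(all(u$start >= scan$regions$start[i]))
    expect_true(all(u$end <= scan$regions$end[i]))
    if (nrow(u) > 1) expect_true(all(u$start[-1] >= u$end[-nrow(u)]))
  }
  # every detected region matches a planted region (containment one-way)
  ok <- vapply(seq_len(nrow(sim$regions)), function(i) {
    ov <- pmax(0, pmin(sim$regions$end[i], scan$regions$end) -
                 pmax(sim$regions$start[i], scan$regions$start))
    any(ov >= 0.8 * (sim$regions$end[i] - sim$regions$start[i]))
  }, logical(1))
  expect_true(all(ok))
})

test_that("detection output is byte-identical across repeated runs", {
  sim <- simulate_genome(sim_config(genome_length = 40000, n_regions = 5,
                                    seed = 23))
  s1 <- detect_repeats(sim$genome)
  s2 <- detect_repeats(sim$genome)
  f1 <- tempfile(); f2 <- tempfile()
  write_repeat_scan(s1, f1)
  write_repeat_scan(s2, f2)
  expect_identical(readLines(paste0(f1, ".regions.bed")),
                   readLines(paste0(f2, ".regions.bed")))
  expect_identical(readLines(paste0(f1, ".units.bed")),
                   readLines(paste0(f2, ".units.bed")))
})
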