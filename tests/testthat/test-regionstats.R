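# Gene/region intersection, enrichment and trend tests, NG86 dN/dS,
# masked metrics, modified-base density and placement uniformity.

test_that("gene-in-region flags agree with a brute-force interval scan", {
  genes0 <- data.frame(start = c(100L, 500L), end = c(200L, 700L))
  expect_false(any(genes_in_regions(genes0, data.frame(start = integer(),
                                                       end = integer()))$in_repeat))
  expect_true(genes_in_regions(data.frame(start = 100L, end = 200L),
                               data.frame(start = 0L, end = 1000L))$in_repeat)

  set.seed(12)
  genes <- data.frame(start = sort(sample(0:9000, 100)))
  genes$end <- genes$start + sample(50:400, 100, replace = TRUE)
  rs <- sort(sample(0:9500, 12))
  regions <- data.frame(start = rs, end = rs + sample(100:500, 12, replace = TRUE))
  got <- genes_in_regions(genes, regions)$in_repeat
  brute <- vapply(seq_len(nrow(genes)), function(i) {
    m <- (genes$start[i] + genes$end[i]) / 2
    hit <- FALSE
    for (j in seq_len(nrow(regions)))
      if (regions$start[j] <= m && m < regions$end[j]) hit <- TRUE
    hit
  }, logical(1))
  expect_identical(got, brute)
  # overlap rule differs where genes straddle region edges only
  ov <- genes_in_regions(genes, regions, rule = "overlap")$in_repeat
  expect_true(all(ov[got]))
})

test_that("2x2 chi-squared equals the closed form and a permutation null", {
  r <- enrichment_chi2(10, 100, 2, 100)
  expect_equal(r$statistic, brute_chi2_2x2(10, 90, 2, 98), tolerance = 1e-9)
  expect_equal(r$statistic, 5.674, tolerance = 2e-4)

  eq <- enrichment_chi2(10, 100, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  expect_error(enrichment_chi2(0, 10, 0, 10), "degenerate")

  # Monte-Carlo agreement where the asymptotic approximation is adequate;
  # the permutation null is discrete, so the mid-p convention (half weight
  # on the atom at the observed statistic) is the comparable quantity
  set.seed(7)
  k_in <- 40; n_in <- 200; k_out <- 24; n_out <- 240
  obs <- enrichment_chi2(k_in, n_in, k_out, n_out)
  labels <- rep(c(TRUE, FALSE), c(k_in + k_out, n_in + n_out - k_in - k_out))
  grp <- rep(c("in", "out"), c(n_in, n_out))
  perm <- replicate(10000, {
    l <- sample(labels)
    a <- sum(l[grp == "in"]); b <- sum(l[grp == "out"])
    brute_chi2_2x2(a, n_in - a, b, n_out - b)
  })
  midp <- mean(perm > obs$statistic + 1e-9) +
    0.5 * mean(abs(perm - obs$statistic) < 1e-9)
  expect_lt(abs(midp - obs$p), 0.002)
})

test_that("ancestry ranks follow HOG composition on the species tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- hog_matrix(rbind(all = c(A = 1L, B = 1L, C = 1L, D = 1L),
                        pairAB = c(1L, 1L, 0L, 0L),
                        onlyA = c(1L, 0L, 0L, 0L),
                        noA = c(0L, 1L, 1L, 1L)))
  anc <- assign_ancestry(m, tree, "A")
  expect_equal(nrow(anc), 3)  # HOGs containing A
  ranks <- setNames(anc$ancestry_rank, anc$hog_id)
  expect_equal(unname(ranks["all"]), 0)      # root: most ancient
  expect_equal(unname(ranks["pairAB"]), 1)
  expect_equal(unname(ranks["onlyA"]), 2)    # leaf: most recent
  expect_error(assign_ancestry(m, tree, "Z"), "tip")
})

test_that("Cochran-Armitage trend test matches a permutation oracle", {
  flat <- ancestry_trend(rep(c(TRUE, FALSE), 30), rep(0:2, each = 20))
  expect_lt(flat$statistic, 1e-20)
  expect_gt(flat$p, 0.99)

  set.seed(9)
  rank <- rep(0:2, each = 100)
  inrep <- c(runif(100) < 0.1, runif(100) < 0.2, runif(100) < 0.4)
  rising <- ancestry_trend(inrep, rank)
  expect_lt(rising$p, 0.01)
  expect_equal(perm_trend_p(inrep, rank, n_perm = 4000), rising$p / 2,
               tolerance = 0.015)  # one-sided permutation vs two-sided test

  expect_error(ancestry_trend(c(TRUE, FALSE), c(0, 0)), "two ancestry nodes")
})

test_that("NG86 counting estimator behaves on canonical cases", {
  same <- ng86_dnds("ATGGCTAAAGCT", "ATGGCTAAAGCT")
  expect_equal(same$dn, 0)
  expect_equal(same$ds, 0)
  expect_false(same$accepted)  # dS below the 0.1 filter

  syn <- ng86_dnds("TTT", "TTC")
  expect_equal(syn$dn, 0)
  expect_gt(syn$ds, 0)

  expect_error(ng86_dnds("ATGTAAGCT", "ATGTATGCT"), "stop codon")
  expect_error(ng86_dnds("ATGGCT", "ATG"), "equal lengths")

  # site counts: 3x sense codons partition into S + N (stops excluded)
  ff <- ng86_dnds("GGTGGA", "GGCGGG")  # Gly: 4-fold degenerate
  expect_equal(ff$S, 2)
  expect_equal(ff$dn, 0)
})

test_that("NG86 recovers simulated omega and is unbiased under neutrality", {
  omegas <- vapply(1:50, function(s) {
    p <- simulate_cds_pair(300, omega = 0.3, n_proposals = 450, seed = s)
    ng86_dnds(p$cds_a, p$cds_b)$omega
  }, numeric(1))
  expect_equal(mean(omegas), 0.3, tolerance = 0.1 / 0.3)
  expect_lt(abs(median(omegas) - 0.3), 0.1)

  # neutral simulation: dn ~ ds
  ratio <- vapply(1:60, function(s) {
    p <- simulate_cds_pair(200, omega = 1, n_proposals = 260, seed = s + 100)
    e <- ng86_dnds(p$cds_a, p$cds_b)
    e$dn / e$ds
  }, numeric(1))
  expect_equal(mean(ratio), 1, tolerance = 0.08)

  # independent reference: ape's counting dN/dS on one pair
  p <- simulate_cds_pair(300, omega = 0.3, n_proposals = 450, seed = 11)
  mine <- ng86_dnds(p$cds_a, p$cds_b)$omega
  mat <- matrix(c(strsplit(tolower(p$cds_a), "")[[1]],
                  strsplit(tolower(p$cds_b), "")[[1]]), nrow = 2, byrow = TRUE)
  ref <- as.numeric(ape::dnds(ape::as.DNAbin(mat), quiet = TRUE))
  expect_equal(mine, ref, tolerance = 0.12)
})

test_that("per-gene dN/dS means and inside/outside comparisons work", {
  pairs <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3"),
                      dn = c(0.1, 0.2, 0.3, 0.5, 0.2),
                      ds = c(0.5, 0.7, 0.6, 0.8, 0.4),
                      omega = c(0.2, 0.29, 0.5, 0.62, 0.5),
                      accepted = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  gm <- gene_dnds_means(pairs)
  expect_equal(gm$dn[gm$gene_id == "g1"], 0.15)
  expect_equal(gm$ds[gm$gene_id == "g2"], 0.6)

  set.seed(3)
  gv <- data.frame(in_repeat = rep(c(TRUE, FALSE), each = 100),
                   dn = c(rnorm(100, 0.45, 0.1), rnorm(100, 0.15, 0.05)),
                   ds = abs(rnorm(200, 0.5, 0.1)))
  gv$omega <- gv$dn / gv$ds
  res <- compare_dnds(gv)
  expect_lt(res$omega$p, 0.01)
  expect_lt(res$dn$p, 0.01)
  expect_gt(res$ds$p, 0.05)

  gv_same <- gv
  gv_same$dn <- rep(gv$dn[1:100], 2)
  gv_same$omega <- gv_same$dn / gv_same$ds
  expect_error(compare_dnds(gv[gv$in_repeat, ]), "each side")
})

test_that("masked metrics drop repeat regions and shift GC in the right direction", {
  g <- circular_genome("m", random_genome(100000, gc = 0.45, seed = 21))
  genes <- data.frame(start = seq(0, 90000, by = 10000),
                      end = seq(0, 90000, by = 10000) + 4000)
  none <- masked_metrics(g, data.frame(start = integer(), end = integer()), genes)
  expect_equal(none["real", ], none["without_repeats", ], ignore_attr = TRUE)
  expect_equal(none$length_kb[1], 100)
  expect_equal(none$coding_density[1], 0.4, tolerance = 1e-6)

  regions <- data.frame(start = c(20000L, 60000L), end = c(30000L, 70000L))
  mm <- masked_metrics(g, regions, genes)
  expect_equal(mm["without_repeats", "length_kb"], 80)

  # AT-rich repeats: masking them must raise GC
  at_seq <- strsplit(g$seq, "")[[1]]
  for (i in seq_len(nrow(regions)))
    at_seq[(regions$start[i] + 1):regions$end[i]] <-
      sample(c("A", "T"), 10000, replace = TRUE, prob = c(0.6, 0.4))
  g2 <- circular_genome("m2", paste(at_seq, collapse = ""))
  mm2 <- masked_metrics(g2, regions, genes)
  expect_gt(mm2["without_repeats", "gc_pct"], mm2["real", "gc_pct"])

  expect_error(masked_metrics(g, data.frame(start = 0L, end = 200000L), genes),
               "exceed")
})

test_that("modified-base densities and their chi-squared comparison", {
  track <- data.frame(position = 0:9999,
                      ipd_ratio = c(rep(1, 9995), rep(5, 5)))
  halves <- data.frame(name = c("a", "b"), start = c(0L, 5000L),
                       end = c(5000L, 10000L))
  res <- modified_base_density(track, halves)
  expect_equal(res$densities$per_kb, c(0, 1))
  expect_equal(sum(res$densities$modified), 5)

  one <- modified_base_density(
    data.frame(position = 0:9999, ipd_ratio = rep(c(1, 5), 5000)),
    halves)
  expect_equal(one$densities$per_kb, c(500, 500))
  expect_gt(one$test$p, 0.99)

  # Poisson tracks at the study's two rates over 300 kb halves are rarely
  # significantly different
  ps <- vapply(1:10, function(s) {
    t1 <- simulate_ipd_track("g", 300000, 0.53, seed = s)
    t2 <- simulate_ipd_track("g", 300000, 0.61, seed = s + 50)
    t2$position <- t2$position + 300000
    tr <- rbind(t1, t2)
    iv <- data.frame(name = c("conservative", "creative"),
                     start = c(0L, 300000L), end = c(300000L, 600000L))
    modified_base_density(tr, iv)$test$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)

  expect_error(modified_base_density(track, data.frame(name = "x", start = 5L,
                                                       end = 5L)), "empty")
})

test_that("KS uniformity of region placement matches the brute-force D", {
  qs <- (seq_len(20) - 0.5) / 20 * 50000
  reg_unif <- data.frame(start = qs - 50, end = qs + 50)
  r <- repeat_uniformity(reg_unif, 50000)
  expect_gt(r$p, 0.95)

  set.seed(8)
  cl_starts <- sort(runif(50, 0, 5000))
  reg_cl <- data.frame(start = cl_starts, end = cl_starts + 100)
  rc <- repeat_uniformity(reg_cl, 50000)
  expect_lt(rc$p, 0.01)
  mids <- (reg_cl$start + reg_cl$end) / 2
  expect_equal(rc$statistic, brute_ks_d(mids, 50000), tolerance = 1e-9)

  expect_error(repeat_uniformity(reg_cl[1:3, ], 50000), "at least 5")
})

test_that("core-density extremes split the genome into conservative/creative arcs", {
  starts <- seq(0, 99000, by = 1000)
  dens <- c(rep(0.9, 40), rep(0.2, 60))  # core-rich head, core-poor tail
  halves <- creative_conservative_split(starts, dens, 100000)
  cons <- halves[halves$name == "conservative", ]
  expect_true(all(c("conservative", "creative") %in% halves$name))
  # the conservative arc must contain the density maximum
  expect_true(any(cons$start <= starts[which.max(dens)] &
                    starts[which.max(dens)] < cons$end))
  # arcs tile the genome
  expect_equal(sum(halves$end - halves$start), 100000)
})
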