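# Synthetic genomes with planted repeat structure, orthologous-group
# matrices, base-modification tracks, and codon pairs under known selection.
# The generator emits the planted truth next to each dataset so detection,
# clustering and the downstream statistics can be validated end to end.

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate a pithovirus-like genome: ~600 kb, AT-rich (GC 0.36),
#' repeat-rich regions built from two palindromic MITE-like families
#' (M1: 54-nt TIRs, M2: 47-nt TIRs, both with a 37-nt internal sequence)
#' arranged as (M1-M2){n}-M1 with consecutive M1 units separated by a
#' ~140-nt sequence (measured end-to-start; the separating sequence carries
#' the M2 element when present), flanked by a "TA" target-site duplication.
#'
#' @param genome_length Genome length in nt.
#' @param gc_fraction Background GC content (0-1).
#' @param n_regions Number of planted repeat-rich regions.
#' @param units_per_region_range Integer pair: range of n in (M1-M2){n}-M1.
#' @param family_specs List of family descriptions, each a list with
#'   `label`, `tir_length` (nt), `internal_length` (nt) and
#'   `divergence_rate` (per-site substitution probability per copy).
#' @param spacer_length Median gap (nt) between the end of one M1 unit and
#'   the start of the next within a region.
#' @param tsd Target-site duplication planted immediately flanking each
#'   region on both sides.
#' @param orf_density Approximate fraction of the genome covered by
#'   simulated ORFs.
#' @param region_drift Extra per-site divergence applied once per region to
#'   each family consensus, making copies from the same region more similar
#'   to each other than to copies from other regions (0 disables).
#' @param seed Integer seed; a given seed reproduces the dataset exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 600000L, gc_fraction = 0.36,
                       n_regions = 100L, units_per_region_range = c(1L, 8L),
                       family_specs = list(
                         list(label = "M1", tir_length = 54L,
                              internal_length = 37L, divergence_rate = 0.02),
                         list(label = "M2", tir_length = 47L,
                              internal_length = 37L, divergence_rate = 0.02)),
                       spacer_length = 140L, tsd = "TA", orf_density = 0.5,
                       region_drift = 0, seed = 1L) {
  if (!length(family_specs)) stop("family_specs must be non-empty")
  stopifnot(genome_length > 0, gc_fraction >= 0, gc_fraction <= 1,
            n_regions >= 0, length(units_per_region_range) == 2,
            units_per_region_range[1] >= 1)
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_regions = as.integer(n_regions),
                 units_per_region_range = as.integer(units_per_region_range),
                 family_specs = family_specs,
                 spacer_length = as.integer(spacer_length), tsd = toupper(tsd),
                 orf_density = orf_density, region_drift = region_drift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

family_consensus <- function(spec, gc) {
  tir <- random_dna(spec$tir_length, gc)
  internal <- random_dna(spec$internal_length, gc)
  paste0(tir, internal, revcomp(tir))
}

#' Simulate a circular genome with planted repeat-rich regions
#'
#' Plants `n_regions` regions with (M1-M2){n}-M1 structure into an i.i.d.
#' background sequence, flanks each region with the TSD on both sides, and
#' lays interleaved ORFs over the genome.  The planted truth (region
#' coordinates, unit coordinates with family labels, gene table) is
#' returned alongside the sequence in BED-compatible 0-based half-open
#' coordinates.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_genome`: `genome` (a [circular_genome()]),
#'   `regions`, `units`, `genes` (data.frames), `consensus` (named vector of
#'   family consensus sequences) and `config`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  gid <- sprintf("simvir_seed%d", cfg$seed)
  consensus <- vapply(cfg$family_specs, family_consensus, "", gc = cfg$gc_fraction)
  names(consensus) <- vapply(cfg$family_specs, `[[`, "", "label")
  fam_div <- setNames(vapply(cfg$family_specs, `[[`, 0, "divergence_rate"),
                      names(consensus))
  m1 <- names(consensus)[1]
  m2 <- if (length(consensus) >= 2) names(consensus)[2] else NA_character_

  bg <- strsplit(random_dna(L, cfg$gc_fraction), "")[[1]]

  regions <- NULL; units <- NULL
  if (cfg$n_regions > 0) {
    slot <- L %/% cfg$n_regions
    nmax <- cfg$units_per_region_range[2]
    # worst-case region span; refuse densities that cannot fit
    span_max <- (nmax + 1) * max(nchar(consensus)) +
      nmax * (cfg$spacer_length + 2) + 2 * nchar(cfg$tsd) + 20
    if (span_max + 200 > slot)
      stop("cannot place ", cfg$n_regions, " regions of up to ", nmax,
           " repeat units in ", L, " nt without overlap")
    rs <- us <- ue <- rid <- integer(0); ufam <- character(0); re <- integer(0)
    for (r in seq_len(cfg$n_regions)) {
      n <- sample(seq(cfg$units_per_region_range[1],
                      cfg$units_per_region_range[2]), 1)
      reg_cons <- consensus
      if (cfg$region_drift > 0)
        reg_cons <- vapply(consensus, mutate_seq, "", rate = cfg$region_drift)
      pieces <- character(0)
      u_off <- integer(0); u_end <- integer(0); u_lab <- character(0)
      pos <- 0L
      add_unit <- function(lab) {
        s <- mutate_seq(reg_cons[[lab]], fam_div[[lab]])
        u_off <<- c(u_off, pos); u_end <<- c(u_end, pos + nchar(s))
        u_lab <<- c(u_lab, lab)
        pieces <<- c(pieces, s); pos <<- pos + nchar(s)
      }
      add_gap <- function(g) {
        if (g > 0) { pieces <<- c(pieces, random_dna(g, cfg$gc_fraction)); pos <<- pos + g }
      }
      if (!is.na(m2)) {
        for (k in seq_len(n)) {
          add_unit(m1)
          spacer <- cfg$spacer_length + sample(-1:1, 1)
          g1 <- sample(3:6, 1)
          g2 <- spacer - g1 - nchar(reg_cons[[m2]])
          if (g2 < 0) { g1 <- max(0L, g1 + g2); g2 <- 0L }
          add_gap(g1); add_unit(m2); add_gap(g2)
        }
        add_unit(m1)
      } else {
        for (k in seq_len(n)) { add_unit(m1); add_gap(cfg$spacer_length + sample(-1:1, 1)) }
        add_unit(m1)
      }
      block <- paste(pieces, collapse = "")
      start <- (r - 1L) * slot +
        sample(seq(200L, slot - nchar(block) - 200L), 1)
      # splice region + flanking TSDs into the background
      tl <- nchar(cfg$tsd)
      bseq <- strsplit(block, "")[[1]]
      bg[(start - tl + 1L):start] <- strsplit(cfg$tsd, "")[[1]]
      bg[(start + 1L):(start + nchar(block))] <- bseq
      bg[(start + nchar(block) + 1L):(start + nchar(block) + tl)] <-
        strsplit(cfg$tsd, "")[[1]]
      rs <- c(rs, start); re <- c(re, start + nchar(block))
      us <- c(us, start + u_off); ue <- c(ue, start + u_end)
      ufam <- c(ufam, u_lab); rid <- c(rid, rep.int(r, length(u_off)))
    }
    regions <- data.frame(genome_id = gid, region_id = seq_len(cfg$n_regions),
                          start = rs, end = re, stringsAsFactors = FALSE)
    units <- data.frame(genome_id = gid, region_id = rid, start = us, end = ue,
                        family = ufam, stringsAsFactors = FALSE)
  } else {
    regions <- data.frame(genome_id = character(), region_id = integer(),
                          start = integer(), end = integer())
    units <- data.frame(genome_id = character(), region_id = integer(),
                        start = integer(), end = integer(), family = character())
  }

  genes <- sim_gene_table(L, gid, cfg$orf_density, regions)
  genome <- circular_genome(gid, paste(bg, collapse = ""))
  structure(list(genome = genome, regions = regions, units = units,
                 genes = genes, consensus = consensus, config = cfg),
            class = "sim_genome")
}

# interleaved ORFs laid sequentially over the genome; midpoint-in-region
# truth flag included
sim_gene_table <- function(L, gid, density, regions) {
  if (density <= 0)
    return(data.frame(gene_id = character(), genome = character(),
                      start = integer(), end = integer(), strand = character(),
                      in_repeat = logical()))
  pos <- sample.int(1000L, 1); starts <- integer(0); ends <- integer(0)
  while (pos < L - 2000L) {
    len <- 3L * sample(100:500, 1)
    gap <- max(30L, round(len * (1 - density) / max(density, 1e-6)))
    if (pos + len >= L) break
    starts <- c(starts, pos); ends <- c(ends, pos + len)
    pos <- pos + len + sample.int(2L * gap, 1)
  }
  mid <- (starts + ends) / 2
  inr <- vapply(mid, function(m)
    any(regions$start <= m & m < regions$end), logical(1))
  data.frame(gene_id = sprintf("%s_g%04d", gid, seq_along(starts)),
             genome = gid, start = starts, end = ends,
             strand = sample(c("+", "-"), length(starts), replace = TRUE),
             in_repeat = inr, stringsAsFactors = FALSE)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d nt, %d planted regions, %d units, %d genes\n",
              x$genome$id, x$genome$length, nrow(x$regions), nrow(x$units),
              nrow(x$genes)))
  invisible(x)
}

#' Simulate a HOG gene-count matrix
#'
#' Builds a hierarchical-orthologous-group count matrix (HOGs x genomes)
#' with tunable core/accessory/novel/duplication structure:
#' every genome carries all `core_size` core HOGs; each of the
#' `accessory_pool` shared accessory HOGs is present in each genome
#' independently (presence probability drawn per HOG from a Beta
#' distribution, see below); each genome additionally carries
#' `new_per_genome` HOGs never seen in any other genome; finally a
#' `dup_rate` fraction of each genome's gene slots are extra copies within
#' already-present HOGs.
#'
#' Accessory presence probabilities are drawn from
#' `Beta(accessory_shape[1], accessory_shape[2])`.  The expected number of
#' previously unseen accessory HOGs contributed by the k-th genome then
#' decays as `B(a+1, b+k-1)/B(a,b)`, asymptotically a power law in k with
#' exponent `a+1`, which makes the openness (Heaps' law) behaviour of the
#' matrix tunable; see [heaps_expected_new()] for the closed form.
#'
#' @param n_genomes Number of genomes.
#' @param core_size HOGs present in every genome.
#' @param accessory_pool Size of the shared accessory HOG pool.
#' @param new_per_genome Genome-specific novel HOGs per genome.
#' @param dup_rate Target fraction of gene slots that are duplicate copies.
#' @param seed Integer seed.
#' @param accessory_shape Beta shape pair for accessory presence
#'   probabilities.
#' @return A [hog_matrix()].
#' @export
simulate_hog_matrix <- function(n_genomes, core_size, accessory_pool = 0,
                                new_per_genome = 0, dup_rate = 0, seed = 1L,
                                accessory_shape = c(1, 1)) {
  stopifnot(n_genomes >= 1, core_size >= 0, accessory_pool >= 0,
            new_per_genome >= 0, dup_rate >= 0, dup_rate < 1)
  set.seed(seed)
  genomes <- sprintf("genome%02d", seq_len(n_genomes))
  blocks <- list()
  if (core_size > 0)
    blocks$core <- matrix(1L, core_size, n_genomes,
                          dimnames = list(sprintf("core%04d", seq_len(core_size)), genomes))
  if (accessory_pool > 0) {
    p <- stats::rbeta(accessory_pool, accessory_shape[1], accessory_shape[2])
    acc <- matrix(rbinom(accessory_pool * n_genomes, 1L, rep(p, n_genomes)),
                  accessory_pool, n_genomes,
                  dimnames = list(sprintf("acc%04d", seq_len(accessory_pool)), genomes))
    acc <- acc[rowSums(acc) > 0, , drop = FALSE]
    blocks$acc <- acc
  }
  if (new_per_genome > 0) {
    nov <- matrix(0L, new_per_genome * n_genomes, n_genomes,
                  dimnames = list(sprintf("new%04d", seq_len(new_per_genome * n_genomes)),
                                  genomes))
    for (g in seq_len(n_genomes))
      nov[(g - 1L) * new_per_genome + seq_len(new_per_genome), g] <- 1L
    blocks$new <- nov
  }
  counts <- do.call(rbind, blocks)
  if (is.null(counts)) stop("matrix would be empty")
  if (dup_rate > 0) {
    for (g in seq_len(n_genomes)) {
      present <- which(counts[, g] >= 1L)
      n <- sum(counts[, g])
      d <- round(dup_rate * n / (1 - dup_rate))
      if (d > 0) {
        extra <- table(sample(present, d, replace = TRUE))
        counts[as.integer(names(extra)), g] <-
          counts[as.integer(names(extra)), g] + as.integer(extra)
      }
    }
  }
  hog_matrix(counts)
}

#' Simulate a per-position IPD-ratio track
#'
#' Baseline interpulse-duration ratios are drawn from a gamma distribution
#' centred at 1; putatively modified positions are planted as a Poisson
#' process at `modified_per_kb` and given IPD ratios above the detection
#' threshold.
#'
#' @param genome_id Genome identifier.
#' @param length Track length (nt).
#' @param modified_per_kb Expected planted modified positions per kb.
#' @param threshold IPD ratio above which a position counts as modified.
#' @param seed Integer seed.
#' @return data.frame: genome_id, position (0-based), ipd_ratio.
#' @export
simulate_ipd_track <- function(genome_id, length, modified_per_kb = 0.5,
                               threshold = 4.5, seed = 1L) {
  set.seed(seed)
  ipd <- stats::rgamma(length, shape = 8, rate = 8)  # baseline ~1, sd ~0.35
  ipd[ipd > threshold] <- threshold * 0.99           # baseline never crosses
  n_mod <- rpois(1, modified_per_kb * length / 1000)
  if (n_mod > 0) {
    at <- sample.int(length, min(n_mod, length))
    ipd[at] <- threshold + stats::rexp(base::length(at), 1 / 2)
  }
  data.frame(genome_id = genome_id, position = seq_len(length) - 1L,
             ipd_ratio = ipd, stringsAsFactors = FALSE)
}

#' Simulate an aligned CDS pair under known selection pressure
#'
#' Evolves a random coding sequence by proposing random single-nucleotide
#' substitutions: synonymous proposals are always accepted, nonsynonymous
#' ones with probability `omega`, and proposals creating stop codons are
#' rejected.  The resulting pair is gap-free, frame-preserving and free of
#' internal stops, with a true dN/dS of `omega`.
#'
#' @param n_codons Number of codons.
#' @param omega True dN/dS (acceptance probability of nonsynonymous
#'   proposals).
#' @param n_proposals Number of substitution proposals (controls total
#'   divergence; default scales with length).
#' @param seed Integer seed.
#' @return list(cds_a, cds_b, omega).
#' @export
simulate_cds_pair <- function(n_codons, omega, n_proposals = n_codons, seed = 1L) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  sense <- setdiff(names(code), stops)
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  bases <- c("A", "C", "G", "T")
  done <- 0L
  while (done < n_proposals) {
    i <- sample.int(n_codons, 1); p <- sample.int(3L, 1)
    cod <- b[i]
    old <- substr(cod, p, p)
    new <- sample(setdiff(bases, old), 1)
    cand <- cod
    substr(cand, p, p) <- new
    done <- done + 1L
    if (cand %in% stops) next
    syn <- code[[cand]] == code[[cod]]
    if (syn || runif(1) < omega) b[i] <- cand
  }
  list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
       omega = omega)
}
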