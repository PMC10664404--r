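# Independent oracles and small fixture builders used across the suite.

random_genome <- function(n, gc = 0.36, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force circular centred sliding mean (even windows put the extra
# weight forward, matching the convolution filter convention)
brute_circular_mean <- function(x, w) {
  n <- length(x)
  hi <- w %/% 2
  lo <- -(w - 1 - hi)
  vapply(seq_len(n), function(i) {
    idx <- ((i + lo):(i + hi) - 1) %% n + 1
    mean(x[idx])
  }, numeric(1))
}

# reference global alignment identity via Biostrings (independent of the
# package's own aligner), needle scoring, identity over all columns
oracle_global_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 0.5)
  # columns incl. end gaps = len_a + len_b - aligned residue pairs
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  cols <- nchar(a) + nchar(b) - pairs
  100 * Biostrings::nmatch(aln) / cols
}

# greedy clustering applied under an arbitrary processing order; returns the
# partition as a canonical list of sorted member index vectors
greedy_partition_for_order <- function(idmat, ord, threshold = 70) {
  refs <- integer(0)
  assign <- integer(nrow(idmat))
  for (i in ord) {
    hit <- if (length(refs)) which(idmat[i, refs] >= threshold)[1] else NA
    if (is.na(hit)) {
      refs <- c(refs, i)
      assign[i] <- length(refs)
    } else assign[i] <- hit
  }
  unname(lapply(split(seq_len(nrow(idmat)), assign), sort))
}

canonical_partition <- function(assign) {
  unname(lapply(split(seq_along(assign), assign), sort))
}

same_partition <- function(p1, p2) {
  setequal(lapply(p1, paste, collapse = ","), lapply(p2, paste, collapse = ","))
}

# brute-force one-sample KS D statistic against Uniform(0, L)
brute_ks_d <- function(x, L) {
  x <- sort(x) / L
  n <- length(x)
  max(pmax(abs(seq_len(n) / n - x), abs(x - (seq_len(n) - 1) / n)))
}

# closed-form 2x2 Pearson chi-squared
brute_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# permutation null for the Cochran-Armitage trend statistic: shuffle the
# in/out labels across genes keeping node sizes fixed
perm_trend_p <- function(in_repeat, rank, n_perm = 2000, seed = 1) {
  obs <- ancestry_trend(in_repeat, rank)$statistic
  set.seed(seed)
  perm <- replicate(n_perm, {
    ancestry_trend(sample(in_repeat), rank)$statistic
  })
  mean(perm >= obs - 1e-12)
}

# planted two-family unit set with tunable divergence
make_two_families <- function(n_per = 10, len = 120, div = 0.02, seed = 1) {
  set.seed(seed)
  f1 <- random_genome(len)
  f2 <- random_genome(len)
  seqs <- c(vapply(seq_len(n_per), function(i) gvrepeats:::mutate_seq(f1, div), ""),
            vapply(seq_len(n_per), function(i) gvrepeats:::mutate_seq(f2, div), ""))
  data.frame(seq = seqs, start = seq_along(seqs) * 200,
             family = rep(c("A", "B"), each = n_per),
             stringsAsFactors = FALSE)
}
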