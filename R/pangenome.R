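# Pan/core-genome rarefaction, Heaps'-law openness, duplication fractions,
# sliding-window core-gene density, RSCU and AAI.

#' HOG gene-count matrix
#'
#' Container for a hierarchical-orthologous-group count matrix with HOGs as
#' rows and genomes as columns; presence is count >= 1.  All-zero rows are
#' rejected.
#'
#' @param counts Nonnegative integer matrix (HOGs x genomes) with
#'   dimnames.
#' @return Matrix of class `hog_matrix`.
#' @export
hog_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("HOG counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("HOG%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("genome%02d", seq_len(ncol(counts)))
  if (any(rowSums(counts) == 0)) stop("all-zero HOG rows are not allowed")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("hog_matrix", "matrix", "array"))
}

#' @export
print.hog_matrix <- function(x, ...) {
  cat(sprintf("<hog_matrix> %d HOGs x %d genomes, %d genes\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

all_orderings <- function(g) {
  if (g == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(g - 1L)
  do.call(rbind, lapply(seq_len(g), function(k)
    cbind(k, sub + (sub >= k))))
}

sample_orderings <- function(g, n) {
  t(vapply(seq_len(n), function(i) sample.int(g), integer(g)))
}

#' Pan/core-genome rarefaction curves
#'
#' Genomes are added iteratively in every possible order (or a seeded
#' uniform subsample of `max_combinations` orders when the factorial
#' exceeds it).  At each step n the core genome is the set of HOGs present
#' in all n genomes, the pan genome those present in at least one, and the
#' new HOGs those absent from the first n - 1.  Presence/absence is used,
#' not gene counts.
#'
#' @param m A [hog_matrix()].
#' @param max_combinations Cap on the number of genome orderings.
#' @param seed Seed for the ordering subsample.
#' @param normalize Report curves relative to the mean single-genome size
#'   (curves then start at 1)?
#' @return data.frame of class `pan_curve`: n, core_mean, core_sd,
#'   pan_mean, pan_sd, new_mean, new_sd; attribute `n_orderings`.
#' @export
pan_core_rarefaction <- function(m, max_combinations = 5000, seed = 1L,
                                 normalize = FALSE) {
  stopifnot(inherits(m, "hog_matrix"))
  g <- ncol(m)
  if (g < 2) stop("at least 2 genomes are required")
  pres <- m >= 1L
  if (factorial(g) <= max_combinations) {
    ords <- all_orderings(g)
  } else {
    set.seed(seed)
    ords <- sample_orderings(g, max_combinations)
  }
  core <- pan <- newh <- matrix(0, nrow(ords), g)
  for (r in seq_len(nrow(ords))) {
    o <- ords[r, ]
    cpn <- pan_core_one_ordering(pres, o)
    core[r, ] <- cpn$core; pan[r, ] <- cpn$pan; newh[r, ] <- cpn$new
  }
  scale <- if (normalize) mean(colSums(pres)) else 1
  out <- data.frame(
    n = seq_len(g),
    core_mean = colMeans(core) / scale, core_sd = apply(core, 2, sd) / scale,
    pan_mean = colMeans(pan) / scale, pan_sd = apply(pan, 2, sd) / scale,
    new_mean = colMeans(newh) / scale, new_sd = apply(newh, 2, sd) / scale)
  attr(out, "n_orderings") <- nrow(ords)
  attr(out, "normalized") <- normalize
  attr(out, "per_ordering") <- list(core = core, pan = pan, new = newh)
  class(out) <- c("pan_curve", "data.frame")
  out
}

# core/pan/new along one genome ordering, via each HOG's first occurrence
# (and, for the core, first absence) position in the ordering
pan_core_one_ordering <- function(pres, o) {
  g <- length(o)
  A <- pres[, o, drop = FALSE]
  first_in <- max.col(A + 0L, ties.method = "first")
  first_in[rowSums(A) == 0] <- g + 1L  # cannot happen for hog_matrix; safety
  newc <- tabulate(first_in, g)
  pan <- cumsum(newc)
  # a HOG is core at step n iff present in all of the first n genomes,
  # i.e. its first absence comes after position n
  first_out <- max.col(1L - A, ties.method = "first")
  always <- rowSums(A) == g
  core <- vapply(seq_len(g), function(n) sum(always | first_out > n), numeric(1))
  list(core = core, pan = pan, new = newc)
}

#' @export
plot.pan_curve <- function(x, ...) {
  ylim <- c(0, max(x$pan_mean + x$pan_sd))
  plot(x$n, x$pan_mean, type = "b", pch = 19, col = "steelblue4",
       ylim = ylim, xlab = "genomes", ylab = if (attr(x, "normalized"))
         "relative HOGs" else "HOGs", ...)
  arrows2 <- function(y, s, col) suppressWarnings(
    graphics::arrows(x$n, y - s, x$n, y + s, angle = 90, code = 3,
                     length = 0.03, col = col))
  arrows2(x$pan_mean, x$pan_sd, "steelblue4")
  lines(x$n, x$core_mean, type = "b", pch = 19, col = "firebrick")
  arrows2(x$core_mean, x$core_sd, "firebrick")
  lines(x$n, x$new_mean, type = "b", pch = 1, col = "grey40")
  legend("topleft", bty = "n", col = c("steelblue4", "firebrick", "grey40"),
         pch = c(19, 19, 1), legend = c("pan", "core", "new"))
  invisible(x)
}

#' Heaps'-law openness of a pan-genome
#'
#' For `n_perm` random genome orderings, records the number of new HOGs
#' contributed at each step, averages the counts over the permutations,
#' and fits E\[new at step n\] = kappa * n^(-alpha) by least squares on the
#' log-log scale, excluding n = 1.  The pan-genome is called open when
#' alpha < 1 and closed otherwise.  When no new HOGs ever arrive past the
#' first genome, alpha is reported as `Inf` (closed).
#'
#' @param m A [hog_matrix()].
#' @param n_perm Number of random orderings (default 1000).
#' @param seed Integer seed.
#' @return List of class `heaps_fit`: kappa, alpha, n_perm, open,
#'   mean_new (the permutation-averaged counts by step).
#' @export
heaps_alpha <- function(m, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(m, "hog_matrix"))
  g <- ncol(m)
  if (g < 3) stop("at least 3 genomes are required")
  pres <- m >= 1L
  set.seed(seed)
  newh <- matrix(0, n_perm, g)
  for (r in seq_len(n_perm)) {
    A <- pres[, sample.int(g), drop = FALSE]
    newh[r, ] <- tabulate(max.col(A + 0L, ties.method = "first"), g)
  }
  mean_new <- colMeans(newh)
  steps <- 2:g
  keep <- mean_new[steps] > 0
  if (sum(keep) < 2) {
    fit <- list(kappa = NA_real_, alpha = Inf)
  } else {
    ll <- lm(log(mean_new[steps][keep]) ~ log(steps[keep]))
    fit <- list(kappa = exp(unname(coef(ll)[1])), alpha = -unname(coef(ll)[2]))
  }
  structure(list(kappa = fit$kappa, alpha = fit$alpha, n_perm = n_perm,
                 open = is.finite(fit$alpha) && fit$alpha < 1,
                 mean_new = mean_new),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("<heaps_fit> alpha = %.3g (kappa = %.3g, %d permutations): %s pan-genome\n",
              x$alpha, x$kappa, x$n_perm, if (x$open) "open" else "closed"))
  invisible(x)
}

#' Expected new-HOG curve of the simulated matrix (closed form)
#'
#' For a matrix from [simulate_hog_matrix()], the expected number of
#' previously unseen HOGs contributed by the genome added at step k of a
#' random ordering: `new_per_genome` genome-specific HOGs plus
#' `accessory_pool * B(a+1, b+k-1) / B(a,b)` accessory HOGs (presence
#' probabilities Beta(a,b)); the core only counts at k = 1.  Serves as an
#' independent oracle for [heaps_alpha()].
#'
#' @param k Step (vector allowed).
#' @param core_size,accessory_pool,new_per_genome,accessory_shape As in
#'   [simulate_hog_matrix()].
#' @return Expected new-HOG counts at each step.
#' @export
heaps_expected_new <- function(k, core_size, accessory_pool = 0,
                               new_per_genome = 0, accessory_shape = c(1, 1)) {
  a <- accessory_shape[1]; b <- accessory_shape[2]
  acc <- if (accessory_pool > 0)
    accessory_pool * exp(lbeta(a + 1, b + k - 1) - lbeta(a, b))
  else 0
  new_per_genome + acc + ifelse(k == 1, core_size, 0)
}

#' Duplication fraction of a genome
#'
#' Percentage of a genome's genes that arose from duplication.  The
#' default counts, in each HOG, the copies in excess of one
#' (`mode = "excess"`); `mode = "all"` instead counts every member of a
#' multi-copy HOG.
#'
#' @param m A [hog_matrix()].
#' @param genome Genome id (column name) or index; all genomes when NULL.
#' @param mode Counting mode, see above.
#' @return Named numeric vector of percentages.
#' @export
duplication_fraction <- function(m, genome = NULL, mode = c("excess", "all")) {
  stopifnot(inherits(m, "hog_matrix"))
  mode <- match.arg(mode)
  if (is.null(genome)) genome <- colnames(m)
  if (is.character(genome) && !all(genome %in% colnames(m)))
    stop("unknown genome: ", paste(setdiff(genome, colnames(m)), collapse = ", "))
  vapply(genome, function(g) {
    cnt <- m[, g]
    total <- sum(cnt)
    dup <- if (mode == "excess") sum(pmax(cnt - 1L, 0L)) else sum(cnt[cnt >= 2L])
    100 * dup / total
  }, numeric(1))
}

#' Sliding-window core-gene density / copy number along a genome
#'
#' For each gene on the circularly ordered genome, the fraction of core
#' genes (`mode = "core"`, on a logical vector) or the mean HOG copy
#' number (`mode = "copies"`, on a numeric vector) within the centred
#' window of `window` genes.  The window wraps around the linearization
#' origin.
#'
#' @param x Per-gene values in genome order: logical core flags or numeric
#'   HOG copy numbers.
#' @param window Window size in genes (odd; default 21).
#' @param mode See above.
#' @return Numeric vector, one value per gene.
#' @export
core_density_window <- function(x, window = 21L, mode = c("core", "copies")) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < window) {
    window <- max(3L, if (n %% 2L == 0L) n - 1L else n)
    warning("fewer genes than window; window shrunk to ", window)
  }
  if (window %% 2L == 0L) stop("window must be odd")
  vals <- if (mode == "core") as.numeric(x) else as.numeric(x)
  circular_mean(vals, window)
}

#' Relative synonymous codon usage
#'
#' Counts all codons of the supplied coding sequences at once and applies
#' RSCU(c) = count(c) * n_syn(aa) / count(aa).  Stop codons and the
#' single-codon families (Met, Trp) are excluded, leaving the 59 codons of
#' the synonymous families.  Families absent from the input yield `NA`.
#'
#' @param cds Character vector (or DNAStringSet) of CDS; every length must
#'   be a multiple of 3 (standard genetic code, frame 1).
#' @return Named numeric vector of class `rscu` over the 59 codons, with
#'   attribute `aa` naming each codon's amino acid.
#' @export
rscu <- function(cds) {
  cds <- toupper(as.character(cds))
  bad <- which(nchar(cds) %% 3L != 0L)
  if (length(bad))
    stop("CDS length not a multiple of 3 at sequence ",
         paste(bad, collapse = ", "))
  code <- Biostrings::GENETIC_CODE
  fam <- table(code)
  keep <- names(code)[!(code[names(code)] %in% c("*")) &
                        fam[code[names(code)]] > 1]
  codons <- unlist(lapply(cds, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  counts <- table(factor(codons, levels = names(code)))
  out <- setNames(rep(NA_real_, length(keep)), keep)
  for (cdn in keep) {
    aa <- code[[cdn]]
    syn <- names(code)[code == aa]
    aa_count <- sum(counts[syn])
    if (aa_count > 0)
      out[cdn] <- as.numeric(counts[cdn]) * length(syn) / aa_count
  }
  structure(out, aa = setNames(unname(code[keep]), keep), class = "rscu")
}

#' @export
print.rscu <- function(x, ...) {
  cat("<rscu> 59 synonymous-family codons; family means = 1 where defined\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Average amino-acid identity between two proteomes
#'
#' Reciprocal best-hit protein pairs are found by local (Smith-Waterman)
#' alignment with BLOSUM62; pairs are kept when their identity is at least
#' `min_identity` percent and the aligned region covers at least
#' `min_frac` of the shorter protein.  The AAI is the mean identity of the
#' kept pairs, averaged over both directions.
#'
#' @param proteome_a,proteome_b Named character vectors (or AAStringSets)
#'   of protein sequences.
#' @param min_identity Minimum identity percent (default 15).
#' @param min_frac Minimum aligned fraction of the shorter protein
#'   (default 0.4).
#' @return List of class `aai_result`: aai_pct, n_pairs, pairs
#'   (data.frame).  `aai_pct` is `NA` when no pair qualifies.
#' @export
aai <- function(proteome_a, proteome_b, min_identity = 15, min_frac = 0.4) {
  a <- Biostrings::AAStringSet(proteome_a)
  b <- Biostrings::AAStringSet(proteome_b)
  if (!length(a) || !length(b)) stop("both proteomes must be non-empty")
  if (is.null(names(a))) names(a) <- sprintf("a%03d", seq_along(a))
  if (is.null(names(b))) names(b) <- sprintf("b%03d", seq_along(b))
  score <- ident <- frac <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) {
    aln <- Biostrings::pairwiseAlignment(
      b, a[[i]], type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    score[i, ] <- Biostrings::score(aln)
    cols <- Biostrings::nchar(aln)
    ident[i, ] <- 100 * Biostrings::nmatch(aln) / cols
    frac[i, ] <- cols / pmin(Biostrings::width(a)[i], Biostrings::width(b))
  }
  best_ab <- apply(score, 1, which.max)
  best_ba <- apply(score, 2, which.max)
  rbh <- which(best_ba[best_ab] == seq_along(a))
  pairs <- data.frame(protein_a = names(a)[rbh],
                      protein_b = names(b)[best_ab[rbh]],
                      identity_pct = ident[cbind(rbh, best_ab[rbh])],
                      aligned_frac = frac[cbind(rbh, best_ab[rbh])])
  pairs <- pairs[pairs$identity_pct >= min_identity &
                   pairs$aligned_frac >= min_frac, , drop = FALSE]
  structure(list(aai_pct = if (nrow(pairs)) mean(pairs$identity_pct) else NA_real_,
                 n_pairs = nrow(pairs), pairs = pairs,
                 min_identity = min_identity, min_frac = min_frac),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  cat(sprintf("<aai_result> AAI = %.2f%% over %d reciprocal best-hit pairs\n",
              x$aai_pct, x$n_pairs))
  invisible(x)
}
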