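# Statistics on genes inside vs outside repeat-rich regions and on genome
# intervals: intersection, enrichment, ancestry trend, dN/dS comparisons,
# masked-genome metrics, modified-base density, placement uniformity.

#' Flag genes inside repeat-rich regions
#'
#' A gene is inside a region when its midpoint falls in the region
#' (default; avoids double counting at boundaries) or, under
#' `rule = "overlap"`, when it overlaps a region by at least one bp
#' (bedtools-intersect style).
#'
#' @param genes Gene table with `start`, `end` (0-based half-open) and
#'   optionally `genome`.
#' @param regions Region table with `start`, `end` and optionally
#'   `genome_id`.
#' @param rule Containment rule.
#' @return `genes` with a logical `in_repeat` column; attribute `counts`
#'   holds the inside/outside totals.
#' @export
genes_in_regions <- function(genes, regions, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  if (!is.null(genes$genome) && !is.null(regions$genome_id) &&
      nrow(genes) && nrow(regions) &&
      !any(unique(genes$genome) %in% unique(regions$genome_id)))
    stop("gene and region tables refer to different genomes")
  if (!nrow(regions)) {
    genes$in_repeat <- rep(FALSE, nrow(genes))
  } else if (rule == "midpoint") {
    mid <- (genes$start + genes$end) / 2
    genes$in_repeat <- vapply(mid, function(m)
      any(regions$start <= m & m < regions$end), logical(1))
  } else {
    genes$in_repeat <- vapply(seq_len(nrow(genes)), function(i)
      any(pmin(genes$end[i], regions$end) - pmax(genes$start[i], regions$start) > 0),
      logical(1))
  }
  attr(genes, "counts") <- c(inside = sum(genes$in_repeat),
                             outside = sum(!genes$in_repeat))
  genes
}

#' Chi-squared enrichment test on a 2x2 table
#'
#' Pearson chi-squared without continuity correction (the study's tooling
#' default) on counts of a property inside vs outside repeat regions.
#'
#' @param k_in,n_in Successes and totals inside.
#' @param k_out,n_out Successes and totals outside.
#' @param correct Apply the Yates continuity correction?
#' @return List of class `contingency_result`: test, table, statistic, p.
#' @export
enrichment_chi2 <- function(k_in, n_in, k_out, n_out, correct = FALSE) {
  if (n_in <= 0 || n_out <= 0) stop("totals must be positive")
  tab <- rbind(inside = c(k_in, n_in - k_in),
               outside = c(k_out, n_out - k_out))
  colnames(tab) <- c("yes", "no")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  contingency_result("chi2", tab, unname(ct$statistic), ct$p.value)
}

contingency_result <- function(test, tab, statistic, p) {
  structure(list(test = test, table = tab, statistic = statistic, p = p),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<%s test> statistic = %.4g, p = %.3g\n", x$test, x$statistic, x$p))
  invisible(x)
}

#' Assign gene ancestry nodes from HOG composition
#'
#' The ancestry of a gene is the last common ancestor of the species
#' present in its HOG: a HOG spanning all leaves maps to the root, a
#' genome-specific HOG to the genome's leaf.  Nodes are ranked along the
#' root-to-leaf path of the focal genome, 0 = most ancient.
#'
#' @param m A [hog_matrix()] (or presence matrix) whose columns are tree
#'   tip labels.
#' @param tree Rooted `phylo` species tree.
#' @param genome Focal genome (must be a tree tip).
#' @return data.frame: hog_id, ancestry_node (node number), ancestry_rank;
#'   one row per HOG present in `genome`.
#' @export
assign_ancestry <- function(m, tree, genome) {
  if (!genome %in% tree$tip.label) stop("genome is not a tip of the tree")
  if (!all(colnames(m) %in% tree$tip.label))
    stop("HOG matrix genomes missing from the tree: ",
         paste(setdiff(colnames(m), tree$tip.label), collapse = ", "))
  tip <- match(genome, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  path <- ape::nodepath(tree, root, tip)  # root ... leaf
  pres <- m >= 1L
  hogs <- rownames(m)[pres[, genome]]
  node <- vapply(hogs, function(h) {
    leaves <- colnames(m)[pres[h, ]]
    if (length(leaves) == 1L) match(leaves, tree$tip.label)
    else ape::getMRCA(tree, leaves)
  }, integer(1))
  rank <- match(node, path) - 1L
  if (anyNA(rank))
    stop("ancestry node off the focal root-to-leaf path for HOG ",
         paste(hogs[is.na(rank)][1]))
  data.frame(hog_id = hogs, ancestry_node = node, ancestry_rank = rank,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cochran-Armitage trend of repeat-region membership across gene ancestry
#'
#' Counts, for each ancestry node ordered most ancient to most recent,
#' the genes inside vs outside repeat-rich regions and applies the
#' Cochran-Armitage trend test with integer scores 0..k-1.
#'
#' @param in_repeat Logical vector, one per gene.
#' @param ancestry_rank Integer node ranks, 0 = most ancient.
#' @return `contingency_result` (test `cochran_armitage`, two-sided p);
#'   the table holds inside/outside counts per node.
#' @export
ancestry_trend <- function(in_repeat, ancestry_rank) {
  stopifnot(length(in_repeat) == length(ancestry_rank))
  lev <- sort(unique(ancestry_rank))
  if (length(lev) < 2) stop("need at least two ancestry nodes")
  k_in <- vapply(lev, function(l) sum(in_repeat[ancestry_rank == l]), 0)
  n <- vapply(lev, function(l) sum(ancestry_rank == l), 0)
  tt <- suppressWarnings(prop.trend.test(k_in, n, score = lev))
  tab <- rbind(inside = k_in, outside = n - k_in)
  colnames(tab) <- paste0("node", lev)
  contingency_result("cochran_armitage", tab, unname(tt$statistic), tt$p.value)
}

#' Wilcoxon comparison of dN/dS metrics inside vs outside repeat regions
#'
#' Two-sided rank-sum tests on each of dN, dS and dN/dS, computed
#' independently, between genes inside and outside repeat-rich regions.
#'
#' @param gene_values data.frame with columns `in_repeat`, `dn`, `ds`,
#'   `omega` (per-gene means over accepted ortholog pairs).
#' @return Named list of `contingency_result`s (`dn`, `ds`, `omega`).
#' @export
compare_dnds <- function(gene_values) {
  out <- list()
  for (metric in c("dn", "ds", "omega")) {
    x <- gene_values[[metric]][gene_values$in_repeat]
    y <- gene_values[[metric]][!gene_values$in_repeat]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      stop("need at least 2 accepted estimates on each side for ", metric)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    tab <- rbind(inside = c(n = length(x), median = median(x)),
                 outside = c(n = length(y), median = median(y)))
    out[[metric]] <- contingency_result("wilcoxon", tab,
                                        unname(wt$statistic), wt$p.value)
  }
  out
}

#' Genome metrics with and without repeat-rich regions
#'
#' Length, GC content and coding density of the full genome and of its
#' repeat-masked complement.
#'
#' @param genome A [circular_genome()].
#' @param regions Repeat-region table (`start`, `end`).
#' @param genes Gene table (`start`, `end`).
#' @return data.frame with rows `real` and `without_repeats`:
#'   length_kb, gc_pct, coding_density.
#' @export
masked_metrics <- function(genome, regions, genes) {
  L <- genome$length
  if (nrow(regions) && any(regions$start < 0 | regions$end > L))
    stop("regions exceed the genome")
  b <- strsplit(genome$seq, "")[[1]]
  inrep <- logical(L)
  for (i in seq_len(nrow(regions)))
    inrep[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  coding <- logical(L)
  for (i in seq_len(nrow(genes))) {
    s <- max(0L, genes$start[i]); e <- min(L, genes$end[i])
    if (e > s) coding[(s + 1L):e] <- TRUE
  }
  metrics <- function(keep) {
    bb <- b[keep]
    c(length_kb = sum(keep) / 1000,
      gc_pct = 100 * sum(bb %in% c("G", "C")) / sum(bb %in% c("A", "C", "G", "T")),
      coding_density = mean(coding[keep]))
  }
  out <- rbind(real = metrics(rep(TRUE, L)), without_repeats = metrics(!inrep))
  as.data.frame(out)
}

#' Modified-base density comparison between genome intervals
#'
#' Counts positions with IPD ratio above `threshold` in each interval,
#' reports per-kb densities, and tests the counts (modified vs unmodified
#' positions) with a chi-squared test.
#'
#' @param track IPD track data.frame (`position`, `ipd_ratio`).
#' @param intervals data.frame with `name`, `start`, `end` (0-based
#'   half-open); typically the "conservative" and "creative" halves.
#' @param threshold IPD ratio above which a position is called modified
#'   (default 4.5).
#' @return List: per-interval data.frame (name, length_kb, modified,
#'   per_kb) and `test` (`contingency_result`).
#' @export
modified_base_density <- function(track, intervals, threshold = 4.5) {
  if (any(intervals$end <= intervals$start)) stop("empty interval")
  stats_df <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
    sel <- track$position >= intervals$start[i] & track$position < intervals$end[i]
    len <- intervals$end[i] - intervals$start[i]
    mod <- sum(track$ipd_ratio[sel] > threshold)
    data.frame(name = intervals$name[i], length_kb = len / 1000,
               modified = mod, per_kb = mod / (len / 1000))
  }))
  tab <- rbind(modified = stats_df$modified,
               unmodified = stats_df$length_kb * 1000 - stats_df$modified)
  colnames(tab) <- stats_df$name
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(densities = stats_df,
       test = contingency_result("chi2", tab, unname(ct$statistic), ct$p.value))
}

#' Kolmogorov-Smirnov test of repeat-region placement uniformity
#'
#' One-sample KS test of region midpoints against Uniform(0, L).
#'
#' @param regions Region table (`start`, `end`).
#' @param genome_length Genome length L.
#' @return `contingency_result` (test `ks`; statistic is D).
#' @export
repeat_uniformity <- function(regions, genome_length) {
  if (nrow(regions) < 5) stop("need at least 5 regions")
  mids <- (regions$start + regions$end) / 2
  kt <- suppressWarnings(ks.test(mids, "punif", 0, genome_length))
  tab <- rbind(midpoints = c(n = length(mids)))
  contingency_result("ks", tab, unname(kt$statistic), kt$p.value)
}

#' Split a circular genome into core-rich and core-poor halves
#'
#' Uses the sliding-window core-gene density ([core_density_window()]):
#' the genome is cut at the positions of the density maximum and minimum,
#' and the arc with the higher mean density is called "conservative", the
#' other "creative".
#'
#' @param gene_starts Gene start coordinates in genome order.
#' @param density Per-gene core density (same order).
#' @param genome_length Genome length L.
#' @return data.frame: name, start, end (the creative half may wrap; it is
#'   then reported split in two rows sharing the name).
#' @export
creative_conservative_split <- function(gene_starts, density, genome_length) {
  i_max <- which.max(density); i_min <- which.min(density)
  c1 <- gene_starts[min(i_max, i_min)]
  c2 <- gene_starts[max(i_max, i_min)]
  arcs <- list(inner = c(c1, c2), outer = c(c2, genome_length, 0, c1))
  mean_arc <- function(lohi) {
    sel <- gene_starts >= lohi[1] & gene_starts < lohi[2]
    if (length(lohi) == 4) sel <- sel | (gene_starts >= lohi[3] & gene_starts < lohi[4])
    mean(density[sel])
  }
  inner_cons <- mean_arc(arcs$inner) >= mean_arc(c(c2, genome_length, 0, c1))
  inner <- data.frame(name = if (inner_cons) "conservative" else "creative",
                      start = c1, end = c2)
  outer <- data.frame(name = if (inner_cons) "creative" else "conservative",
                      start = c(c2, 0), end = c(genome_length, c1))
  out <- rbind(inner, outer)
  out[out$end > out$start, , drop = FALSE]
}
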