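# Greedy identity clustering of repeat units, family labeling, structural
# grammar of repeat regions, TSD/TIR annotation, and within- vs
# between-region identity comparison.

#' Global pairwise identity (needle-style)
#'
#' Needleman-Wunsch global alignment with EMBOSS-needle DNA scoring
#' (match +5, mismatch -4, gap open 10, gap extend 0.5); identity is
#' matches divided by alignment columns, end gaps included.
#'
#' @param a,b DNA strings.
#' @return Identity percentage in \[0, 100\].
#' @examples
#' global_identity("ACGTACGT", "ACGAACGT")  # 87.5
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  unname(.nw_stats_cpp(toupper(a), toupper(b))["identity_pct"])
}

#' All-pairs global identity matrix
#'
#' @param seqs Character vector of DNA sequences.
#' @return Symmetric matrix of identity percentages (diagonal 100).
#' @export
identity_matrix <- function(seqs) {
  .nw_identity_matrix_cpp(toupper(seqs))
}

#' Greedy identity clustering of repeat units
#'
#' Units are ordered by the mean distance (100 - identity) to their
#' `knn` closest neighbours (all available neighbours when fewer exist),
#' ties broken by genomic coordinate.  The first unit becomes a reference;
#' each subsequent unit joins the first existing reference it matches at
#' `>= threshold` identity, or becomes a new reference itself.
#'
#' @param units data.frame with at least a `seq` column; `start` and
#'   `region_id` are used for deterministic tie-breaking when present.
#' @param threshold Identity threshold in percent (default 70).
#' @param knn Number of nearest neighbours for the ordering (default 10).
#' @param idmat Optional precomputed identity matrix over `units`.
#' @return Object of class `repeat_clusters`: the input units plus
#'   `cluster` assignments, reference indices, the identity matrix, and
#'   (after [label_m1_m2()]) family labels.
#' @export
greedy_cluster <- function(units, threshold = 70, knn = 10, idmat = NULL) {
  n <- nrow(units)
  if (n < 1) stop("at least one unit is required")
  if (is.null(idmat)) idmat <- identity_matrix(units$seq)
  stopifnot(nrow(idmat) == n)
  if (n == 1) {
    mean_d <- 0
  } else {
    mean_d <- vapply(seq_len(n), function(i) {
      d <- sort((100 - idmat[i, -i]))
      mean(d[seq_len(min(knn, n - 1))])
    }, numeric(1))
  }
  coord <- if ("start" %in% names(units)) units$start else seq_len(n)
  ord <- order(mean_d, coord)
  refs <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    hit <- if (length(refs)) which(idmat[i, refs] >= threshold)[1] else NA_integer_
    if (is.na(hit)) {
      refs <- c(refs, i)
      assign[i] <- length(refs)
    } else {
      assign[i] <- hit
    }
  }
  structure(list(units = units, cluster = assign, refs = refs,
                 idmat = idmat, threshold = threshold, knn = knn,
                 labels = rep(NA_character_, length(refs))),
            class = "repeat_clusters")
}

#' Merge clusters sharing most of their members
#'
#' Two clusters merge when more than half of each cluster's members are at
#' least `threshold` identical to the other cluster's reference; merges
#' are closed transitively and the merged cluster keeps the larger
#' cluster's reference.  Idempotent.
#'
#' @param cl A [greedy_cluster()] result.
#' @param threshold Identity threshold in percent (defaults to the
#'   clustering threshold).
#' @return Updated `repeat_clusters`.
#' @export
merge_clusters <- function(cl, threshold = cl$threshold) {
  stopifnot(inherits(cl, "repeat_clusters"))
  k <- length(cl$refs)
  if (k < 2) return(cl)
  members <- split(seq_along(cl$cluster), cl$cluster)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  frac_ok <- function(a, b)  # fraction of cluster a's members matching ref of b
    mean(cl$idmat[members[[a]], cl$refs[b]] >= threshold)
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    if (frac_ok(a, b) > 0.5 && frac_ok(b, a) > 0.5) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  groups <- vapply(seq_len(k), find, integer(1))
  new_ids <- match(groups, unique(groups))
  # representative reference: the largest original cluster in each group
  sizes <- lengths(members)
  new_refs <- vapply(unique(groups), function(g) {
    cand <- which(groups == g)
    cl$refs[cand[which.max(sizes[cand])]]
  }, integer(1))
  structure(list(units = cl$units, cluster = new_ids[cl$cluster],
                 refs = new_refs, idmat = cl$idmat, threshold = cl$threshold,
                 knn = cl$knn, labels = rep(NA_character_, length(new_refs))),
            class = "repeat_clusters")
}

#' Label clusters as M1/M2 (and -like satellites)
#'
#' Without external references the most populous cluster is labeled M1 and
#' the second most populous M2; any smaller cluster whose reference aligns
#' to the M1 (resp. M2) reference at `>= threshold` identity becomes
#' M1-like (M2-like).  With a supplied named reference set, each cluster
#' follows its best-matching reference.
#'
#' @param cl A `repeat_clusters` object.
#' @param references Optional named character vector (or path to a FASTA
#'   file) of family reference sequences.
#' @param threshold Identity threshold in percent.
#' @return `repeat_clusters` with `labels` filled in; `cl$units` gains a
#'   `label` column.
#' @export
label_m1_m2 <- function(cl, references = NULL, threshold = cl$threshold) {
  stopifnot(inherits(cl, "repeat_clusters"), length(cl$refs) >= 1)
  k <- length(cl$refs)
  sizes <- tabulate(cl$cluster, k)
  labels <- rep("unlabeled", k)
  ref_seqs <- cl$units$seq[cl$refs]
  coord <- if ("start" %in% names(cl$units)) cl$units$start[cl$refs] else cl$refs
  if (is.null(references)) {
    ord <- order(-sizes, coord)
    labels[ord[1]] <- "M1"
    if (k >= 2) labels[ord[2]] <- "M2"
    if (k >= 3) {
      for (i in ord[-(1:2)]) {
        id1 <- .nw_stats_cpp(ref_seqs[i], ref_seqs[ord[1]])["identity_pct"]
        id2 <- if (k >= 2) .nw_stats_cpp(ref_seqs[i], ref_seqs[ord[2]])["identity_pct"] else -Inf
        if (max(id1, id2) >= threshold)
          labels[i] <- if (id1 >= id2) "M1-like" else "M2-like"
      }
    }
  } else {
    if (is.character(references) && length(references) == 1 &&
        file.exists(references)) {
      ss <- Biostrings::readDNAStringSet(references)
      references <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    }
    for (i in seq_len(k)) {
      ids <- vapply(references, function(r)
        unname(.nw_stats_cpp(ref_seqs[i], r)["identity_pct"]), numeric(1))
      if (max(ids) >= threshold) labels[i] <- names(references)[which.max(ids)]
    }
  }
  cl$labels <- labels
  cl$units$label <- labels[cl$cluster]
  cl
}

#' @export
print.repeat_clusters <- function(x, ...) {
  k <- length(x$refs)
  sizes <- tabulate(x$cluster, k)
  cat(sprintf("<repeat_clusters> %d units in %d clusters (threshold %.0f%%)\n",
              nrow(x$units), k, x$threshold))
  lab <- if (all(is.na(x$labels))) rep("?", k) else x$labels
  for (i in order(-sizes)[seq_len(min(k, 8))])
    cat(sprintf("  cluster %d [%s]: %d members\n", i, lab[i], sizes[i]))
  if (k > 8) cat("  ...\n")
  invisible(x)
}

#' Validate the structural grammar of a labeled repeat region
#'
#' Checks the region's unit labels against the observed organisation of
#' pithovirus repeat regions: (1) M2 never occurs without M1; (2) M1 may
#' stand alone; (3) consecutive M1 units are separated by about
#' `spacer` nt (end-to-start, the separating sequence carrying the M2
#' element when one is present); (4) between any two M2 there is an M1.
#'
#' @param region_units data.frame of units ordered by `start`, with
#'   `start`, `end`, `label`.
#' @param spacer Expected inter-M1 separation (nt).
#' @param spacer_tol Tolerance around `spacer`.
#' @return List of class `grammar_string`: tokens, spacers (inter-M1
#'   gaps), pattern (compressed, e.g. `"(M1-M2){3}-M1"`), per-rule logical
#'   `rules`, and `well_formed`.
#' @export
validate_grammar <- function(region_units, spacer = 140, spacer_tol = 60) {
  lab <- region_units$label
  if (is.null(lab) || anyNA(lab))
    stop("all units must carry an M1/M2 (or other) label")
  ord <- order(region_units$start)
  region_units <- region_units[ord, , drop = FALSE]
  tok <- ifelse(region_units$label %in% c("M1", "M1-like"), "M1",
                ifelse(region_units$label %in% c("M2", "M2-like"), "M2", "other"))
  m1 <- which(tok == "M1")
  gaps <- if (length(m1) >= 2)
    region_units$start[m1[-1]] - region_units$end[m1[-length(m1)]]
  else numeric(0)
  rules <- c(
    m2_implies_m1 = !("M2" %in% tok) || ("M1" %in% tok),
    m1_alone_ok = TRUE,
    m1_spacing = !length(gaps) || all(abs(gaps - spacer) <= spacer_tol),
    m1_between_m2 = {
      m2 <- which(tok == "M2")
      length(m2) < 2 ||
        all(vapply(seq_len(length(m2) - 1), function(i)
          any(m1 > m2[i] & m1 < m2[i + 1]), logical(1)))
    })
  structure(list(tokens = tok, spacers = gaps,
                 pattern = compress_pattern(tok),
                 rules = rules, well_formed = all(rules)),
            class = "grammar_string")
}

compress_pattern <- function(tok) {
  k <- length(tok)
  if (k == 1) return(sprintf("(%s)", tok))
  n <- (k - 1) / 2
  if (n == round(n) && identical(tok, c(rep(c("M1", "M2"), n), "M1")))
    return(sprintf("(M1-M2){%d}-M1", as.integer(n)))
  if (all(tok == tok[1])) return(sprintf("(%s){%d}", tok[1], k))
  paste(tok, collapse = "-")
}

#' @export
print.grammar_string <- function(x, ...) {
  cat(sprintf("<grammar> %s  [%s]\n", x$pattern,
              if (x$well_formed) "well-formed" else
                paste("violates:", paste(names(x$rules)[!x$rules], collapse = ", "))))
  invisible(x)
}

#' Detect a target-site duplication flanking an element or region
#'
#' Finds the longest exact duplication (up to `max_len` nt) whose copies
#' immediately flank both ends of the interval.  Flanks are read on the
#' circular sequence, so intervals at the linearization boundary are
#' handled.
#'
#' @param genome A [circular_genome()].
#' @param start,end Interval (0-based half-open) of the element/region,
#'   TSD copies excluded.
#' @param max_len Maximum TSD length to consider (default 6).
#' @return The TSD string, or `NA_character_` when the flanks share no
#'   suffix/prefix.
#' @export
detect_tsd <- function(genome, start, end, max_len = 6) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  idx_left <- ((start - max_len):(start - 1)) %% L + 1
  idx_right <- (end:(end + max_len - 1)) %% L + 1
  b <- strsplit(genome$seq, "")[[1]]
  left <- b[idx_left]; right <- b[idx_right]
  for (l in max_len:1) {
    if (identical(left[(max_len - l + 1):max_len], right[1:l]))
      return(paste(right[1:l], collapse = ""))
  }
  NA_character_
}

#' Measure the terminal inverted repeat of an element
#'
#' Compares the element's prefix with the reverse complement of its suffix
#' in the palindrome frame (the zero band of a banded alignment) and
#' reports the longest prefix matching at `>= min_identity` percent.  To
#' keep diluted mismatches from silently extending the TIR into the
#' internal sequence, the TIR end is placed at the running maximum of a
#' +1/-2 match/mismatch score along the frame (so extension requires local
#' identity above two thirds) and the reported TIR must match at
#' `>= min_identity` overall.
#' Low-complexity elements (dinucleotide entropy below 1 bit) and elements
#' with no TIR of at least `min_tir` nt report a TIR length of 0.
#'
#' @param unit_seq Element sequence (length >= 10).
#' @param min_tir Minimum TIR length (nt).
#' @param min_identity Identity threshold in percent.
#' @param band Offset band searched to absorb imprecise element boundaries
#'   (a few nt of flanking sequence on either end).
#' @return Named vector: `tir_length`, `internal_length`.
#' @export
detect_tir <- function(unit_seq, min_tir = 10, min_identity = 80, band = 10) {
  unit_seq <- toupper(unit_seq)
  n <- nchar(unit_seq)
  stopifnot(n >= 10)
  none <- c(tir_length = 0L, internal_length = n)
  di <- substring(unit_seq, 1:(n - 1), 2:n)
  p <- table(di) / (n - 1)
  if (-sum(p * log2(p)) < 1) return(none)  # low-complexity guard
  half <- n %/% 2L
  pre <- strsplit(substr(unit_seq, 1, half), "")[[1]]
  sufc <- strsplit(revcomp(substr(unit_seq, n - half + 1, n)), "")[[1]]
  best <- 0L
  for (d in -min(band, half - min_tir):min(band, half - min_tir)) {
    # pair pre[i] with sufc[i + d]
    i0 <- max(1L, 1L - d)
    i1 <- min(length(pre), length(sufc) - d)
    if (i1 - i0 + 1L < min_tir) next
    m <- pre[i0:i1] == sufc[(i0 + d):(i1 + d)]
    # frames tried: the full frame, and one anchored at the first run of 6
    # consecutive matches (skips residual flanking sequence on imprecise
    # element boundaries; at most `band` positions in)
    r <- rle(m)
    runs <- which(r$values & r$lengths >= 6)
    if (!length(runs)) next
    fa <- if (runs[1] == 1) 1L else sum(r$lengths[seq_len(runs[1] - 1)]) + 1L
    for (f in unique(c(1L, if (fa <= band + 1L) fa))) {
      mm <- m[f:length(m)]
      k <- length(mm)
      # score +1/-2 along the palindrome frame: the running maximum sits at
      # the TIR end unless the internal sequence itself matches at > 2/3
      sc <- cumsum(ifelse(mm, 1, -2))
      cum <- cumsum(mm) / seq_len(k)
      cand <- which(mm & cum >= min_identity / 100)
      cand <- cand[cand >= min_tir]
      if (!length(cand)) next
      l <- cand[which.max(sc[cand])]
      best <- max(best, l)
    }
  }
  if (best < min_tir) return(none)
  c(tir_length = best, internal_length = n - 2L * best)
}

#' Compare repeat identity within vs between regions
#'
#' Computes all pairwise identities of units from the same region and an
#' equal-size random subsample of pairs from different regions, then a
#' two-sided Wilcoxon rank-sum test between the two distributions.
#'
#' @param units data.frame with `seq` and `region_id` columns.
#' @param subsample Subsample different-region pairs down to the number of
#'   same-region pairs (default TRUE)?
#' @param seed Seed for the subsampling.
#' @param idmat Optional precomputed identity matrix over `units`.
#' @return List: `within`, `between` (identity vectors), `statistic`, `p`.
#' @export
identity_within_between <- function(units, subsample = TRUE, seed = 1L,
                                    idmat = NULL) {
  tab <- table(units$region_id)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 regions with at least 2 units each")
  if (is.null(idmat)) idmat <- identity_matrix(units$seq)
  n <- nrow(units)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  same <- units$region_id[pair_i] == units$region_id[pair_j]
  ids <- idmat[cbind(pair_i, pair_j)]
  within <- ids[same]
  between <- ids[!same]
  if (subsample) {
    set.seed(seed)
    between <- between[sample.int(length(between),
                                  min(length(within), length(between)))]
  }
  if (length(unique(c(within, between))) == 1L) {
    # degenerate: all identities equal, nothing to rank
    return(list(within = within, between = between, statistic = NA_real_,
                p = 1))
  }
  wt <- suppressWarnings(wilcox.test(within, between, exact = FALSE))
  list(within = within, between = between,
       statistic = unname(wt$statistic), p = wt$p.value)
}

#' Dotplot matrix of cluster reference sequences
#'
#' Draws a k x k matrix of word-match dotplots between cluster references
#' for visual inspection of family relatedness.
#'
#' @param cl A `repeat_clusters` object.
#' @param word Word size for dot matches.
#' @export
reference_dotplot <- function(cl, word = 8) {
  refs <- cl$units$seq[cl$refs]
  k <- length(refs)
  op <- par(mfrow = c(k, k), mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(par(op))
  words <- function(s) {
    n <- nchar(s)
    if (n < word) return(character(0))
    substring(s, 1:(n - word + 1), word:n)
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    wi <- words(refs[i]); wj <- words(refs[j])
    m <- outer(wi, wj, "==") | outer(wi, vapply(wj, revcomp, ""), "==")
    idx <- which(m, arr.ind = TRUE)
    plot(NA, xlim = c(1, max(1, length(wj))), ylim = c(1, max(1, length(wi))),
         axes = FALSE, xlab = "", ylab = "", frame.plot = TRUE)
    if (nrow(idx)) points(idx[, 2], idx[, 1], pch = ".", cex = 0.6)
  }
  invisible(cl)
}
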