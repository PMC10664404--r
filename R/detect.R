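# Repeat-rich region detection from genome self-alignment coverage:
# (i) self-alignment, (ii) flattened-dotplot coverage vector, (iii) smoothed
# coverage thresholding into regions, (iv) unit splitting on the smoothed
# coverage derivative.

#' Detection parameters
#'
#' @param evalue_max E-value threshold for self-alignment hits.
#' @param region_window Sliding-mean window (nt) for region detection;
#'   500 nt for repeat mapping, 4000 nt when defining the broader
#'   repeat-rich regions used for gene statistics.
#' @param derivative_window Sliding-mean window (nt) applied before and
#'   after the derivative when splitting units.
#' @param derivative_cutoff Minimum height of a derivative local maximum to
#'   count as a unit boundary.
#' @param sensitivity Sensitivity coefficient of the detection threshold;
#'   larger values lower the threshold.
#' @param tau_mode How the printed threshold expression is read:
#'   `"divide"` (default) gives tau = mean(ys)/sensitivity; `"affine"`
#'   gives tau = mean(ys)*sensitivity - 1.
#' @param min_region_length Discard regions shorter than this
#'   (default window/5), suppressing single-crossing noise.
#' @param word_size Exact-match seed length of the internal aligner.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(evalue_max = 1e-10, region_window = 500L,
                             derivative_window = 20L, derivative_cutoff = 10,
                             sensitivity = 2.5,
                             tau_mode = c("divide", "affine"),
                             min_region_length = region_window %/% 5L,
                             word_size = 12L) {
  stopifnot(evalue_max > 0, region_window > 0, derivative_window > 0,
            derivative_cutoff > 0, sensitivity > 0, word_size >= 11)
  structure(list(evalue_max = evalue_max,
                 region_window = as.integer(region_window),
                 derivative_window = as.integer(derivative_window),
                 derivative_cutoff = derivative_cutoff,
                 sensitivity = sensitivity,
                 tau_mode = match.arg(tau_mode),
                 min_region_length = as.integer(min_region_length),
                 word_size = as.integer(word_size)),
            class = "detection_params")
}

#' Align a genome against itself
#'
#' The internal backend seeds on exact words (>= 11 nt) and extends them
#' without gaps under an X-drop criterion, reporting both orientations with
#' Karlin-Altschul E-values comparable to BLASTN's; hits above
#' `params$evalue_max` are discarded and the trivial full-length self-hit
#' is never formed.  Alternatively, precomputed hits in the 12-column
#' tabular alignment format can be imported with `hits_file`.
#'
#' @param genome A [circular_genome()].
#' @param params [detection_params()].
#' @param hits_file Optional tabular alignment file; when given, the
#'   internal aligner is skipped.
#' @return data.frame of hits: q_start, q_end, s_start, s_end (0-based
#'   half-open), strand, identity_pct, evalue, bitscore.
#' @export
self_align <- function(genome, params = detection_params(), hits_file = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!is.null(hits_file))
    return(read_tabular_hits(hits_file, genome$length, params$evalue_max))
  .self_align_cpp(genome$seq, word = params$word_size,
                  evalue_max = params$evalue_max)
}

#' Flattened-dotplot coverage vector
#'
#' Counts, for every genome position, the number of times it was covered by
#' a self-alignment hit: each hit increments every position of its query
#' interval and of its subject interval by one.
#'
#' @param hits Hit data.frame from [self_align()].
#' @param L Genome length.
#' @return Integer vector of length `L`.
#' @export
coverage_vector <- function(hits, L) {
  .coverage_cpp(as.integer(hits$q_start), as.integer(hits$q_end),
                as.integer(hits$s_start), as.integer(hits$s_end), as.integer(L))
}

circular_mean <- function(x, window) {
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2,
                           circular = TRUE))
}

#' Smooth the coverage vector and derive the detection threshold
#'
#' The smooth vector `ys` is a circular centred sliding mean of `y` over
#' `region_window` nt.  The detection threshold is
#' `tau = mean(ys)/sensitivity` (or `mean(ys)*sensitivity - 1` under
#' `tau_mode = "affine"`).
#'
#' @param y Integer coverage vector.
#' @param params [detection_params()].
#' @return List of class `coverage_profile`: y, ys, window, tau,
#'   sensitivity, tau_mode.
#' @export
smooth_threshold <- function(y, params = detection_params()) {
  if (length(y) <= params$region_window)
    stop("smoothing window (", params$region_window,
         ") must be smaller than the sequence (", length(y), ")")
  ys <- circular_mean(y, params$region_window)
  tau <- switch(params$tau_mode,
                divide = mean(ys) / params$sensitivity,
                affine = mean(ys) * params$sensitivity - 1)
  structure(list(y = y, ys = ys, window = params$region_window, tau = tau,
                 sensitivity = params$sensitivity, tau_mode = params$tau_mode,
                 params = params),
            class = "coverage_profile")
}

#' Detect repeat-rich regions
#'
#' Repeat-rich regions are the maximal runs where the smoothed coverage
#' `ys` exceeds the threshold `tau`; region boundaries are the crossing
#' positions.  A run wrapping the linearization origin is split at the
#' origin and both parts are flagged `wrapped`.  Runs shorter than
#' `min_region_length` are discarded.
#'
#' @param profile A [smooth_threshold()] profile.
#' @param genome_id Identifier attached to the output (optional).
#' @return data.frame: genome_id, start, end (0-based half-open), mean_ys,
#'   wrapped; disjoint and sorted.
#' @export
detect_regions <- function(profile, genome_id = NA_character_) {
  stopifnot(inherits(profile, "coverage_profile"))
  above <- profile$ys > profile$tau
  L <- length(above)
  empty <- data.frame(genome_id = character(), start = integer(),
                      end = integer(), mean_ys = numeric(), wrapped = logical())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- data.frame(start = starts[r$values] - 1L, end = ends[r$values],
                    wrapped = FALSE)
  if (all(above)) reg <- data.frame(start = 0L, end = L, wrapped = FALSE)
  else if (nrow(reg) > 1 && reg$start[1] == 0L && reg$end[nrow(reg)] == L) {
    # single circular run crossing the origin, reported split and flagged
    reg$wrapped[c(1L, nrow(reg))] <- TRUE
  }
  keep <- (reg$end - reg$start) >= profile$params$min_region_length | reg$wrapped
  reg <- reg[keep, , drop = FALSE]
  if (!nrow(reg)) return(empty)
  reg$mean_ys <- vapply(seq_len(nrow(reg)), function(i)
    mean(profile$ys[(reg$start[i] + 1L):reg$end[i]]), numeric(1))
  data.frame(genome_id = genome_id, start = reg$start, end = reg$end,
             mean_ys = reg$mean_ys, wrapped = reg$wrapped,
             row.names = NULL, stringsAsFactors = FALSE)
}

# strict local maxima over a 3-point neighborhood; plateaus take the
# leftmost position (deterministic tie-break)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  cand <- which(x > left & x >= right)
  # drop plateau positions that are not the leftmost of their plateau
  cand[x[cand] > right[cand] |
         vapply(cand, function(i) {
           j <- i
           while (j < n && x[j + 1] == x[i]) j <- j + 1L
           j < n && x[j + 1] < x[i]
         }, logical(1))]
}

#' Split a region into individual repeat units
#'
#' Unit boundaries are local maxima of the absolute smoothed derivative of
#' the smoothed coverage vector (sliding mean of window
#' `derivative_window` applied to `y` before the first difference and to
#' its absolute value after), kept when they exceed `derivative_cutoff`
#' and restricted to the region.  Consecutive boundaries delimit units;
#' a region with no internal boundary yields a single unit spanning it.
#'
#' @param profile A [smooth_threshold()] profile.
#' @param region Single-row region data.frame (from [detect_regions()]).
#' @param params [detection_params()].
#' @return data.frame: start, end of each unit (0-based half-open), ordered
#'   and non-overlapping, nested within the region.
#' @export
split_units <- function(profile, region, params = detection_params()) {
  stopifnot(inherits(profile, "coverage_profile"), nrow(region) == 1)
  deriv <- unit_derivative(profile$y, params$derivative_window)
  idx <- seq(region$start + 1L, region$end)  # 1-based positions in region
  cand <- local_maxima(deriv[idx])
  cand <- cand[deriv[idx][cand] > params$derivative_cutoff]
  bounds <- region$start + cand - 1L         # 0-based boundary coordinates
  if (length(bounds) < 2)
    return(data.frame(start = region$start, end = region$end))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

unit_derivative <- function(y, window) {
  s1 <- circular_mean(y, window)
  d <- c(diff(s1), s1[1] - s1[length(s1)])  # circular first difference
  circular_mean(abs(d), window)
}

#' Run the full repeat-detection pipeline on one genome
#'
#' Chains [self_align()], [coverage_vector()], [smooth_threshold()],
#' [detect_regions()] and [split_units()], and extracts unit sequences.
#'
#' @param genome A [circular_genome()].
#' @param params [detection_params()].
#' @param hits_file Optional precomputed tabular alignment file.
#' @return Object of class `repeat_scan`: genome, hits, profile, regions,
#'   units (with sequences), params.
#' @examples
#' sim <- simulate_genome(sim_config(genome_length = 50000, n_regions = 8,
#'                                   seed = 42))
#' scan <- detect_repeats(sim$genome)
#' summary(scan)
#' @export
detect_repeats <- function(genome, params = detection_params(),
                           hits_file = NULL) {
  hits <- self_align(genome, params, hits_file)
  y <- coverage_vector(hits, genome$length)
  profile <- smooth_threshold(y, params)
  regions <- detect_regions(profile, genome$id)
  units <- NULL
  if (nrow(regions)) {
    units <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      u <- split_units(profile, regions[i, ], params)
      u$region_id <- i
      u
    }))
    units$genome_id <- genome$id
    units$seq <- substring(genome$seq, units$start + 1L, units$end)
    units <- units[, c("genome_id", "region_id", "start", "end", "seq")]
  } else {
    units <- data.frame(genome_id = character(), region_id = integer(),
                        start = integer(), end = integer(), seq = character())
  }
  structure(list(genome = genome, hits = hits, profile = profile,
                 regions = regions, units = units, params = params),
            class = "repeat_scan")
}

#' @export
print.repeat_scan <- function(x, ...) {
  cat(sprintf("<repeat_scan> %s (%d nt): %d hits, tau = %.3g, %d regions, %d units\n",
              x$genome$id, x$genome$length, nrow(x$hits), x$profile$tau,
              nrow(x$regions), nrow(x$units)))
  invisible(x)
}

#' @export
summary.repeat_scan <- function(object, ...) {
  reg <- object$regions
  masked <- sum(reg$end - reg$start)
  cat(sprintf("Repeat scan of %s (%d nt)\n", object$genome$id,
              object$genome$length))
  cat(sprintf("  hits kept (E <= %.1g): %d\n", object$params$evalue_max,
              nrow(object$hits)))
  cat(sprintf("  threshold tau = %.4g (%s mode, sensitivity %.2f)\n",
              object$profile$tau, object$profile$tau_mode,
              object$profile$sensitivity))
  cat(sprintf("  repeat-rich regions: %d covering %d nt (%.1f%% of genome)\n",
              nrow(reg), masked, 100 * masked / object$genome$length))
  cat(sprintf("  repeat units: %d (median length %.0f nt)\n",
              nrow(object$units),
              if (nrow(object$units)) median(object$units$end - object$units$start)
              else NA))
  invisible(object)
}

#' Plot the smoothed coverage profile with detected regions
#'
#' @param x A `repeat_scan`.
#' @param xlim Optional coordinate window.
#' @param ... Passed to [plot()].
#' @export
plot.repeat_scan <- function(x, xlim = NULL, ...) {
  L <- x$genome$length
  if (is.null(xlim)) xlim <- c(0, L)
  pos <- seq.int(max(1, xlim[1]), min(L, xlim[2]))
  plot(pos, x$profile$ys[pos], type = "l", xlab = "genome position (nt)",
       ylab = "smoothed self-alignment coverage", ...)
  abline(h = x$profile$tau, lty = 2, col = "red3")
  if (nrow(x$regions))
    rect(x$regions$start, 0, x$regions$end, x$profile$tau,
         col = rgb(0.8, 0.3, 0.2, 0.3), border = NA)
  invisible(x)
}

#' Export a repeat scan to disk
#'
#' Writes regions BED, units BED, units FASTA and the profile TSV
#' (pos, y, ys, tau); byte-identical for identical genome and parameters.
#'
#' @param scan A `repeat_scan`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_repeat_scan <- function(scan, prefix) {
  reg <- scan$regions
  files <- character(0)
  f <- paste0(prefix, ".regions.bed")
  write_bed(data.frame(chrom = reg$genome_id, start = reg$start, end = reg$end,
                       name = sprintf("region%03d", seq_len(nrow(reg))),
                       score = round(reg$mean_ys, 2)), f)
  files <- c(files, f)
  u <- scan$units
  f <- paste0(prefix, ".units.bed")
  write_bed(data.frame(chrom = u$genome_id, start = u$start, end = u$end,
                       name = sprintf("region%03d", u$region_id),
                       score = stats::ave(u$start, u$region_id, FUN = seq_along)), f)
  files <- c(files, f)
  f <- paste0(prefix, ".units.fasta")
  if (nrow(u)) {
    seqs <- setNames(u$seq, sprintf("%s:%d-%d|region%03d", u$genome_id,
                                    u$start, u$end, u$region_id))
    write_fasta(seqs, f)
    files <- c(files, f)
  }
  f <- paste0(prefix, ".profile.tsv")
  write.table(data.frame(pos = seq_along(scan$profile$y) - 1L,
                         y = scan$profile$y,
                         ys = signif(scan$profile$ys, 8),
                         tau = signif(scan$profile$tau, 8)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
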