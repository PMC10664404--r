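#' Circular genome objects
#'
#' A `circular_genome` is a plain container for a single (usually circular)
#' DNA sequence together with the rotation (`offset`) that was applied to
#' linearize it relative to the deposited sequence.  All coordinates used by
#' the package are 0-based half-open on the linearized sequence.
#'
#' @param id Sequence identifier.
#' @param seq DNA string over A, C, G, T, N (case-insensitive; stored
#'   uppercase).
#' @param circular Logical; is the molecule circular?
#' @param offset Rotation (in nt) already applied relative to the reference
#'   start position.
#' @return An object of class `circular_genome` with fields `id`, `seq`,
#'   `length`, `circular` and `offset`.
#' @examples
#' g <- circular_genome("toy", "ACGTACGT")
#' g$length
#' @export
circular_genome <- function(id, seq, circular = TRUE, offset = 0L) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", seq)) stop("genome sequence contains characters outside {A,C,G,T,N}")
  structure(
    list(id = as.character(id), seq = seq, length = nchar(seq),
         circular = isTRUE(circular), offset = as.integer(offset)),
    class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d nt (%s, offset %d), GC %.1f%%\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              x$offset, 100 * gc_fraction(x$seq)))
  invisible(x)
}

#' Rotate and linearize a circular genome
#'
#' Cuts a circular genome at `new_start` and swaps the two arcs so that the
#' linearized sequence begins at that position, optionally reverse
#' complementing the result.  Used to place related genomes on a common
#' reference coordinate system before comparative analyses.
#'
#' @param genome A [circular_genome()].
#' @param new_start 0-based position that becomes position 0.
#' @param reverse_complement Reverse complement after rotating?
#' @return A new `circular_genome`; length and base composition are
#'   unchanged and the cumulative `offset` is recorded.
#' @examples
#' rotate_linearize(circular_genome("g", "ACGTAC"), 2)$seq  # "GTACAC"
#' @export
rotate_linearize <- function(genome, new_start, reverse_complement = FALSE) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (new_start < 0 || new_start >= L)
    stop("new_start must lie in [0, genome length): got ", new_start)
  s <- if (new_start == 0) genome$seq else
    paste0(substr(genome$seq, new_start + 1L, L), substr(genome$seq, 1L, new_start))
  if (reverse_complement) s <- revcomp(s)
  circular_genome(genome$id, s, genome$circular,
                  (genome$offset + new_start) %% L)
}

#' Reverse complement of a DNA string
#'
#' @param x A DNA string (character scalar or vector).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (acgt == 0) return(NA_real_)
  sum(b %in% c("G", "C")) / acgt
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param circular Mark sequences as circular?
#' @return A list of [circular_genome()] objects (named by sequence id).
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    circular_genome(sub("\\s.*$", "", names(ss)[i]), as.character(ss[[i]]), circular))
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write genomes (or any named sequences) to FASTA
#'
#' @param x A `circular_genome`, a list of them, or a named character vector
#'   of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "circular_genome")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "circular_genome"))) {
    seqs <- vapply(x, `[[`, "", "seq")
    names(seqs) <- vapply(x, `[[`, "", "id")
    x <- seqs
  }
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
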