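# Readers/writers for the small tabular formats the analyses consume.
# Internal convention everywhere: 0-based half-open intervals (BED-style);
# GFF3 export converts to 1-based inclusive.

#' Write intervals as BED6
#'
#' @param x data.frame with columns `chrom` (or `genome_id`), `start`, `end`
#'   and optionally `name`, `score`, `strand`.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  chrom <- if ("chrom" %in% names(x)) x$chrom else x$genome_id
  df <- data.frame(
    chrom = chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) x$strand else ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file (3-6 columns).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand")[seq_len(max(count.fields(path, sep = "\t")))],
                   stringsAsFactors = FALSE)
  for (col in c("name", "score", "strand"))
    if (is.null(df[[col]])) df[[col]] <- if (col == "score") 0L else "."
  df
}

#' Read gene annotations from GFF3
#'
#' Keeps rows of the requested feature type and extracts `ID` from the
#' attribute column.  Coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param feature Feature type(s) to keep (default CDS and gene).
#' @param min_aa Keep genes longer than this many amino acids (0 keeps
#'   all; core/pan-genome analyses conventionally use 100).
#' @return data.frame: gene_id, genome, start, end, strand.
#' @export
read_gff_genes <- function(path, feature = c("gene", "CDS"), min_aa = 0) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(data.frame(gene_id = character(), genome = character(),
                                        start = integer(), end = integer(),
                                        strand = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("malformed GFF3 row at line ", bad[1])
  f <- do.call(rbind, f)
  keep <- f[, 3] %in% feature
  f <- f[keep, , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", f[, 9])
  out <- data.frame(gene_id = ids, genome = f[, 1],
                    start = as.integer(f[, 4]) - 1L, end = as.integer(f[, 5]),
                    strand = f[, 7], stringsAsFactors = FALSE)
  out[(out$end - out$start) / 3 > min_aa, , drop = FALSE]
}

#' Write a gene table as GFF3
#'
#' @param genes data.frame with gene_id, genome, start, end, strand
#'   (0-based half-open).
#' @param path Output file.
#' @param feature Feature type to write.
#' @export
write_gff_genes <- function(genes, path, feature = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tgvrepeats\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$genome, feature, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id), con)
  invisible(path)
}

#' Import precomputed self-alignment hits (12-column tabular format)
#'
#' Reads the standard 12-column tabular alignment format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore;
#' 1-based inclusive coordinates), converts to the package's 0-based
#' half-open convention, infers strand from subject coordinate order,
#' drops hits above the E-value threshold and removes the trivial
#' full-length self-hit.
#'
#' @param path Tabular alignment file.
#' @param genome_length Genome length in nt (used to identify the trivial
#'   self-hit and to validate coordinates).
#' @param evalue_max Keep hits with evalue <= this (default 1e-10).
#' @return data.frame of hits: q_start, q_end, s_start, s_end, strand,
#'   identity_pct, evalue, bitscore.
#' @export
read_tabular_hits <- function(path, genome_length, evalue_max = 1e-10) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 12L)
  if (length(bad))
    stop("malformed tabular alignment row at line ", bad[1],
         ": expected 12 columns, got ", lengths(f)[bad[1]])
  f <- do.call(rbind, f)
  qs <- as.integer(f[, 7]); qe <- as.integer(f[, 8])
  ss <- as.integer(f[, 9]); se <- as.integer(f[, 10])
  minus <- ss > se
  tmp <- ss[minus]; ss[minus] <- se[minus]; se[minus] <- tmp
  hits <- data.frame(
    q_start = qs - 1L, q_end = qe, s_start = ss - 1L, s_end = se,
    strand = ifelse(minus, "-", "+"),
    identity_pct = as.numeric(f[, 3]), evalue = as.numeric(f[, 11]),
    bitscore = as.numeric(f[, 12]), stringsAsFactors = FALSE)
  if (any(hits$q_end > genome_length | hits$s_end > genome_length))
    stop("alignment coordinates exceed genome length")
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  trivial <- hits$strand == "+" & hits$q_start == 0L & hits$s_start == 0L &
    hits$q_end == genome_length & hits$s_end == genome_length
  hits <- hits[!trivial, , drop = FALSE]
  # canonical ordering: symmetric duplicates (A<->B and B<->A) collapse
  swap <- hits$q_start > hits$s_start
  if (any(swap)) {
    qtmp <- hits[swap, c("q_start", "q_end")]
    hits[swap, c("q_start", "q_end")] <- hits[swap, c("s_start", "s_end")]
    hits[swap, c("s_start", "s_end")] <- qtmp
  }
  unique(hits)
}

#' Read an OrthoFinder-style HOG table
#'
#' One row per hierarchical orthologous group (HOG), one column per genome
#' holding comma-separated gene identifiers; empty cells mean absence.
#' Columns named `HOG`, `OG` or `Gene.Tree.Parent.Clade` are treated as
#' metadata, the first being used as HOG identifier.
#'
#' @param path TSV file.
#' @return A [hog_matrix()] of gene counts (HOGs x genomes).
#' @export
read_hog_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  meta <- intersect(c("HOG", "OG", "Gene Tree Parent Clade",
                      "Gene.Tree.Parent.Clade"), names(df))
  ids <- if (length(meta)) df[[meta[1]]] else paste0("HOG", seq_len(nrow(df)))
  gcols <- setdiff(names(df), meta)
  counts <- vapply(gcols, function(cn) {
    x <- df[[cn]]
    ifelse(is.na(x) | x == "", 0L, lengths(strsplit(x, ",")))
  }, integer(nrow(df)))
  counts <- matrix(counts, nrow = nrow(df),
                   dimnames = list(ids, gcols))
  hog_matrix(counts)
}

#' Read a rooted species tree in Newick format
#'
#' Thin wrapper around [ape::read.tree()] that checks the tree is rooted.
#'
#' @param path Newick file.
#' @return An object of class `phylo`.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (!ape::is.rooted(tr)) stop("species tree must be rooted")
  tr
}

#' Read a per-position IPD-ratio track
#'
#' @param path TSV with columns genome_id, position (0-based), ipd_ratio.
#' @return data.frame with those columns.
#' @export
read_ipd_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("genome_id", "position", "ipd_ratio")
  if (!all(need %in% names(df)))
    stop("IPD track must have columns: ", paste(need, collapse = ", "))
  if (any(df$ipd_ratio < 0)) stop("ipd_ratio must be nonnegative")
  df
}

count.fields <- utils::count.fields
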