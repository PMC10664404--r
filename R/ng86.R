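# Nei-Gojobori (1986) counting dN/dS with Jukes-Cantor correction.
# Synonymous/nonsynonymous site counts are averaged over both sequences;
# per-codon-pair differences are averaged over all shortest substitution
# paths, excluding paths through stop codons.  Deterministic and
# dependency-free, adequate for the rank-based comparisons downstream.

.ng86 <- new.env(parent = emptyenv())

.ng86_init <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  syn_sites <- nonsyn_sites <- setNames(numeric(length(sense)), sense)
  for (cdn in sense) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cdn, p, p))) {
        mut <- cdn
        substr(mut, p, p) <- b
        if (code[[mut]] == "*") next      # stop mutations count as neither
        if (code[[mut]] == code[[cdn]]) syn_sites[cdn] <- syn_sites[cdn] + 1 / 3
        else nonsyn_sites[cdn] <- nonsyn_sites[cdn] + 1 / 3
      }
    }
  }
  .ng86$code <- code
  .ng86$syn_sites <- syn_sites
  .ng86$nonsyn_sites <- nonsyn_sites
  .ng86$pair_cache <- new.env(parent = emptyenv())
  invisible()
}

# average (syn, nonsyn) difference counts over all shortest paths c1 -> c2
.ng86_pair <- function(c1, c2) {
  key <- paste0(c1, c2)
  cached <- .ng86$pair_cache[[key]]
  if (!is.null(cached)) return(cached)
  code <- .ng86$code
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 1) list(pos) else
    apply(perms(length(pos)), 1, function(o) pos[o], simplify = FALSE)
  count_path <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") return(NULL)  # path through a stop codon
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counted <- Filter(Negate(is.null), lapply(paths, count_path))
  if (!length(counted))  # all paths pass through stops: fall back to all
    counted <- lapply(paths, function(order) {
      cur <- c1; sd <- nd <- 0
      for (p in order) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  res <- colMeans(do.call(rbind, counted))
  assign(key, res, envir = .ng86$pair_cache)
  res
}

perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Counting-method dN/dS for an aligned CDS pair
#'
#' Nei-Gojobori (1986) estimator: synonymous and nonsynonymous sites are
#' counted per codon (averaged over the two sequences), differences are
#' counted over all shortest substitution paths between each codon pair
#' (paths through stop codons excluded), and the proportions are
#' Jukes-Cantor corrected.  Following the study's filters, an estimate is
#' `accepted` only when 0.1 < dS < 1.5 and dN/dS < 10.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length, frame 1.
#'   Gap ("-") or ambiguous codons are skipped; a shared terminal stop
#'   codon is tolerated and dropped.
#' @return List of class `dnds_estimate`: dn, ds, omega, S, N, Sd, Nd,
#'   n_codons, accepted.
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("aligned CDS pair must have equal lengths")
  if (nchar(a) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  n <- nchar(a) %/% 3L
  ca <- substring(a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  code <- .ng86$code
  # shared terminal stop is allowed; internal stops are data errors
  if (n > 1 && !is.na(code[ca[n]]) && !is.na(code[cb[n]]) &&
      code[ca[n]] == "*" && code[cb[n]] == "*") {
    ca <- ca[-n]; cb <- cb[-n]
  }
  usable <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  if (any(usable & (code[ca] == "*" | code[cb] == "*")))
    stop("internal stop codon in aligned CDS pair")
  ca <- ca[usable]; cb <- cb[usable]
  if (!length(ca)) stop("no usable codons in alignment")
  S <- (sum(.ng86$syn_sites[ca]) + sum(.ng86$syn_sites[cb])) / 2
  N <- (sum(.ng86$nonsyn_sites[ca]) + sum(.ng86$nonsyn_sites[cb])) / 2
  diffs <- which(ca != cb)
  Sd <- Nd <- 0
  for (i in diffs) {
    d <- .ng86_pair(ca[i], cb[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  ds <- jc_correct(if (S > 0) Sd / S else NA_real_)
  dn <- jc_correct(if (N > 0) Nd / N else NA_real_)
  omega <- if (!is.na(ds) && is.finite(ds) && ds > 0) dn / ds else NA_real_
  accepted <- !is.na(ds) && !is.na(omega) && is.finite(omega) &&
    ds > 0.1 && ds < 1.5 && omega < 10
  structure(list(dn = dn, ds = ds, omega = omega, S = S, N = N, Sd = Sd,
                 Nd = Nd, n_codons = length(ca), accepted = accepted),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("<dnds_estimate> dN = %.4f, dS = %.4f, dN/dS = %s (%s)\n",
              x$dn, x$ds, ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega)),
              if (x$accepted) "accepted" else "rejected by filters"))
  invisible(x)
}

#' Per-gene dN/dS summaries from ortholog-pair estimates
#'
#' The dN and dS values for each gene are the means over all accepted
#' pairwise estimates involving it.
#'
#' @param pairs data.frame with columns `gene_id`, `dn`, `ds`, `omega`,
#'   `accepted` (one row per ortholog pair a gene participates in).
#' @return data.frame: gene_id, dn, ds, omega (means over accepted pairs);
#'   genes with no accepted pair are dropped.
#' @export
gene_dnds_means <- function(pairs) {
  keep <- pairs[pairs$accepted, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(gene_id = character(), dn = numeric(), ds = numeric(),
                      omega = numeric()))
  agg <- aggregate(keep[, c("dn", "ds", "omega")],
                   by = list(gene_id = keep$gene_id), FUN = mean)
  agg[order(agg$gene_id), ]
}
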