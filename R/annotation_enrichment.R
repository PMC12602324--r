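#' Genomic annotation and enrichment statistics
#'
#' Cis/trans classification of SNP-CpG pairs, nearest-gene annotation,
#' Fisher 2x2 tests for suggestive-set overlap between models, and
#' hypergeometric gene-set enrichment with a resampling family-wise error
#' rate.
#'
#' @name annotation_enrichment
NULL

#' Classify a SNP-CpG pair as cis or trans
#'
#' Distance is the absolute base-pair difference of the two positions --
#' computed from the raw coordinates even for inter-chromosomal pairs, which
#' is how pair distances are conventionally tabulated; the cis call
#' additionally requires the same chromosome and distance at most `window`.
#'
#' @param snp_chr,snp_pos SNP chromosome and 1-based position.
#' @param cpg_chr,cpg_pos CpG chromosome and 1-based position.
#' @param window Cis window in bp (default 1e6).
#' @return Data frame with `distance` (bp) and `cis` (logical). Vectorized.
#' @export
classify_cis_trans <- function(snp_chr, snp_pos, cpg_chr, cpg_pos,
                               window = 1e6) {
  distance <- abs(as.numeric(cpg_pos) - as.numeric(snp_pos))
  cis <- (as.character(snp_chr) == as.character(cpg_chr)) &
    distance <= window
  data.frame(distance = distance, cis = cis)
}

#' Nearest gene to a locus
#'
#' Finds, per locus, the gene interval minimizing the distance (0 if the
#' locus falls inside the gene); equidistant candidates are resolved in
#' favour of the lower start coordinate.
#'
#' @param chr,pos Locus chromosome(s) and 1-based position(s); vectorized.
#' @param genes Data frame with `chr`, `start`, `end` (1-based inclusive)
#'   and `gene` columns, e.g. from [read_genes_bed()].
#' @return Data frame with `gene` and `distance` per locus (`NA` where the
#'   chromosome carries no annotation).
#' @export
nearest_gene <- function(chr, pos, genes) {
  stopifnot(all(c("chr", "start", "end", "gene") %in% names(genes)))
  out <- data.frame(gene = rep(NA_character_, length(pos)),
                    distance = rep(NA_real_, length(pos)))
  for (i in seq_along(pos)) {
    g <- genes[genes$chr == as.character(chr[i]), , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(g$start - pos[i], pos[i] - g$end, 0)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(g$start[best])]
    out$gene[i] <- g$gene[best]
    out$distance[i] <- d[best]
  }
  out
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive
#' coordinates.
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return Data frame with `chr`, `start`, `end`, `gene`.
#' @export
read_genes_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    data.frame(chr = as.character(gr$seqnames), start = gr$start,
               end = gr$end, gene = gr$name, stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(chr = as.character(d[[1L]]), start = d[[2L]] + 1L,
               end = d[[3L]], gene = d[[4L]], stringsAsFactors = FALSE)
  }
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration (summing all tables with
#' the observed margins whose probability does not exceed the observed
#' table's); odds ratio as the sample cross-product ratio with Haldane +0.5
#' continuity correction when any cell is zero; Woolf 95% CI on the log OR.
#'
#' @param a,b,c,d Cell counts: rows = classification 1, columns =
#'   classification 2.
#' @return List with `p`, `or`, `ci_low`, `ci_high`, `table`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("fisher_2x2: cells must be non-negative integers")
  }
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 + m2 == 0 || (n1 == 0 && b + d == 0)) {
    stop("fisher_2x2: empty margin")
  }
  lo <- max(0L, n1 - m2)
  hi <- min(m1, n1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m1, m2, n1)
  p_obs <- stats::dhyper(a, m1, m2, n1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  cc <- if (any(counts == 0)) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  se_log <- sqrt(sum(1 / (counts + if (cc > 0) 0.5 else 0)))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  list(p = p, or = or, ci_low = ci[1L], ci_high = ci[2L],
       table = matrix(counts, 2L, byrow = TRUE))
}

#' Cross-model suggestive-overlap tables
#'
#' Builds, per entity type (SNP or CpG), the 2x2 table of unique entities
#' cross-classified by suggestive status in two models over a shared
#' universe, and runs [fisher_2x2()] on it. Used e.g. to ask whether
#' suggestive Gmodel SNPs are over-represented among suggestive GxEmodel
#' SNPs.
#'
#' @param universe Character vector of all tested entity ids (shared by both
#'   models).
#' @param suggestive_a,suggestive_b Character vectors of suggestive entities
#'   in each model; must be subsets of `universe`.
#' @return List with the 2x2 `table` (a = suggestive in both) and the
#'   [fisher_2x2()] result under `fisher`.
#' @export
suggestive_overlap_test <- function(universe, suggestive_a, suggestive_b) {
  if (length(setdiff(suggestive_a, universe)) ||
      length(setdiff(suggestive_b, universe))) {
    stop("suggestive_overlap_test: suggestive sets must lie in the universe")
  }
  in_a <- universe %in% suggestive_a
  in_b <- universe %in% suggestive_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  list(table = matrix(c(a, b, c_, d), 2L, byrow = TRUE),
       fisher = fisher_2x2(a, b, c_, d))
}

#' Gene-set enrichment with resampling FWER
#'
#' Per-set hypergeometric over-representation test of candidate genes
#' against the full universe (candidates plus background), with a
#' family-wise-error-rate-adjusted p computed by resampling: the adjusted p
#' of a set is the fraction of `n_random` random candidate sets (same size,
#' drawn from the universe) whose minimum raw p across sets is at most the
#' observed set's raw p.
#'
#' @param candidates Character vector of candidate gene ids (non-empty).
#' @param background Character vector of background gene ids.
#' @param sets Named list of gene sets (character vectors).
#' @param n_random Number of random candidate sets (default 1000).
#' @param seed RNG seed for the resampling.
#' @return Data frame with one row per set: `set`, `n_set`, `n_overlap`,
#'   `p_hyper`, `p_fwer`.
#' @export
geneset_enrichment <- function(candidates, background, sets,
                               n_random = 1000, seed = 1L) {
  candidates <- unique(candidates)
  if (!length(candidates)) stop("geneset_enrichment: empty candidate list")
  universe <- unique(c(candidates, background))
  n_u <- length(universe)
  n_c <- length(candidates)

  raw_p <- function(cand) {
    vapply(sets, function(s) {
      s <- intersect(s, universe)
      k <- length(intersect(s, cand))
      # over-representation: P(X >= k)
      stats::phyper(k - 1L, length(s), n_u - length(s), length(cand),
                    lower.tail = FALSE)
    }, numeric(1))
  }
  obs <- raw_p(candidates)

  set.seed(as.integer(seed))
  min_ps <- vapply(seq_len(n_random), function(r) {
    min(raw_p(sample(universe, n_c)))
  }, numeric(1))
  fwer <- vapply(obs, function(p) mean(min_ps <= p), numeric(1))
  # the minP adjustment is bounded below by the raw p; enforce the bound
  # against resampling noise
  fwer <- pmax(fwer, obs)

  data.frame(
    set = names(sets),
    n_set = vapply(sets, function(s) length(intersect(s, universe)),
                   integer(1)),
    n_overlap = vapply(sets, function(s)
      length(intersect(intersect(s, universe), candidates)), integer(1)),
    p_hyper = unname(obs),
    p_fwer = unname(fwer),
    row.names = NULL)
}
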