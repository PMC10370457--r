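# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (per-base set arithmetic, exhaustive
# enumeration, all-pairs counting) and independent of the implementation
# paths they check.

# Per-base representation of a set of 0-based half-open intervals.
bases_of <- function(df) {
  if (nrow(df) == 0) return(integer())
  unique(unlist(Map(function(s, e) seq.int(s, e - 1L), df$start, df$end)))
}

# Per-base overlap width between two interval sets on one chromosome.
oracle_overlap_bases <- function(a, b) {
  length(intersect(bases_of(a), bases_of(b)))
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# point probabilities not exceeding the observed one (standard epsilon
# for floating-point ties).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All-pairs AUC with half-credit ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Gene tibble from a list of exon tibbles (0-based half-open).
make_genes <- function(exon_list, chrom = "chr1", strand = "+") {
  if (is.null(names(exon_list))) {
    names(exon_list) <- sprintf("g%d", seq_along(exon_list))
  }
  purrr::imap_dfr(exon_list, function(ex, nm) {
    un <- retrotx:::interval_union(ex$start, ex$end)
    tibble::tibble(
      gene_id = nm,
      chrom = chrom, strand = strand,
      start = min(un$start), end = max(un$end),
      exons = list(un),
      introns = list(retrotx::derive_introns(un)))
  })
}

make_contig <- function(id, blocks, chrom = "chr1", strand = "+") {
  tibble::tibble(transcript_id = id, chrom = chrom, strand = strand,
                 start = min(blocks$start), end = max(blocks$end),
                 blocks = list(blocks))
}

make_repeats <- function(starts, ends, subfamily = "AluSx", family = "Alu",
                         rte_class = "SINE", chrom = "chr1", strand = "+") {
  tibble::tibble(repeat_id = sprintf("r%03d", seq_along(starts)),
                 chrom = chrom, start = starts, end = ends, strand = strand,
                 subfamily = subfamily, family = family, rte_class = rte_class)
}

# Random annotation pieces for property tests.
random_intervals <- function(n, max_pos = 5000, max_len = 200) {
  s <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(start = s, end = s + sample.int(max_len, n, replace = TRUE))
}

# Wide expression tibble from a matrix.
expr_tbl <- function(m) tibble::as_tibble(m, rownames = "feature_id")

# One cached default simulation shared by read-only tests.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- retrotx::simulate_dataset(retrotx::sim_config(seed = 42))
    cache
  }
})
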