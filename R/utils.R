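# Shared internal helpers: validation, coordinate conversion, seeds.

# Abort with a consistent class so tests can target retrotx errors.
stop_retrotx <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "retrotx_error")
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_retrotx("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  }
  invisible(df)
}

# 0-based half-open tibble -> GRanges (1-based closed). `strand` optional.
as_granges0 <- function(df, strand = NULL) {
  s <- if (is.null(strand)) "*" else ifelse(strand %in% c("+", "-"), strand, "*")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = s
  )
}

# Deterministic sub-seed derivation: component streams stay stable when
# other components change size. Kept below 2^31 - 1.
derive_seed <- function(master, component) {
  stopifnot(is.numeric(master), length(master) == 1)
  offs <- c(annotation = 11L, sequence = 23L, expression = 37L,
            survival = 53L, drivers = 71L, theta = 89L)
  k <- offs[[component]]
  as.integer((abs(master) * 97L + k * 1009L) %% 2147483399)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# log2 with the pseudocount used throughout the expression statistics.
log2p <- function(x, pseudo = 0.1) log2(x + pseudo)

# Expression tibbles are wide: feature_id + one column per sample.
expr_matrix <- function(expr) {
  assert_columns(expr, "feature_id", "expression table")
  if (anyDuplicated(expr$feature_id)) {
    stop_retrotx("duplicate feature_id values in expression table")
  }
  m <- as.matrix(expr[setdiff(names(expr), "feature_id")])
  if (any(m < 0, na.rm = TRUE)) stop_retrotx("negative expression values")
  rownames(m) <- expr$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_expr <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

# Row-wise mean/variance without loops.
row_means <- function(m) rowMeans(m)
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

# Welch two-sample t-test, vectorised over matrix rows (log scale upstream).
# Returns tibble(diff, t, df, p). Zero variance in both groups -> p = 1 when
# means equal; p = 0 when they differ (a degenerate, perfectly separated case).
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- row_means(a); mb <- row_means(b)
  va <- row_vars(a); vb <- row_vars(b)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zerovar <- va + vb == 0
  p[zerovar & ma == mb] <- 1
  t[zerovar & ma == mb] <- 0
  p[zerovar & ma != mb] <- 0
  tibble::tibble(diff = unname(ma - mb), statistic = unname(t),
                 df = unname(df), p = unname(p),
                 zero_variance = unname(zerovar))
}

# Benjamini-Hochberg wrapper (explicit name at call sites).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

first_tiebreak_order <- function(values, ids) order(values, ids)
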