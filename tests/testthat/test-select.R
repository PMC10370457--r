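# Complexity metric, overexpression selection, differential expression,
# Fisher enrichment, copy-number bias.

sel_meta <- function(n_c = 6, n_h = 6) {
  tibble::tibble(
    sample_id = c(sprintf("c%02d", 1:n_c), sprintf("h%02d", 1:n_h)),
    cohort = "x",
    condition = rep(c("EAC", "esophagus"), c(n_c, n_h)),
    matched_tissue = rep(c("esophagus", NA), c(n_c, n_h)))
}

test_that("transcriptome complexity counts features at the inclusive floor", {
  m <- rbind(f1 = c(0, 0.5), f2 = c(0, 0.49), f3 = c(0, 3))
  colnames(m) <- c("s1", "s2")
  cx <- transcriptome_complexity(expr_tbl(m))
  expect_equal(cx$n_expressed, c(0, 2))  # 0.5 itself counts, 0.49 does not
})

test_that("selection keeps silent-in-healthy, expressed-in-cancer features", {
  meta <- sel_meta()
  m <- rbind(
    good = c(rep(1.0, 6), rep(0, 6)),       # median 1, healthy 0 -> selected
    low = c(rep(0.4, 6), rep(0, 6)),        # cancer median below 0.5 -> rejected
    leaky = c(rep(5, 6), rep(2, 6)))        # healthy high -> rejected
  colnames(m) <- meta$sample_id
  sel <- select_overexpressed(expr_tbl(m), meta, "EAC")
  got <- stats::setNames(sel$selected, sel$feature_id)
  expect_true(got[["good"]])
  expect_false(got[["low"]])
  expect_false(got[["leaky"]])
})

test_that("the 3x fold gate compares the healthy reference to the cancer percentile", {
  meta <- sel_meta()
  # healthy constant 0.2 -> H = 0.2 (both percentile and median)
  mk <- function(q75c) {
    # constant cancer value -> both median and q75 equal that value
    m <- rbind(f = c(rep(q75c, 6), rep(0.2, 6)))
    colnames(m) <- meta$sample_id
    expr_tbl(m)
  }
  sel1 <- select_overexpressed(mk(0.5), meta, "EAC")
  expect_false(sel1$selected)  # 3 * 0.2 = 0.6 > 0.5
  sel2 <- select_overexpressed(mk(0.7), meta, "EAC")
  expect_true(sel2$selected)   # 3 * 0.2 = 0.6 <= 0.7 and H < 0.5
  # direct arithmetic oracle on sorted percentiles for a ragged case
  set.seed(2)
  cv <- round(runif(6, 0, 4), 2); hv <- round(runif(6, 0, 0.4), 2)
  m <- rbind(f = c(cv, hv)); colnames(m) <- meta$sample_id
  sel3 <- select_overexpressed(expr_tbl(m), meta, "EAC")
  q75 <- unname(quantile(cv, 0.75)); h <- max(quantile(hv, 0.9), median(hv))
  expect_equal(sel3$cancer_q, q75)
  expect_equal(sel3$healthy_ref, h)
  expect_equal(sel3$selected,
               median(cv) > 0.5 && 3 * h <= q75 && h < 0.5)
})

test_that("selection errors without a matched healthy tissue", {
  meta <- sel_meta()
  meta$matched_tissue[meta$condition == "EAC"] <- NA
  m <- rbind(f = rep(1, 12)); colnames(m) <- meta$sample_id
  expect_error(select_overexpressed(expr_tbl(m), meta, "EAC"),
               "matched healthy tissue")
})

test_that("selection is monotone under cancer raises and healthy lowers", {
  set.seed(31)
  meta <- sel_meta(8, 8)
  m <- matrix(2^rnorm(30 * 16, 0, 2), 30, 16,
              dimnames = list(sprintf("f%02d", 1:30), meta$sample_id))
  base_sel <- select_overexpressed(expr_tbl(m), meta, "EAC")
  base_ids <- selected_features(base_sel)
  cancer_cols <- which(meta$condition == "EAC")
  healthy_cols <- which(meta$condition != "EAC")
  for (i in 1:60) {
    m2 <- m
    # raise a random cancer entry and lower a random healthy entry
    m2[sample(30, 1), sample(cancer_cols, 1)] <- 2^rnorm(1, 4, 1)
    m2[sample(30, 1), sample(healthy_cols, 1)] <- 0
    new_ids <- selected_features(select_overexpressed(expr_tbl(m2), meta, "EAC"))
    expect_true(all(base_ids %in% new_ids))
    m <- m2  # compound the perturbations
    base_ids <- new_ids
  }
})

test_that("differential expression gates are strict and the Welch test is sound", {
  set.seed(41)
  a_ids <- sprintf("a%02d", 1:10); b_ids <- sprintf("b%02d", 1:10)
  # identical group distributions: zero passes
  m <- matrix(2^rnorm(50 * 20, 2, 0.5), 50, 20,
              dimnames = list(sprintf("f%02d", 1:50), c(a_ids, b_ids)))
  de <- differential_repeat_expression(expr_tbl(m), a_ids, b_ids)
  expect_equal(sum(de$pass), 0)
  # a fold of exactly 6 fails the strict gate
  m2 <- rbind(fold6 = c(rep((6 * (1 + 0.1)) - 0.1, 10), rep(1, 10)),
              ctrl = c(rep(1, 10), rep(1, 10)))
  colnames(m2) <- c(a_ids, b_ids)
  de2 <- differential_repeat_expression(expr_tbl(m2), a_ids, b_ids)
  expect_equal(de2$fold[de2$feature_id == "fold6"], 6, tolerance = 1e-12)
  expect_false(de2$pass[de2$feature_id == "fold6"])
  expect_true(de2$zero_variance[de2$feature_id == "ctrl"])
  expect_equal(de2$p[de2$feature_id == "ctrl"], 1)
})

test_that("a planted 8-fold shift at n=20/20 is detected (Monte-Carlo)", {
  set.seed(51)
  a_ids <- sprintf("a%02d", 1:20); b_ids <- sprintf("b%02d", 1:20)
  hits <- 0
  for (r in 1:50) {
    m <- matrix(2^rnorm(40 * 40, 1, 0.3), 40, 40,
                dimnames = list(sprintf("f%02d", 1:40), c(a_ids, b_ids)))
    m["f01", a_ids] <- 2^rnorm(20, 4, 0.3)  # 8-fold shift
    de <- differential_repeat_expression(expr_tbl(m), a_ids, b_ids)
    hits <- hits + de$pass[de$feature_id == "f01"]
  }
  expect_gte(hits / 50, 0.99)
})

test_that("Fisher enrichment matches the exhaustive hypergeometric oracle", {
  memb <- tibble::tibble(
    transcript_id = c(sprintf("s%02d", 1:8), sprintf("bg%02d", 1:10)),
    subfamily = "AluY")
  selected <- c(sprintf("s%02d", 1:8), sprintf("x%02d", 1:2))
  background <- c(selected, sprintf("bg%02d", 1:10), sprintf("y%02d", 1:90))
  enr <- subfamily_enrichment(selected, background, memb)
  expect_equal(enr$a, 8); expect_equal(enr$b, 2)
  expect_equal(enr$c, 10); expect_equal(enr$d, 90)
  expect_equal(enr$p, oracle_fisher_p(8, 2, 10, 90), tolerance = 1e-12)
  # equal proportions: OR 1, p 1
  memb2 <- tibble::tibble(transcript_id = c("s01", "bg01"), subfamily = "L1HS")
  enr2 <- subfamily_enrichment(c("s01", "s02"), c("s01", "s02", "bg01", "bg02"),
                               memb2)
  expect_equal(enr2$odds_ratio, 1)
  expect_equal(enr2$p, 1)
  # depletion: subfamily only outside the selection
  memb3 <- tibble::tibble(transcript_id = c("bg01", "bg02"), subfamily = "MIR")
  enr3 <- subfamily_enrichment(c("s01", "s02"), c("s01", "s02", "bg01", "bg02"),
                               memb3)
  expect_lt(enr3$odds_ratio, 1)
})

test_that("BH q-values are monotone in sorted p order and bounded by 1", {
  set.seed(61)
  p <- runif(200)^2
  q <- retrotx:::bh_adjust(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q <= 1 & q >= p - 1e-12))
})

test_that("copy-number bias is the Spearman rho of copies vs log OR", {
  enr <- tibble::tibble(subfamily = sprintf("s%d", 1:5),
                        odds_ratio = c(1.2, 2.5, 4, 8, 16))
  cn <- tibble::tibble(subfamily = sprintf("s%d", 1:5),
                       copies = c(10, 20, 40, 80, 160))
  cb <- copy_number_bias(enr, cn)
  expect_equal(cb$rho, 1)
  # hand-sized 5-point table against the rank formula
  cn2 <- tibble::tibble(subfamily = sprintf("s%d", 1:5),
                        copies = c(50, 10, 80, 20, 40))
  cb2 <- copy_number_bias(enr, cn2)
  rx <- rank(cn2$copies); ry <- rank(log(enr$odds_ratio))
  rho_hand <- 1 - 6 * sum((rx - ry)^2) / (5 * (5^2 - 1))
  expect_equal(cb2$rho, rho_hand)
  expect_error(copy_number_bias(enr[1:2, ], cn[1:2, ]), ">= 3 subfamilies")
  enr_const <- dplyr::mutate(enr, odds_ratio = 2)
  expect_error(copy_number_bias(enr_const, cn), "undefined correlation")
})

test_that("planted overexpression is recovered perfectly on synthetic data", {
  sim <- default_sim()
  sel <- select_overexpressed(sim$expr, sim$meta, "EAC")
  hits <- selected_features(sel)
  planted <- sim$truth$overexpressed
  prov <- sim$truth$proviruses$provirus
  expect_equal(mean(planted %in% hits), 1)  # sensitivity
  # no false positives outside the planted cancer-specific features
  # (proviruses are cancer-specific by construction)
  expect_length(setdiff(hits, c(planted, prov)), 0)
})

test_that("an empty feature set yields an empty selection result", {
  meta <- sel_meta()
  empty <- tibble::tibble(feature_id = character())
  for (s in meta$sample_id) empty[[s]] <- double()
  sel <- select_overexpressed(empty, meta, "EAC")
  expect_s3_class(sel, "rte_selection")
  expect_equal(nrow(sel), 0)
})
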