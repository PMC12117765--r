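# The statistical core: hypergeometric and chi-squared tests, p-value
# adjustment, the enrich() driver, and GO redundancy reduction.

test_that("hypergeometric tail matches closed forms", {
  expect_identical(hypergeometric_pvalue(0, 3, 5, 10), 1)
  expect_equal(hypergeometric_pvalue(2, 6, 2, 6), 1) # K = N degenerate
  expect_equal(hypergeometric_pvalue(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_error(hypergeometric_pvalue(3, 2, 3, 4), "invalid")
  expect_error(hypergeometric_pvalue(-1, 2, 3, 4), "non-negative")
})

test_that("hypergeometric tail is non-increasing in k and matches enumeration", {
  for (N in c(8L, 10L)) {
    for (n in c(3L, 5L)) {
      for (K in c(2L, 4L, N)) {
        ks <- 0:min(K, n)
        ps <- hypergeometric_pvalue(ks, K, n, N)
        expect_true(all(diff(ps) <= 1e-12))
        for (k in ks) {
          expect_equal(
            hypergeometric_pvalue(k, K, n, N),
            enum_hyper_tail(k, K, n, N),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("chi-squared test handles independence and degeneracy", {
  expect_equal(chisquared_pvalue(5, 10, 10, 20), 1)
  expect_warning(p <- chisquared_pvalue(4, 4, 4, 4), "degenerate")
  expect_identical(p, 1)
  # classical uncorrected statistic on a hand-picked table
  k <- 8L; n <- 10L; K <- 10L; N <- 40L
  a <- k; b <- n - k; c_ <- K - k; d <- (N - K) - (n - k)
  stat <- N * (abs(a * d - b * c_))^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(
    chisquared_pvalue(k, K, n, N, correct = FALSE),
    stats::pchisq(stat, df = 1, lower.tail = FALSE),
    tolerance = 1e-12
  )
})

test_that("p-value adjustment follows the classical definitions", {
  expect_equal(adjust_pvalues(c(0.3, 0.01), method = "none"), c(0.3, 0.01))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), method = "BH"),
    c(0.03, 0.03, 0.03)
  )
  expect_equal(adjust_pvalues(c(0.02, 0.5), method = "bonferroni"), c(0.04, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # single test: BH equals bonferroni equals identity
  expect_equal(adjust_pvalues(0.037, "BH"), adjust_pvalues(0.037, "bonferroni"))
  # BH preserves the order of sorted inputs and stays in [0, 1]
  withr::local_seed(5)
  p <- sort(runif(50))
  q <- adjust_pvalues(p, "BH")
  expect_true(all(diff(q) >= 0) && all(q >= p - 1e-15) && all(q <= 1))
})

toy_model <- function() {
  # 30-protein background; category "c1" holds exactly b01..b03
  enrichment_model("kog_letter", tibble::tibble(
    category_id = c("c1", "c2"),
    label = c("c1", "c2"),
    group = c("g", "g"),
    proteins = list(
      sprintf("b%02d", 1:3),
      sprintf("b%02d", 4:30)
    )
  ))
}

test_that("enrich computes counts, ratio, and the closed-form p-value", {
  model <- toy_model()
  report <- enrich(model, sprintf("b%02d", 1:3))
  row <- report$results[report$results$category_id == "c1", ]
  expect_equal(row$k, 3L)
  expect_equal(row$K, 3L)
  expect_equal(row$n, 3L)
  expect_equal(row$N, 30L)
  expect_equal(row$p_value, 1 / choose(30, 3), tolerance = 1e-12)
  expect_equal(row$ratio, (3 / 3) / (3 / 30))
})

test_that("a saturating query drives every ratio and p-value to 1", {
  model <- toy_model()
  report <- enrich(model, model$background)
  expect_true(all(report$results$ratio == 1))
  expect_true(all(report$results$p_value == 1))
  expect_true(all(report$results$k == report$results$K))
})

test_that("enrich keeps mapping bookkeeping and handles unmappable queries", {
  model <- toy_model()
  report <- enrich(model, c("ghost1", "ghost2", "b01"))
  expect_equal(report$n_input, 3L)
  expect_equal(report$n_mapped, 1L)
  expect_setequal(report$dropped_ids, c("ghost1", "ghost2"))
  expect_equal(report$n_input, report$n_mapped + length(report$dropped_ids))

  expect_warning(empty <- enrich(model, c("x", "y")), "no query ids")
  expect_equal(nrow(empty$results), 0L)
  expect_equal(empty$n_mapped, 0L)
})

test_that("correction spans all model categories, not only observed ones", {
  # query hits only c1; m = 2 categories, so BH multiplies the best p by 2/1
  model <- toy_model()
  report <- enrich(model, sprintf("b%02d", 1:3))
  row <- report$results[report$results$category_id == "c1", ]
  expect_equal(row$p_adjusted, min(1, row$p_value * 2), tolerance = 1e-12)
})

test_that("results are sorted by adjusted p then category id", {
  model <- toy_model()
  report <- enrich(model, c(sprintf("b%02d", 1:3), "b04"))
  res <- report$results
  expect_true(!is.unsorted(res$p_adjusted))
  ties <- split(res$category_id, res$p_adjusted)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

sig_report <- function(ids, padj, p = padj / 2, model_kind = "go_bp") {
  structure(
    list(
      results = tibble::tibble(
        category_id = ids, label = ids, group = "biological_process",
        k = 2L, K = 4L, n = 10L, N = 100L, ratio = 5,
        p_value = p, p_adjusted = padj,
        query_hits = replicate(length(ids), c("p1", "p2"), simplify = FALSE)
      ),
      n_input = 10L, n_mapped = 10L, dropped_ids = character(),
      model_kind = model_kind, test = "hypergeometric", correction = "BH"
    ),
    class = "enrichment_report"
  )
}

test_that("redundancy reduction keeps the best representative per block", {
  sib <- make_dag(tibble::tibble(child = c("t1", "t2"), parent = c("P", "P")))
  rep2 <- sig_report(c("t1", "t2"), c(0.01, 0.02))
  out <- reduce_go_redundancy(rep2, sib, depth_limit = 1, alpha = 0.05)
  expect_equal(out$results$category_id, "t1")
  expect_equal(out$results$p_adjusted, 0.01) # not recomputed

  # depth 0: only identical terms group, all significant rows survive
  out0 <- reduce_go_redundancy(rep2, sib, depth_limit = 0, alpha = 0.05)
  expect_setequal(out0$results$category_id, c("t1", "t2"))
})

test_that("redundancy reduction drops non-significant rows and splits components", {
  dag <- make_dag(tibble::tibble(
    child = c("t1", "t2", "t3", "P", "Q"),
    parent = c("P", "P", "Q", "R", "R")
  ))
  rep3 <- sig_report(c("t1", "t2", "t3"), c(0.01, 0.02, 0.03))
  out <- reduce_go_redundancy(rep3, dag, depth_limit = 1, alpha = 0.05)
  expect_setequal(out$results$category_id, c("t1", "t3"))

  mixed <- sig_report(c("t1", "t2", "t3"), c(0.01, 0.2, 0.03))
  out2 <- reduce_go_redundancy(mixed, dag, depth_limit = 1, alpha = 0.05)
  expect_setequal(out2$results$category_id, c("t1", "t3"))

  none <- reduce_go_redundancy(
    sig_report("t1", 0.5), dag,
    depth_limit = 1, alpha = 0.05
  )
  expect_equal(nrow(none$results), 0L)
})

test_that("ties in adjusted p resolve by raw p then lexicographic id", {
  sib <- make_dag(tibble::tibble(child = c("t1", "t2"), parent = c("P", "P")))
  tied <- sig_report(c("t1", "t2"), c(0.02, 0.02), p = c(0.015, 0.01))
  out <- reduce_go_redundancy(tied, sib, depth_limit = 1, alpha = 0.05)
  expect_equal(out$results$category_id, "t2")

  fully_tied <- sig_report(c("t2", "t1"), c(0.02, 0.02), p = c(0.01, 0.01))
  out2 <- reduce_go_redundancy(fully_tied, sib, depth_limit = 1, alpha = 0.05)
  expect_equal(out2$results$category_id, "t1")
})

test_that("report serialization round-trips results and bookkeeping", {
  model <- toy_model()
  report <- enrich(model, c(sprintf("b%02d", 1:3), "ghost"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_report(report, path)
  back <- read_enrichment_report(path)
  expect_equal(back$results$category_id, report$results$category_id)
  expect_equal(back$results$k, report$results$k)
  expect_equal(back$results$p_adjusted, report$results$p_adjusted,
    tolerance = 1e-5
  )
  expect_equal(back$results$query_hits, report$results$query_hits)
  expect_equal(back$n_input, report$n_input)
  expect_equal(back$dropped_ids, "ghost")
})
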