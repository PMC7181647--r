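test_that("hit probability matches closed forms and stays stable", {
  expect_equal(hit_probability(0.5, 2), 0.75)
  expect_equal(hit_probability(0, 1000), 0)
  # frozen 60-digit arithmetic reference for 1 - (1 - 1e-4)^1000
  expect_equal(hit_probability(1e-4, 1000),
               0.0951671064414537449608702688810508, tolerance = 1e-15)
  expect_error(hit_probability(1, 10), "\\[0, 1\\)")
  expect_error(hit_probability(0.1, 0), "width")
})

test_that("Poisson-binomial pmf matches enumeration and binomial forms", {
  expect_equal(pbd_pmf(c(0.1, 0.2)), c(0.72, 0.26, 0.02))
  expect_equal(pbd_pmf(rep(0, 5)), c(1, rep(0, 5)))
  for (p in c(0.01, 0.3, 0.77)) {
    expect_equal(pbd_pmf(rep(p, 12)), dbinom(0:12, 12, p),
                 tolerance = 1e-12)
  }
  set.seed(17)
  for (i in 1:10) {
    probs <- runif(sample(2:10, 1))
    probs[probs >= 1] <- 0.99
    expect_equal(pbd_pmf(probs), enum_pbd_pmf(probs), tolerance = 1e-12)
    expect_equal(sum(pbd_pmf(probs)), 1, tolerance = 1e-12)
  }
  expect_error(pbd_pmf(c(0.5, 1)), "\\[0, 1\\)")
  expect_error(pbd_pmf(numeric(0)), "at least one")
})

test_that("Poisson-binomial tail is exact, monotone and bounded", {
  expect_equal(pbd_tail(c(0.5, 0.5), 1), 0.75)
  expect_equal(pbd_tail(c(0.3, 0.9, 0.2), 0), 1)
  expect_equal(pbd_tail(c(0.1, 0.2, 0.3), 2), 0.098, tolerance = 1e-12)
  expect_error(pbd_tail(c(0.1, 0.2), 3), "out of range")
  set.seed(23)
  probs <- runif(8, 0, 0.9)
  tails <- vapply(0:8, function(s) pbd_tail(probs, s), numeric(1))
  expect_true(all(diff(tails) <= 1e-15))       # non-increasing in s
  # constant-p tail equals the binomial survival function
  expect_equal(vapply(0:8, function(s) pbd_tail(rep(0.4, 8), s),
                      numeric(1)),
               c(1, pbinom(0:7, 8, 0.4, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  # independent hand implementation of the step-up rule
  step_up <- function(p) {
    m <- length(p); o <- order(p)
    q <- pmin(1, cummin(rev(p[o] * m / seq_len(m)))[m:1])
    q[order(o)]
  }
  set.seed(9)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("background rates are the exact count/coverage ratio", {
  cov <- covered_regions(regulatory_set("chr1", 0, 1e6))
  counts <- data.frame(sample_id = c("A", "B", "C"), n_k = c(100, 0, 7))
  rates <- background_rates(counts, cov)
  expect_equal(rates$p_k, c(1e-4, 0, 7e-6))
  expect_equal(mean(rates$p_k) * 3, sum(counts$n_k) / cov$n_cov)
  expect_error(background_rates(data.frame(sample_id = "A", n_k = 2e6),
                                cov), "rate")
})

test_that("covered regions merge overlaps before summing", {
  res <- regulatory_set("chr1", c(0, 50, 200), c(100, 150, 300))
  cov <- covered_regions(res)
  expect_equal(cov$n_cov, 150 + 100)
  expect_equal(nrow(cov$intervals), 2L)
})

test_that("RE burden handles never-mutated and fully-mutated elements", {
  res <- regulatory_set("chr1", c(0, 1000), c(500, 1800), c("E1", "E2"))
  rates <- data.frame(sample_id = c("S1", "S2", "S3"), n_k = c(5, 9, 2),
                      p_k = c(5e-4, 9e-4, 2e-4))
  snvs <- data.frame(sample_id = c("S1", "S2", "S3"), chrom = "chr1",
                     pos = c(10, 20, 499), ref = "A", alt = "C")
  mm <- build_mutation_matrix(snvs, res, samples = rates$sample_id)
  b <- re_burden(mm, rates, res)
  never <- b[b$unit_id == "E2", ]
  expect_equal(never$p_value, 1)
  expect_false(never$fmre)
  # s = n closed form: P(all samples hit) = prod of hit probabilities
  all3 <- b[b$unit_id == "E1", ]
  expect_equal(all3$s, 3L)
  expect_equal(all3$p_value, prod(hit_probability(rates$p_k, 500)),
               tolerance = 1e-12)
  expect_error(re_burden(mm, rates[1:2, ], res), "without background")
})

test_that("enlarging an element never shrinks its hit probabilities", {
  p_k <- c(1e-4, 5e-4, 2e-3)
  expect_true(all(diff(sapply(c(100, 500, 1000, 5000),
                              function(w) hit_probability(p_k, w))[1, ])
                  > 0))
  # with s fixed, a wider element yields a larger (more conservative) tail?
  # No: wider exposure means MORE expected hits, so the same s is less
  # surprising -> p-value must not decrease.
  s <- 2
  tails <- vapply(c(100, 1000, 10000), function(w)
    pbd_tail(hit_probability(p_k, w), s), numeric(1))
  expect_true(all(diff(tails) >= -1e-15))
})

test_that("CREAG burden reduces to RE burden and counts samples once", {
  res <- regulatory_set("chr1", c(0, 1000, 3000), c(100, 1200, 3300),
                        c("E1", "E2", "E3"))
  rates <- data.frame(sample_id = paste0("S", 1:4), n_k = rep(3, 4),
                      p_k = rep(3e-4, 4))
  snvs <- data.frame(sample_id = c("S1", "S1", "S2"), chrom = "chr1",
                     pos = c(50, 1100, 1150), ref = "G", alt = "T")
  mm <- build_mutation_matrix(snvs, res, samples = rates$sample_id)

  one <- data.frame(gene_id = "G1", n_res = 1L, n_j = 100)
  one$re_ids <- list("E1")
  cb <- creag_burden(mm, rates, one)
  rb <- re_burden(mm, rates, res)
  expect_equal(cb$p_value, rb$p_value[rb$unit_id == "E1"])
  expect_equal(cb$s, rb$s[rb$unit_id == "E1"])

  both <- data.frame(gene_id = "G2", n_res = 2L, n_j = 100 + 200)
  both$re_ids <- list(c("E1", "E2"))
  cb2 <- creag_burden(mm, rates, both)
  # S1 mutated in E1 and E2 counts once; union oracle by brute force
  brute_s <- sum(vapply(rates$sample_id, function(smp)
    any(snvs$sample_id == smp &
          ((snvs$pos >= 0 & snvs$pos < 100) |
             (snvs$pos >= 1000 & snvs$pos < 1200))), logical(1)))
  expect_equal(cb2$s, as.integer(brute_s))
  expect_equal(cb2$n, 300)
  empty <- data.frame(gene_id = "G3", n_res = 0L, n_j = 0)
  empty$re_ids <- list(character(0))
  expect_error(creag_burden(mm, rates, empty), "member")
})

test_that("without rate elevation, labelled REs are indistinguishable", {
  # no hot REs: an arbitrary 'hot' labelling must show the same burden
  # p-value distribution as the rest
  b <- cohort_burden(simulate_cohort(cohort_config(seed = 314)))
  lab <- b$unit_id %in% paste0("RE_", 1:25)
  ks <- suppressWarnings(stats::ks.test(b$p_value[lab], b$p_value[!lab]))
  expect_gt(ks$p.value, 0.01)
})

test_that("QQ columns rank the burden table by significance", {
  b <- data.frame(unit_id = c("a", "b", "c"), s = c(1L, 0L, 2L),
                  n = c(100, 100, 100), p_value = c(0.5, 1, 0.01),
                  q_value = c(0.75, 1, 0.03), fmre = c(FALSE, FALSE, TRUE))
  qq <- burden_qq(b)
  expect_equal(qq$unit_id, c("c", "a", "b"))
  expect_equal(qq$neglog10_expected, -log10((1:3) / 4))
  expect_equal(qq$neglog10_observed, -log10(c(0.01, 0.5, 1)))
})
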