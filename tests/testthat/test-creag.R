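test_that("Spearman rho hits the monotone extremes", {
  up <- spearman_one_sided(1:5, c(2, 4, 6, 8, 10))
  expect_equal(up$rho, 1)
  down <- spearman_one_sided(1:5, c(10, 8, 6, 4, 2))
  expect_equal(down$rho, -1)
  expect_gt(down$p_one_sided, 0.95)   # one-sided: negative pairs rejected
  expect_error(spearman_one_sided(1:3, 1:3), "at least 4")
  expect_error(spearman_one_sided(rep(1, 5), 1:5), "constant")
})

test_that("exact permutation p agrees with the AS89 exact null at n = 7", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- spearman_one_sided(x, y)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", alternative = "greater",
               exact = TRUE))
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p_one_sided, ref$p.value, tolerance = 0.02)
  }
})

test_that("t approximation is close to Monte-Carlo permutation at n = 12", {
  set.seed(13)
  x <- rnorm(12); y <- x * 0.5 + rnorm(12)
  mine <- spearman_one_sided(x, y)
  rx <- rank(x); ry <- rank(y)
  mc <- mean(replicate(20000, cor(rx, sample(ry))) >= mine$rho - 1e-12)
  expect_lt(abs(mine$p_one_sided - mc), 0.02)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- runif(15); y <- runif(15)
  base <- spearman_one_sided(x, y)
  tr <- spearman_one_sided(exp(3 * x), log(y + 1))
  expect_equal(tr$rho, base$rho)
  expect_equal(tr$p_one_sided, base$p_one_sided)
})

# deterministic mini-cosmos: 1 chromosome, 2 TADs, hand-placed features
mini_layout <- function() {
  tads <- regulatory_set("chr1", c(0, 1e6), c(1e6, 2e6), c("T1", "T2"),
                         element_class = "tad")
  genes <- regulatory_set("chr1", c(1e5, 1.2e6), c(1.01e5, 1.201e6),
                          c("GA", "GB"), element_class = "gene")
  res <- regulatory_set("chr1", c(2e5, 3e5, 1.5e6), c(2.01e5, 3.01e5, 1.501e6),
                        c("R1", "R2", "R3"))
  list(tads = tads, genes = genes, res = res)
}

test_that("association gates enforce TAD, distance and correlation rules", {
  lay <- mini_layout()
  set.seed(41)
  n <- 12
  f <- rnorm(n)
  re_signal <- signal_matrix(rbind(
    R1 = exp(f),                       # tracks GA
    R2 = exp(rnorm(n)),                # noise
    R3 = exp(f)),                      # tracks GA but in the other TAD
    col_ids = paste0("S", 1:n))
  gene_expr <- signal_matrix(rbind(
    GA = exp(f + 0.05 * rnorm(n)),
    GB = exp(rnorm(n))),
    col_ids = paste0("S", 1:n))
  out <- build_creags(lay$res, re_signal, lay$genes, gene_expr, lay$tads)
  expect_true(all(c("R1") %in% out$associations$re_id))
  # R3 correlates with GA (rho ~ 1) but sits in TAD T2: must be rejected
  expect_false("R3" %in% out$associations$re_id)
  expect_true(all(out$associations$rho > 0.4))
  expect_true(all(out$associations$p_one_sided < 0.05))
  expect_true(all(out$associations$distance < 5e5))
  # independent validator pass over every retained record
  for (i in seq_len(nrow(out$associations))) {
    a <- out$associations[i, ]
    r <- lay$res[lay$res$name == a$re_id, ]
    g <- lay$genes[lay$genes$name == a$gene_id, ]
    mid <- interval_midpoint(r)
    expect_lt(abs(mid - g$start), 5e5)
    tad <- lay$tads[lay$tads$name == a$tad_id, ]
    expect_true(mid >= tad$start && mid < tad$end)
    expect_true(g$start >= tad$start && g$start < tad$end)
  }
})

test_that("distance gate: a same-TAD pair beyond 500 kb is dropped", {
  tads <- regulatory_set("chr1", 0, 2e6, "T1", element_class = "tad")
  genes <- regulatory_set("chr1", 0, 1000, "GA", element_class = "gene")
  res <- regulatory_set("chr1", c(1e5, 1.8e6), c(1.01e5, 1.801e6),
                        c("NEAR", "FAR"))
  set.seed(6)
  f <- rnorm(10)
  re_signal <- signal_matrix(rbind(NEAR = exp(f), FAR = exp(f)),
                             col_ids = paste0("S", 1:10))
  gene_expr <- signal_matrix(rbind(GA = exp(f)),
                             col_ids = paste0("S", 1:10))
  out <- build_creags(res, re_signal, genes, gene_expr, tads)
  expect_equal(out$associations$re_id, "NEAR")
})

test_that("raising any threshold never enlarges the retained set", {
  cfg <- tiny_config(n_res = 30)
  co <- simulate_cohort(cfg)
  base <- build_creags(co$layout$res, co$re_signal, co$layout$genes,
                       co$gene_expr, co$layout$tads)
  key <- function(a) paste(a$re_id, a$gene_id)
  for (args in list(list(rho_min = 0.6), list(p_max = 0.01),
                    list(max_distance = 1e5))) {
    stricter <- do.call(build_creags, c(
      list(co$layout$res, co$re_signal, co$layout$genes, co$gene_expr,
           co$layout$tads), args))
    expect_true(all(key(stricter$associations) %in%
                      key(base$associations)))
  }
})

test_that("pseudo-RE width sums member widths, with a merge option", {
  assoc <- data.frame(re_id = c("R1", "R2"), gene_id = "GA",
                      rho = 0.9, p_one_sided = 0.01, distance = 1000,
                      tad_id = "T1")
  res <- regulatory_set("chr1", c(100, 150), c(200, 260), c("R1", "R2"))
  plain <- reburden:::creags_from_associations(assoc, res)
  expect_equal(plain$n_j, 100 + 110)
  merged <- reburden:::creags_from_associations(assoc, res,
                                                merge_overlaps = TRUE)
  expect_equal(merged$n_j, 160)    # [100,260) after union
  prom <- regulatory_set("chr1", 1000, 1500, "GA",
                         element_class = "promoter")
  with_prom <- reburden:::creags_from_associations(assoc, res, prom)
  expect_equal(with_prom$n_j, 210 + 500)
})

test_that("CREAG summary reproduces hand counts", {
  assoc <- data.frame(
    re_id = c("R1", "R2", "R3", "R4", "R1"),
    gene_id = c("GA", "GA", "GA", "GA", "GB"),
    rho = 0.9, p_one_sided = 0.01, distance = 1, tad_id = "T1")
  res <- regulatory_set("chr1", seq(0, 300, 100), seq(50, 350, 100),
                        paste0("R", 1:4))
  creags <- reburden:::creags_from_associations(assoc, res)
  s <- creag_summary(creags, assoc)
  expect_equal(s$n_associations, 5)
  expect_equal(s$n_genes, 2)
  expect_equal(s$n_res, 4)
  expect_equal(s$median_res_per_creag, 2.5)   # median of {1, 4}
  expect_equal(s$mean_genes_per_re, mean(c(2, 1, 1, 1)))
  one <- assoc[1, ]
  s1 <- creag_summary(reburden:::creags_from_associations(one, res), one)
  expect_equal(unlist(s1[c("n_associations", "n_genes", "n_res")]),
               c(n_associations = 1, n_genes = 1, n_res = 1))
})
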