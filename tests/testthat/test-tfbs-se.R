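test_that("active sites are those overlapping at least one peak", {
  tfbs <- regulatory_set("chr1", c(0, 100, 200), c(10, 110, 210),
                         paste0("B", 1:3), element_class = "tfbs")
  peaks <- regulatory_set("chr1", 105, 150)
  act <- active_sites(tfbs, peaks)
  expect_equal(act$name, "B2")
  none <- active_sites(tfbs, regulatory_set(character(0), numeric(0),
                                            numeric(0)))
  expect_equal(nrow(none), 0L)
  set.seed(55)
  a <- random_set(80); b <- random_set(40)
  expect_equal(active_sites(a, b)$name,
               a$name[sort(unique(brute_overlaps(a, b)$query))])
})

tf_rates <- function(p) data.frame(sample_id = paste0("S", seq_along(p)),
                                   n_k = NA, p_k = p)

test_that("enrichment expectation matches per-site brute force", {
  set.seed(66)
  sites <- random_set(50, max_pos = 1e5, max_width = 50)
  rates <- tf_rates(c(1e-4, 5e-4, 2e-3))
  snvs <- data.frame(sample_id = "S1", chrom = sites$chrom[1:5],
                     pos = sites$start[1:5], ref = "A", alt = "G")
  enr <- tfbs_enrichment(sites, snvs, rates)
  brute <- vapply(interval_width(sites), function(w)
    1 - prod(1 - (1 - (1 - rates$p_k)^w)), numeric(1))
  expect_equal(enr$expected, sum(brute), tolerance = 1e-10)
  expect_equal(enr$fc, enr$observed / enr$expected)
  expect_gte(enr$observed, 5)   # the 5 planted hits (overlaps may add none)
})

test_that("no SNVs means observed 0 and p-value 1", {
  sites <- regulatory_set("chr1", c(0, 100), c(50, 160), c("B1", "B2"))
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = numeric(0), ref = character(0),
                      alt = character(0))
  enr <- tfbs_enrichment(sites, empty, tf_rates(c(1e-4, 1e-4)))
  expect_equal(enr$observed, 0)
  expect_equal(enr$p_value, 1)
})

test_that("site-level tail matches the 2^5 enumeration oracle", {
  sites <- regulatory_set("chr1", c(0, 100, 200, 300, 400) * 10,
                          c(30, 1050, 2070, 3100, 4200), paste0("B", 1:5))
  rates <- tf_rates(c(2e-3, 5e-3, 1e-3))
  snvs <- data.frame(sample_id = c("S1", "S2"), chrom = "chr1",
                     pos = c(5, 1001), ref = "C", alt = "A")
  enr <- tfbs_enrichment(sites, snvs, rates)
  pmf <- enum_pbd_pmf(enr$site_probs)
  expect_equal(enr$observed, 2)
  expect_equal(enr$p_value, sum(pmf[(2 + 1):6]), tolerance = 1e-12)
})

test_that("adding a never-mutated site cannot raise the fold change", {
  set.seed(91)
  rates <- tf_rates(runif(4, 1e-4, 1e-3))
  sites <- regulatory_set("chr1", c(0, 1000), c(200, 1300), c("B1", "B2"))
  snvs <- data.frame(sample_id = "S1", chrom = "chr1", pos = 10,
                     ref = "A", alt = "T")
  fc1 <- tfbs_enrichment(sites, snvs, rates)$fc
  more <- regulatory_set("chr1", c(0, 1000, 5000), c(200, 1300, 5400),
                         paste0("B", 1:3))
  fc2 <- tfbs_enrichment(more, snvs, rates)$fc
  expect_lte(fc2, fc1)
})

test_that("full TF report counts all and active sites separately", {
  tfbs <- regulatory_set("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350),
                         paste0("B", 1:4), element_class = "tfbs")
  peaks <- regulatory_set("chr1", 90, 260)  # B2, B3 active
  rates <- tf_rates(c(1e-3, 1e-3))
  snvs <- data.frame(sample_id = "S1", chrom = "chr1", pos = c(10, 110),
                     ref = "A", alt = "T")
  rep <- tfbs_report("TF1", tfbs, peaks, snvs, rates)
  expect_equal(rep$n_sites, 4L)
  expect_equal(rep$n_active, 2L)
  expect_equal(rep$n_sites_mutated, 2L)
  expect_equal(rep$n_active_mutated, 1L)
})

test_that("SEs go to the highest expressed overlapping gene", {
  ses <- regulatory_set("chr1", c(0, 5000, 9000), c(1000, 6000, 9500),
                        paste0("SE", 1:3), element_class = "se")
  genes <- regulatory_set("chr1", c(100, 500, 5100, 5200),
                          c(300, 800, 5300, 5500),
                          c("GA", "GB", "GENEA", "GENEB"),
                          element_class = "gene")
  expr <- signal_matrix(
    rbind(GA = c(100, 100), GB = c(10, 10),
          GENEA = c(50, 50), GENEB = c(50, 50)),
    col_ids = c("S1", "S2"))
  out <- assign_se_genes(ses, genes, expr)
  expect_equal(out$gene_id[out$se_id == "SE1"], "GA")
  expect_equal(out$gene_id[out$se_id == "SE2"], "GENEA")  # tie -> lexicographic
  expect_false("SE3" %in% out$se_id)                      # overlaps nothing
  # genes without expression count as zero
  expr2 <- signal_matrix(rbind(GB = c(10, 10), GENEA = c(50, 50),
                               GENEB = c(50, 50)), col_ids = c("S1", "S2"))
  expect_message(out2 <- assign_se_genes(ses, genes, expr2), "treated as 0")
  expect_equal(out2$gene_id[out2$se_id == "SE1"], "GB")
})

test_that("running-sum score matches a hand-computed toy ranking", {
  burden <- data.frame(unit_id = paste0("G", 1:6),
                       p_value = c(0.01, 0.02, 0.1, 0.5, 0.7, 0.9))
  # hits G1, G3 of 6: steps +1/2 at hits, -1/4 at misses
  # running sum: .5, .25, .75, .5, .25, 0 -> max .75
  expect_equal(reburden:::gsea_score(paste0("G", 1:6), c("G1", "G3")),
               0.75)
  enr <- se_creag_enrichment(burden, c("G1", "G3"), n_perm = 200, seed = 4)
  expect_equal(enr$score, 0.75)
  expect_gt(enr$p_value, 0)
  expect_lte(enr$p_value, 1)
})

test_that("a top-loaded gene set attains the permutation floor", {
  burden <- data.frame(unit_id = paste0("G", 1:40),
                       p_value = seq(0.001, 0.8, length.out = 40))
  enr <- se_creag_enrichment(burden, paste0("G", 1:8), n_perm = 500,
                             seed = 2)
  expect_equal(enr$p_value, 1 / 501)
  expect_error(se_creag_enrichment(burden, "ZZZ", n_perm = 500, seed = 1),
               "disjoint")
})

test_that("random gene labels give roughly uniform permutation p", {
  burden <- data.frame(unit_id = paste0("G", 1:60),
                       p_value = seq(0.001, 0.9, length.out = 60))
  set.seed(123)
  ps <- vapply(1:40, function(i)
    se_creag_enrichment(burden, sample(burden$unit_id, 10),
                        n_perm = 200, seed = i)$p_value, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
})
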