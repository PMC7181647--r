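# Independent brute-force oracles used across the suite.

# quadratic all-pairs overlap of half-open intervals
brute_overlaps <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        query$start[i] < subject$end[j] &&
        subject$start[j] < query$end[i])
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0),
                                      subject = integer(0)))
  m <- do.call(rbind, out)
  out <- data.frame(query = m[, 1], subject = m[, 2])
  out[order(out$query, out$subject), , drop = FALSE]
}

# exhaustive 2^n enumeration of the Poisson-binomial pmf
enum_pbd_pmf <- function(probs) {
  n <- length(probs)
  pmf <- numeric(n + 1)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  logp <- log(probs); logq <- log1p(-probs)
  pr <- exp(grid %*% logp + (1 - grid) %*% logq)
  for (k in 0:n) pmf[k + 1] <- sum(pr[rowSums(grid) == k])
  pmf
}

# exact two-sided rank-sum p by enumeration of all group assignments,
# using the doubled-smaller-tail convention
perm_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  vals <- c(x, y)
  u_stat <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - m * (m + 1) / 2
  }
  obs <- u_stat(seq_len(m))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_stat)
  lo <- mean(us <= obs); hi <- mean(us >= obs)
  min(1, 2 * min(lo, hi))
}

# exact two-sided binomial p by direct enumeration (point-probability rule)
enum_binom_p <- function(x, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# per-SNV brute-force recount of the mutation matrix
brute_mutation_counts <- function(snvs, res) {
  samples <- sort(unique(snvs$sample_id))
  cnt <- matrix(0L, nrow(res), length(samples),
                dimnames = list(res$name, samples))
  for (i in seq_len(nrow(snvs))) {
    for (j in seq_len(nrow(res))) {
      if (snvs$chrom[i] == res$chrom[j] &&
          snvs$pos[i] >= res$start[j] && snvs$pos[i] < res$end[j])
        cnt[j, snvs$sample_id[i]] <- cnt[j, snvs$sample_id[i]] + 1L
    }
  }
  cnt
}

# random interval set on a toy genome
random_set <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                       max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  regulatory_set(sample(chroms, n, replace = TRUE), start,
                 start + sample.int(max_width, n, replace = TRUE),
                 name = paste0("X", seq_len(n)))
}

# small cohort configuration shared by several suites
tiny_config <- function(seed = 7, n_res = 40, ...) {
  cohort_config(n_samples = 10, genome_length = 1e6, n_chromosomes = 1,
                n_tads = 4, n_genes = 8, n_res = n_res,
                re_width_mean = 500, seed = seed, ...)
}
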