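test_that("binomial AI p-values match the doubled-tail closed form", {
  expect_equal(binomial_ai(10, 10), 1.0)
  expect_equal(binomial_ai(20, 0), 2 * 0.5^20)
  # oracle: 2 * sum_{k=12}^{20} C(20,k) / 2^20
  expect_equal(binomial_ai(12, 8), 2 * sum(choose(20, 12:20)) / 2^20,
               tolerance = 1e-12)
  expect_error(binomial_ai(0, 0), "positive")
  expect_error(binomial_ai(-1, 5), "negative")
})

test_that("binomial AI is symmetric and monotone in imbalance", {
  for (n in c(5L, 20L, 77L)) {
    ks <- 0:n
    p <- binomial_ai(ks, n - ks)
    expect_equal(p, rev(p))                       # symmetry
    upper <- p[ks >= ceiling(n / 2)]
    expect_true(all(diff(upper) <= 1e-12))        # non-increasing
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("SNP-level p-values respect the coverage threshold per library", {
  counts <- data.frame(library = c("L1", "L1", "L2", "L2"),
                       ref = c(20L, 10L, 3L, 2L),
                       alt = c(6L, 4L, 3L, 2L))
  res <- snp_ai(counts)
  r1 <- res[res$library == "L1", ]
  expect_equal(c(r1$ref, r1$alt), c(30L, 10L))
  expect_equal(r1$p, binomial_ai(30, 10))
  expect_equal(r1$direction, "ref>alt")
  r2 <- res[res$library == "L2", ]
  expect_equal(c(r2$ref, r2$alt), c(5L, 5L))     # 10 < 20
  expect_true(is.na(r2$p))
})

test_that("transcript coverage sums use only cluster representatives", {
  t <- transcript_model("t1", "c1", "+", exons = cbind(1L, 1000L))
  # two clustered SNPs (only the heavier counts) plus a lone SNP
  snps <- data.frame(pos = c(100L, 130L, 600L),
                     coverage = c(40, 200, 20))
  cl <- cluster_snps(t, snps, window = 100L)
  lc <- data.frame(pos = rep(c(100L, 130L, 600L), 1L),
                   library = "L1",
                   ref = c(25L, 30L, 15L), alt = c(15L, 10L, 5L))
  res <- transcript_snp_coverage_ai(cl, lc)
  expect_equal(c(res$ref, res$alt), c(45L, 15L))  # 130 and 600 only
  expect_equal(res$p, binomial_ai(45, 15))
  # dedup never exceeds the naive sum; equality iff all singletons
  expect_lte(res$ref + res$alt, sum(lc$ref + lc$alt))
  cl0 <- cluster_snps(t, snps, window = 0L)
  res0 <- transcript_snp_coverage_ai(cl0, lc)
  expect_equal(res0$ref + res0$alt, sum(lc$ref + lc$alt))
})

test_that("transcript coverage is undefined without a covered member", {
  t <- transcript_model("t1", "c1", "+", exons = cbind(1L, 1000L))
  snps <- data.frame(pos = c(100L, 600L), coverage = c(10, 12))
  cl <- cluster_snps(t, snps, window = 100L)
  lc <- data.frame(pos = c(100L, 600L), library = "L1",
                   ref = c(7L, 8L), alt = c(3L, 4L))
  res <- transcript_snp_coverage_ai(cl, lc)
  expect_true(is.na(res$p))                       # all members < 20
  expect_equal(res$ref + res$alt, 22L)            # counts still summed
  empty <- transcript_snp_coverage_ai(list(), lc[0L, ])
  expect_equal(nrow(empty), 0L)
})

test_that("read-count AI rounds half-up before testing", {
  r <- transcript_read_count_ai(30.4, 9.6)
  expect_equal(c(r$ref, r$alt), c(30L, 10L))
  expect_equal(r$p, binomial_ai(30, 10))
  r2 <- transcript_read_count_ai(7.2, 4.4)
  expect_true(is.na(r2$p))                        # rounded sum 11 < 20
  r3 <- transcript_read_count_ai(10.0, 10.0)
  expect_equal(r3$p, 1.0)
  expect_equal(transcript_read_count_ai(10.5, 9.4)$ref, 11L)  # half up
  expect_error(transcript_read_count_ai(-1, 5), "negative")
})

test_that("gene aggregation sums transcript read counts", {
  tp <- toy_plus()
  rc <- data.frame(library = "L1", ref_est = 30 + 20, alt_est = 10 + 20)
  res <- gene_aggregate(tp$gene,
                        data.frame(pos = integer(), library = character(),
                                   ref = integer(), alt = integer()),
                        stats::setNames(numeric(0), character(0)),
                        read_counts = rc)
  expect_equal(c(res$read_count$ref, res$read_count$alt), c(50L, 30L))
  expect_equal(res$read_count$p, binomial_ai(50, 30))
})

test_that("gene span covers the leftmost start to the rightmost end", {
  t1 <- transcript_model("t1", "c1", "+", exons = cbind(100L, 500L))
  t2 <- transcript_model("t2", "c1", "+",
                         exons = rbind(c(300L, 400L), c(700L, 900L)))
  g <- gene_model("g1", list(t1, t2))
  expect_equal(gene_span(g), c(100L, 900L))
})

test_that("isoform ranking is by descending reads with lexical ties", {
  expect_equal(rank_transcripts(c(a = 100, b = 50, c = 0)),
               c(a = 1L, b = 2L, c = 3L))
  expect_equal(rank_transcripts(c(z = 50, a = 50)),
               c(z = 2L, a = 1L))
  expect_equal(rank_transcripts(c(only = 7)), c(only = 1L))
})

test_that("replicate discordance uses replicate-vs-rest chi-square", {
  # replicate (30,10) against others summing (20,60): chi2 ~ 27.43
  reps <- data.frame(ref = c(30L, 10L, 10L), alt = c(10L, 30L, 30L))
  expect_true(flag_replicate_discordance(reps))
  # proportional replicates: chi2 = 0
  expect_false(flag_replicate_discordance(
    data.frame(ref = c(10L, 20L), alt = c(30L, 60L))))
  # opposite but tiny: (3,2) vs (40,60) has p ~ 0.37
  expect_false(flag_replicate_discordance(
    data.frame(ref = c(3L, 40L), alt = c(2L, 60L))))
  # single replicate is vacuously concordant
  expect_false(flag_replicate_discordance(data.frame(ref = 30L,
                                                     alt = 1L)))
})

test_that("opposite-SNP flag needs two significant opposite directions", {
  base <- data.frame(library = "L1", p = c(0.01, 0.03),
                     direction = c("ref>alt", "alt>ref"))
  expect_true(flag_opposite_snps(base))
  same <- data.frame(library = "L1", p = c(0.01, 0.03),
                     direction = c("ref>alt", "ref>alt"))
  expect_false(flag_opposite_snps(same))
  weak <- data.frame(library = "L1", p = c(0.01, 0.2),
                     direction = c("ref>alt", "alt>ref"))
  expect_false(flag_opposite_snps(weak))
  # directions split across libraries do not count
  split <- data.frame(library = c("L1", "L2"), p = c(0.01, 0.01),
                      direction = c("ref>alt", "alt>ref"))
  expect_false(flag_opposite_snps(split))
  # NA p-values never satisfy the filter
  nap <- data.frame(library = "L1", p = c(NA, 0.01),
                    direction = c("ref>alt", "alt>ref"))
  expect_false(flag_opposite_snps(nap))
})

test_that("reference bias is the pooled ref fraction as a percentage", {
  expect_equal(compute_bias(514, 486), 51.4)
  expect_equal(compute_bias(c(10, 10), c(10, 10)), 50)
  expect_equal(compute_bias(585, 415), 58.5)
  expect_error(compute_bias(0, 0), "no counted reads")
})

test_that("binomial test maintains nominal size and analytic power", {
  set.seed(19)
  # type I at coverage 100: exact test is conservative by discreteness
  x <- stats::rbinom(4000, 100, 0.5)
  rate <- mean(binomial_ai(x, 100 - x) < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.055)
  # estimated ref fraction recovers theta within 3 SE
  theta <- 0.65
  n <- 200L
  k <- stats::rbinom(1L, n * 50L, theta)
  se <- sqrt(theta * (1 - theta) / (n * 50))
  expect_lt(abs(k / (n * 50) - theta), 3 * se)
})
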