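# manual alignment tibble with an rpm denominator, as map_srna_library makes
mk_aln <- function(starts, lens, library = "lib1", clean_total = 1e6,
                   strand = "+") {
  a <- tibble::tibble(read_id = paste0("r", seq_along(starts)),
                      read = NA_character_, status = "unique",
                      ref_name = "ref", start = as.integer(starts),
                      strand = strand, length = as.integer(lens),
                      library = library)
  attr(a, "clean_total") <- clean_total
  a
}

test_that("preprocessing recovers inserts through trim, dedup and UMI removal", {
  adapter <- "TGGAATTCTCGGGTGCCA"
  insert24 <- random_seq(24)
  raw <- paste0("ACGT", insert24, "TTAC", adapter, "GGAT")
  lib <- preprocess_srna(c(raw, raw), adapter, protocol = "umi4n")
  # identical raw reads deduplicate to one survivor; UMIs stripped
  expect_equal(lib$reads, insert24)

  # length boundaries: 17 and 31 nt inserts dropped, 18 and 30 kept
  mk <- function(n) paste0("AAAA", random_seq(n), "CCCC", adapter)
  lib2 <- preprocess_srna(vapply(c(17, 18, 30, 31), mk, character(1)),
                          adapter, protocol = "umi4n")
  expect_equal(sort(nchar(lib2$reads)), c(18L, 30L))

  # plain protocol: no UMI trim, optional dedup
  raw3 <- paste0(insert24, adapter)
  lib3 <- preprocess_srna(c(raw3, raw3), adapter, protocol = "plain",
                          dedup = FALSE)
  expect_equal(lib3$reads, c(insert24, insert24))
  expect_warning(preprocess_srna(character(0), adapter), "empty")
})

test_that("structural reads are removed and clean totals set", {
  set.seed(71)
  rrna <- random_seq(600)
  struct_read <- substr(rrna, 101, 124)
  other <- random_seq(24)
  lib <- srna_library(c(struct_read, other, other), "l1")
  clean <- filter_structural(lib, c(rRNA = rrna))
  expect_equal(clean$reads, c(other, other))
  expect_equal(clean$clean_total, 2L)
})

test_that("cluster merging honors the pad boundary and the coverage floor", {
  # two 24 nt reads with a 49 bp gap merge; a 51 bp gap does not
  near <- mk_aln(c(100, 100 + 24 + 49), c(24, 24), clean_total = 2e6)
  cl1 <- call_clusters(near, mincov_rpm = 0.5, pad = 50)
  expect_equal(nrow(cl1), 1L)
  far <- mk_aln(c(100, 100 + 24 + 51), c(24, 24), clean_total = 2e6)
  cl2 <- call_clusters(far, mincov_rpm = 0.5, pad = 50)
  expect_equal(nrow(cl2), 2L)
  # a 50 bp gap also stays separate (merge requires gap < pad)
  edge <- mk_aln(c(100, 100 + 24 + 50), c(24, 24), clean_total = 2e6)
  expect_equal(nrow(call_clusters(edge, mincov_rpm = 0.5, pad = 50)), 2L)

  # coverage floor: mincov_reads = ceiling(0.5 * 8e6 / 1e6) = 4
  four <- mk_aln(rep(200, 4), rep(24, 4), clean_total = 8e6)
  three <- mk_aln(rep(500, 3), rep(24, 3), clean_total = 8e6)
  kept <- call_clusters(dplyr::bind_rows(four, three),
                        clean_totals = c(lib1 = 8e6), mincov_rpm = 0.5)
  expect_equal(attr(kept, "mincov_reads"), 4)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 200L)
  expect_error(call_clusters(four, pad = -1), "pad")
})

test_that("cluster calling equals the brute-force merge-and-threshold oracle", {
  set.seed(73)
  for (rep in 1:3) {
    n <- 1500
    starts <- sample(0:9970, n, replace = TRUE)
    lens <- sample(18:30, n, replace = TRUE)
    aln <- mk_aln(starts, lens, clean_total = 4e6)
    got <- call_clusters(aln, mincov_rpm = 0.5, pad = 50)
    exp <- oracle_clusters(starts, lens, 50L, ceiling(0.5 * 4e6 / 1e6))
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$n_reads, exp$n_reads)
  }
})

test_that("differential testing matches the closed-form two-sample computation", {
  cl <- call_clusters(mk_aln(rep(100, 5), rep(24, 5), clean_total = 1e6))
  # rpm A = {1,2,3}, B = {2,4,6}: counts at clean_total 1e6
  ga <- lapply(1:3, function(i) mk_aln(rep(100, i), rep(24, i),
                                       library = paste0("a", i)))
  gb <- lapply(1:3, function(i) mk_aln(rep(100, 2 * i), rep(24, 2 * i),
                                       library = paste0("b", i)))
  res <- quantify_and_test(cl, ga, gb, test = "welch")
  expect_equal(res$fold, 2)
  # closed-form Welch statistic for {1,2,3} vs {2,4,6}
  se <- sqrt(1 / 3 + 4 / 3)
  t_exp <- (4 - 2) / se
  df_exp <- (1 / 3 + 4 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2)
  p_exp <- 2 * stats::pt(-abs(t_exp), df_exp)
  expect_equal(res$t, t_exp, tolerance = 1e-10)
  expect_equal(res$p, p_exp, tolerance = 1e-10)

  # pooled variant: classic equal-variance formula
  res_p <- quantify_and_test(cl, ga, gb, test = "pooled")
  sp2 <- (2 * 1 + 2 * 4) / 4
  t_pool <- (4 - 2) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res_p$t, t_pool, tolerance = 1e-10)

  # identical groups: fold 1, p 1
  same <- quantify_and_test(cl, ga, ga)
  expect_equal(same$fold, 1)
  expect_equal(same$p, 1)

  g <- glance(res)
  expect_equal(g$n_clusters, 1L)
})

test_that("5'-collapse is strand aware and conserves rpm", {
  # single plus-strand 24-mer: 5' end is the interval start
  plus <- mk_aln(100, 24, clean_total = 1e6)
  pr <- collapse_5prime_profile(plus, region = c(0, 1000), bin = 10)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$bin_start, 100L)
  expect_equal(pr$strand, "+")

  # minus-strand read: 5' end is interval end - 1
  minus <- mk_aln(100, 24, strand = "-", clean_total = 1e6)
  mr <- collapse_5prime_profile(minus, region = c(0, 1000), bin = 10)
  expect_equal(mr$bin_start, 120L)   # 5' at 123 -> bin [120, 130)

  # random set vs naive loop, and conservation of totals
  set.seed(79)
  n <- 400
  aln <- mk_aln(sample(0:960, n, TRUE), sample(18:30, n, TRUE),
                strand = sample(c("+", "-"), n, TRUE), clean_total = 2e6)
  prof <- collapse_5prime_profile(aln, region = c(0, 1000), bin = 10)
  p5 <- ifelse(aln$strand == "+", aln$start, aln$start + aln$length - 1L)
  keep <- p5 >= 0 & p5 < 1000
  expect_equal(sum(prof$rpm), sum(keep) * 1e6 / 2e6)
  i <- sample(nrow(prof), 10)
  for (k in i) {
    manual <- sum(p5 >= prof$bin_start[k] & p5 < prof$bin_start[k] + 10 &
                    aln$strand == prof$strand[k] &
                    aln$length == prof$length[k] & keep)
    expect_equal(prof$rpm[k], manual * 1e6 / 2e6)
  }
})

test_that("size-class profiles and 21-mer normalization follow the stated arithmetic", {
  lib <- srna_library(rep(strrep("A", 24), 10), "l")
  p <- size_class_profile(lib)
  expect_equal(p$pct[p$length == 24], 100)
  expect_equal(sum(p$pct), 100)

  expect_warning(p0 <- size_class_profile(srna_library(character(0), "e")),
                 "undefined")
  expect_true(attr(p0, "empty"))

  # worked arithmetic: pct_mut(24)=5, pct21_mut=30, pct21_ctrl=15 -> 2.5
  mk_prof <- function(p21, p24) {
    d <- tibble::tibble(length = 18:30, n = 0L, pct = 0)
    d$pct[d$length == 21] <- p21
    d$pct[d$length == 24] <- p24
    d$pct[d$length == 22] <- 100 - p21 - p24
    structure(d, class = c("size_class_profile", class(d)),
              total = 100L, empty = FALSE)
  }
  mut <- mk_prof(30, 5)
  ctl <- mk_prof(15, 40)
  nn <- normalize_by_21mer(mut, ctl)
  expect_equal(nn$normalized_pct[nn$length == 24], 2.5)
  expect_equal(nn$residual_fraction[nn$length == 24], 2.5 / 40)

  # equal 21-mer percentages leave the profile unchanged
  same <- normalize_by_21mer(mk_prof(15, 40), ctl)
  expect_equal(same$normalized_pct, same$pct_mutant)

  # scaling invariance: uniform subsampling leaves expected pcts unchanged
  expect_error(normalize_by_21mer(mk_prof(0, 50), ctl), "undefined")
})

test_that("mutant libraries lose 24-mers at the configured genome-wide retention", {
  fx <- sim_fixture()
  libs <- tibble::tibble(
    name = c("rpd1_het", "rpd1_mut", "rmr1_het", "rmr1_mut"),
    genotype = c("rpd1_het", "rpd1_mut", "rmr1_het", "rmr1_mut"),
    tissue = "cob", depth = 30000)
  sim <- simulate_srna_libraries(fx$hap, libs, seed = 211)
  profs <- lapply(libs$name, function(nm) {
    lib <- preprocess_srna(sim$reads[[nm]], fx$cfg$srna$adapter,
                           protocol = "umi4n", name = nm)
    lib <- filter_structural(lib, fx$idx$structural)
    size_class_profile(lib)
  })
  names(profs) <- libs$name
  rpd1 <- normalize_by_21mer(profs$rpd1_mut, profs$rpd1_het)
  expect_lt(rpd1$residual_fraction[rpd1$length == 24], 0.10)
  rmr1 <- normalize_by_21mer(profs$rmr1_mut, profs$rmr1_het)
  expect_equal(rmr1$residual_fraction[rmr1$length == 24], 0.48,
               tolerance = 0.10)
})
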