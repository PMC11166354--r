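test_that("reads classify as unique, multi or unmapped per the zero-mismatch contract", {
  set.seed(11)
  ref <- random_seq(800)
  idx <- build_index(c(chr = ref))

  once <- substr(ref, 101, 124)
  out <- classify_reads(idx, once)
  expect_equal(out$status, "unique")
  expect_equal(out$start, 100L)
  expect_equal(out$strand, "+")

  # reverse-complement read places on the minus strand at the same interval
  rc <- oracle_revcomp(once)
  out2 <- classify_reads(idx, rc)
  expect_equal(out2$status, "unique")
  expect_equal(out2$start, 100L)
  expect_equal(out2$strand, "-")

  # absent read
  expect_equal(classify_reads(idx, strrep("ACGT", 6))$status, "unmapped")

  # a perfect palindrome matching one locus counts both strands -> multi
  half <- random_seq(12)
  pal <- paste0(half, oracle_revcomp(half))
  idxp <- build_index(c(chr = paste0(random_seq(50), pal, random_seq(50))))
  expect_equal(classify_reads(idxp, pal)$status, "multi")

  # N never matches; non-ACGTN errors
  idxn <- build_index(c(chr = paste0(substr(ref, 1, 200), "N",
                                     substr(ref, 202, 800))))
  span_n <- substr(ref, 190, 213)
  expect_equal(classify_reads(idxn, span_n)$status, "unmapped")
  expect_error(classify_reads(idx, "ACGTX"), "symbols")
  expect_error(build_index(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("repeat-derived reads are multi on the full haplotype but unique on the collapsed one", {
  fx <- sim_fixture()
  hap <- fx$hap
  t <- hap$truth
  read <- substr(hap$model$sequence, t$usr_full[1] + 11L, t$usr_full[1] + 34L)
  full_idx <- build_index(c(full = hap$model$sequence))
  expect_equal(classify_reads(full_idx, read)$status, "multi")
  expect_equal(classify_reads(fx$idx$target, read)$status, "unique")
})

test_that("classification equals the naive two-strand scan oracle", {
  set.seed(23)
  refs <- c(r1 = random_seq(3000), r2 = random_seq(2000))
  idx <- build_index(refs)
  # 1000 reads: drawn from the references (both strands), random, near-misses
  reads <- character(1000)
  for (i in 1:700) {
    nm <- sample(names(refs), 1)
    w <- sample(18:30, 1)
    st <- sample(nchar(refs[[nm]]) - w, 1)
    r <- substr(refs[[nm]], st, st + w - 1L)
    if (runif(1) < 0.5) r <- oracle_revcomp(r)
    reads[i] <- r
  }
  for (i in 701:1000) reads[i] <- random_seq(sample(18:30, 1))
  got <- classify_reads(idx, reads)
  # spot-check a sample against the oracle (full scan of 1000 is slow)
  for (i in sample(1000, 120)) {
    o <- oracle_scan_read(as.list(refs), reads[i])
    expect_equal(got$status[i], o$status, info = paste("read", i))
    if (o$status == "unique") {
      expect_equal(got$ref_name[i], o$hits[[1]][1])
      expect_equal(got$start[i], as.integer(o$hits[[1]][2]))
      expect_equal(got$strand[i], o$hits[[1]][3])
    }
  }
})

test_that("classification is strand symmetric and order invariant", {
  set.seed(31)
  refs <- c(r = random_seq(1500))
  idx <- build_index(refs)
  reads <- c(vapply(1:40, function(i) {
    st <- sample(1400, 1)
    substr(refs[[1]], st, st + 23L)
  }, character(1)), vapply(1:10, function(i) random_seq(24), character(1)))
  fwd <- classify_reads(idx, reads)
  rev <- classify_reads(idx, oracle_revcomp(reads))
  expect_equal(fwd$status, rev$status)
  flip <- c("+" = "-", "-" = "+")
  expect_equal(unname(flip[fwd$strand[fwd$status == "unique"]]),
               rev$strand[rev$status == "unique"])
  expect_equal(fwd$start[fwd$status == "unique"],
               rev$start[rev$status == "unique"])

  perm <- sample(length(reads))
  shuffled <- classify_reads(idx, reads[perm])
  expect_equal(shuffled$status, fwd$status[perm])
  expect_equal(shuffled$start, fwd$start[perm])
})

test_that("two-pass filtering drops genome multi-mappers and keeps target uniques", {
  set.seed(37)
  te <- random_seq(120)
  target <- paste0(random_seq(300), te, random_seq(300))
  genome <- c(target = target, decoy = paste0(random_seq(100), te,
                                              random_seq(80)))
  gi <- build_index(genome)
  ti <- build_index(c(target = target))
  te_read <- substr(te, 21, 44)                 # multi on genome
  usr_read <- substr(target, 51, 74)            # unique everywhere
  novel <- random_seq(24)                       # unmapped everywhere
  out <- two_pass_filter(c(te_read, usr_read, novel), gi, ti)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 50L)
  counts <- attr(out, "filter_counts")
  expect_equal(sum(counts$n), 3L)
  expect_equal(counts$n[counts$stage == "genome_multi"], 1L)

  # skipping the genome pass retains the TE read (unique on target)
  out2 <- two_pass_filter(c(te_read, usr_read), NULL, ti)
  expect_equal(nrow(out2), 2L)
})

test_that("report-all mode enumerates every placement of multi-mappers", {
  set.seed(41)
  u <- random_seq(40)
  ref <- paste0(random_seq(30), u, random_seq(25), u, random_seq(30))
  idx <- build_index(c(chr = ref))
  r <- substr(u, 5, 28)
  all_hits <- classify_reads(idx, r, mode = "all")
  expect_equal(nrow(all_hits), 2L)
  expect_equal(sort(all_hits$start), c(34L, 99L))
  expect_true(all(all_hits$status == "multi"))
})
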