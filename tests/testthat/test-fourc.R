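test_that("proper amplicons parse to their captured fragment, rejects carry one reason", {
  cfg <- fourc_config(bait_position = 0L)
  frag <- paste0("GATC", "ATTGCCATAGCGTACGATTA")     # 24 nt, no CATG/GATC tail
  proper <- proper_4c_read(frag, cfg)
  expect_equal(nchar(proper), 49L)
  reads <- tibble::tibble(
    read_id = c("ok", "noanchor", "anchor_mm", "with_nlaiii", "short", "lowq"),
    read = c(
      proper,
      gsub("GATC", "GTTA", proper),                  # destroys cutter context
      sub("CTCGATC", "CTCCAGC", proper),             # 2 mismatches in anchor
      proper_4c_read(paste0("GATCAGGAT", "CATGAGCTATGA"),
                     cfg),                           # NlaIII + rev primer
      proper_4c_read(paste0("GATCAGG", strrep("A", 0)), cfg),
      proper),
    quality = "")
  # pad the NlaIII-bearing read to full length past the reverse primer
  reads$read[4] <- paste0(reads$read[4],
                          strrep("A", 49L - nchar(reads$read[4])))
  # read 5: primer + GATC + 3 nt fragment + NlaIII adapter + pad
  r5 <- proper_4c_read(paste0("GATCAGG", "CATGAGCTATGA"), cfg)
  reads$read[5] <- paste0(r5, strrep("A", 49L - nchar(r5)))
  reads$quality <- strrep("I", nchar(reads$read))
  reads$quality[6] <- strrep("#", nchar(reads$read[6]))  # Q2 everywhere

  out <- parse_4c_reads(reads, cfg)
  expect_equal(out$fragment[out$read_id == "ok"], frag)
  expect_equal(out$reject_reason[out$read_id == "noanchor"], "anchor")
  # one mismatch is allowed by hdist = 1; two are not
  expect_equal(out$reject_reason[out$read_id == "anchor_mm"], "anchor")
  expect_equal(out$fragment[out$read_id == "with_nlaiii"], "GATCAGGAT")
  expect_equal(out$reject_reason[out$read_id == "short"], "min_fragment_len")
  expect_equal(out$reject_reason[out$read_id == "lowq"], "quality")

  # every read accounted for exactly once
  rep <- fourc_rejection_report(out)
  expect_equal(sum(rep$n), nrow(reads))
  expect_true(all(is.na(out$reject_reason) | !is.na(out$reject_reason)))
  expect_equal(sum(is.na(out$reject_reason)), sum(!is.na(out$fragment)))
})

test_that("single anchor mismatch passes, unrecognized primer fails the length cap", {
  cfg <- fourc_config()
  frag <- paste0("GATC", "TTACGGAATCCGTAGGCAAT")
  one_mm <- sub("CTCGATC", "CTAGATC", proper_4c_read(frag, cfg))
  # mismatch falls in the primer part; anchor window has 1 mismatch: passes
  # anchor but primer still recognized (hdist 2 on 16-mer)
  reads <- tibble::tibble(read_id = "mm1", read = one_mm,
                          quality = strrep("I", 49L))
  out <- parse_4c_reads(reads, cfg)
  expect_true(is.na(out$reject_reason))

  # scramble the primer beyond hdist 2: left trim finds nothing, 49 bp > 28
  scrambled <- paste0("ACTGGTCCA", random_seq(16), frag)
  reads2 <- tibble::tibble(read_id = "scr", read = scrambled,
                           quality = strrep("I", 49L))
  # keep the anchor context (last 3 primer nt + GATC) intact
  reads2$read <- paste0(substr(reads2$read, 1, 22), "CTC",
                        substr(frag, 1, 24))
  out2 <- parse_4c_reads(reads2, cfg)
  expect_equal(out2$reject_reason, "left_trim")
})

test_that("fragment length boundary at the minimum is honored", {
  cfg <- fourc_config()
  # after left trim: GATC + 4 = 8 nt fragment (kept), GATC + 3 = 7 (rejected)
  f8 <- paste0("GATC", "AGGA")
  f7 <- paste0("GATC", "AGG")
  mk <- function(frag) {
    core <- proper_4c_read(paste0(frag, "CATGAGCTATGA"), cfg)
    paste0(core, strrep("A", 49L - nchar(core)))
  }
  reads <- tibble::tibble(read_id = c("f8", "f7"),
                          read = c(mk(f8), mk(f7)),
                          quality = strrep("I", 49L))
  out <- parse_4c_reads(reads, cfg)
  expect_equal(out$fragment[1], f8)
  expect_equal(out$reject_reason[2], "min_fragment_len")
})

test_that("tag tables normalize to rpm, rank with competition ties, exclude the bait window", {
  set.seed(53)
  ref <- random_seq(9000)
  idx <- build_index(c(hap = ref))
  cfg <- fourc_config(bait_position = 4000L)
  # fragments at controlled distances from the bait
  mk_frag <- function(pos) substr(ref, pos + 1L, pos + 24L)
  pos_in <- 4000L + 1999L       # inside exclusion
  pos_edge <- 4000L + 2000L     # boundary: still excluded ("either side 2kb")
  pos_out <- 4000L + 2001L      # retained
  pos_far <- 500L
  frags <- c(rep(mk_frag(pos_in), 5), rep(mk_frag(pos_edge), 4),
             rep(mk_frag(pos_out), 3), rep(mk_frag(pos_far), 3),
             mk_frag(7000L))
  tt <- quantify_tags(frags, NULL, idx, cfg)
  expect_false(pos_in %in% tt$position)
  expect_false(pos_edge %in% tt$position)
  expect_true(pos_out %in% tt$position)
  # rpm sums to 1e6 over retained positions
  expect_equal(sum(tt$rpm), 1e6)
  # competition ranking: two positions tie at count 3 -> both rank 1, next 3
  expect_equal(sort(tt$rank), c(1L, 1L, 3L))

  # all tags at one position
  t1 <- quantify_tags(rep(mk_frag(500L), 10), NULL, idx, cfg)
  expect_equal(t1$rpm, 1e6)
  expect_equal(t1$rank, 1L)

  # zero retained tags -> empty table with warning
  expect_warning(t0 <- quantify_tags(rep(mk_frag(pos_in), 3), NULL, idx, cfg),
                 "no 4C tags")
  expect_equal(nrow(t0), 0L)
})

test_that("minus-strand tags collapse to their 5'-most (right end) coordinate", {
  set.seed(59)
  ref <- random_seq(6000)
  idx <- build_index(c(hap = ref))
  cfg <- fourc_config(bait_position = 5500L)
  frag <- oracle_revcomp(substr(ref, 1001, 1024))    # maps minus at 1000
  tt <- quantify_tags(frag, NULL, idx, cfg)
  expect_equal(tt$position, 1000L + 23L)
})

test_that("binning conserves rpm and matches a naive loop", {
  set.seed(61)
  tt <- tibble::tibble(position = sample(0:9999, 200),
                       count = rpois(200, 5) + 1L)
  tt$rpm <- 1e6 * tt$count / sum(tt$count)
  tt$rank <- dplyr::min_rank(dplyr::desc(tt$rpm))
  class(tt) <- c("fourc_tag_table", class(tt))
  b <- bin_tags(tt, 2000L)
  expect_equal(sum(b$rpm), sum(tt$rpm))
  for (i in seq_len(nrow(b))) {
    manual <- sum(tt$rpm[tt$position >= b$bin_start[i] &
                           tt$position < b$bin_end[i]])
    expect_equal(b$rpm[i], manual)
  }
})

test_that("simulated 4C libraries parse losslessly and recover the modal interaction site", {
  fx <- sim_fixture()
  sim <- simulate_4c_reads(fx$hap, depth = 12000, seed = 77)
  parsed <- parse_4c_reads(sim$reads, sim$config)
  retained <- !is.na(parsed$fragment)
  # zero sequencing error: every proper amplicon retained, every decoy rejected
  proper_ids <- sim$truth$read_id
  expect_true(all(parsed$read_id[retained] %in% proper_ids))
  expect_setequal(parsed$read_id[retained], proper_ids)

  tt <- quantify_tags(parsed, fx$idx$genome, fx$idx$target, sim$config)
  modal_truth <- as.integer(names(sort(table(sim$truth$position),
                                       decreasing = TRUE))[1])
  expect_equal(tt$position[tt$rank == 1L], modal_truth)
  expect_equal(modal_truth, fx$hap$truth$fourc_usr_site)
  # ranks are a valid competition ranking
  expect_equal(min(tt$rank), 1L)
  expect_true(all(tt$rank <= nrow(tt)))
})
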