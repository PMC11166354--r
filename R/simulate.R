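#' Simulation configuration
#'
#' Default conditions emulate the studied haplotype at desk scale: a 50 kb
#' haplotype carrying a perfect 2092 bp x 5 tandem array with a 390 bp
#' unique subregion (USR) embedded in each unit, two TE fragments flanking
#' the USR (one shared with a decoy background so its reads multi-map, one
#' array-private), a bait site upstream, 30 small-RNA source loci (one being
#' the USR), 1e5 reads per sequencing library, and effect sizes matching the
#' reported genotype contrasts (9.9-fold cob / 4.4-fold seedling USR sRNA
#' difference, 79% USR 24-mers, 48% USR reduction with a 15.8-fold TE peak
#' in the chromatin-remodeler mutant, 8% / 48% genome-wide 24-mer retention
#' in the two polymerase-pathway mutants, 0.88/0.60/0.07 CG/CHG/CHH
#' methylation in the repressed state, 15-fold USR RNA difference with Ct
#' noise sd 0.2).
#'
#' @param seed integer seed; every simulated output is reproducible from it.
#' @param ... named overrides of any nested default (e.g.
#'   `haplotype = list(length = 20000)` replaces only that field).
#' @return nested list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    haplotype = list(
      length = 50000L, array_start = 20000L, unit_length = 2092L,
      copy_number = 5L, usr_offset = 800L, usr_length = 390L,
      te1_offset = 300L, te1_length = 200L,
      te2_offset = 1300L, te2_length = 180L,
      bait_position = 5000L, fourc_site_usr_offset = 150L,
      decoy_length = 8000L, n_te1_decoys = 3L),
    srna = list(
      depth = 1e5, adapter = "TGGAATTCTCGGGTGCCA",
      structural_rate = 0.05, te1_rate = 0.02,
      locus_rate = 0.004, n_background_loci = 28L, locus_width = 200L,
      usr_rate_cob = 0.005, usr_rate_seedling = 0.004,
      usr_active_frac_cob = 1 / 9.9, usr_active_frac_seedling = 1 / 4.4,
      te2_rate_chd3a = 4e-4, te2_fold_chd3a_mut = 15.8,
      usr_frac_chd3a_mut = 0.52,
      usr_frac_rddm_mut = 0.02,
      p24_locus = 0.80, p24_usr = 0.79, p24_usr_chd3a_mut = 0.73,
      p24_te2 = 0.678, p24_te2_chd3a_mut = 0.777,
      p24_background = 0.60, p21_background = 0.10,
      retain24_rpd1 = 0.08, retain24_rmr1 = 0.48,
      antisense_23mer_bias = 0.85),
    fourc = list(
      depth = 1e5, proper_fraction = 0.92,
      forward_pad = "ACTGGTCCA", fragment_len = 24L,
      weight_baseline = 1, weight_array = 15, weight_usr = 60),
    methyl = list(
      n_clones = 20L, region_offset = 60L, region_length = 123L,
      conversion_failure = 0,
      rates = list(
        `Pl-Rh` = c(CG = 0.02, CHG = 0.01, CHH = 0.005),
        `Pl'` = c(CG = 0.88, CHG = 0.60, CHH = 0.07),
        het = c(CG = 0.88, CHG = 0.60, CHH = 0.07))),
    qpcr = list(
      n_samples = 3L, n_tech = 3L, ct_sd = 0.2, tech_sd = 0.1,
      sample_sd = 0.3, usr_fold = 15,
      mnase_folds = c(P1 = 1, P2 = 2, P3 = 2, P4 = 1)))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substr_set <- function(x, at, value) {       # at 1-based
  paste0(substr(x, 1L, at - 1L), value,
         substr(x, at + nchar(value), nchar(x)))
}

#' Generate a synthetic haplotype with recorded truth
#'
#' Builds a haplotype whose geometry mirrors the studied locus: a perfect
#' tandem array (unit x copies) embedding a unique subregion (USR) flanked
#' by two TE fragments, a bait position with a first-cutter site, and a
#' clean interaction site planted inside the USR. A decoy background
#' sequence shares the first TE so its reads multi-map at the genome pass,
#' and two structural (rRNA/tRNA-like) references are provided for the
#' clean-read filter.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return list of class `sim_haplotype`: `model` ([haplotype_model()] with
#'   feature annotations), `collapsed` ([collapse_repeats()] output), `decoy`
#'   and `structural` named sequences, and `truth` coordinates (full and
#'   collapsed space).
#' @export
generate_haplotype <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  h <- cfg$haplotype
  te1 <- random_dna(h$te1_length)
  te2 <- random_dna(h$te2_length)

  # USR with a clean interaction site: GATC followed by 20 bp free of
  # either cutter, so simulated 4C fragments parse and map losslessly
  repeat {
    usr <- random_dna(h$usr_length)
    usr <- substr_set(usr, h$fourc_site_usr_offset + 1L, "GATC")
    site24 <- substr(usr, h$fourc_site_usr_offset + 1L,
                     h$fourc_site_usr_offset + 24L)
    if (!grepl("GATC|CATG", substr(site24, 2L, 24L))) break
  }
  unit <- random_dna(h$unit_length)
  unit <- substr_set(unit, h$te1_offset + 1L, te1)
  unit <- substr_set(unit, h$usr_offset + 1L, usr)
  unit <- substr_set(unit, h$te2_offset + 1L, te2)

  flank1 <- random_dna(h$array_start)
  array_len <- h$unit_length * h$copy_number
  flank2 <- random_dna(h$length - h$array_start - array_len)
  # enforce array maximality at the exact phase
  last_u <- substr(unit, h$unit_length, h$unit_length)
  first_u <- substr(unit, 1L, 1L)
  pick_other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  flank1 <- substr_set(flank1, h$array_start, pick_other(last_u))
  flank2 <- substr_set(flank2, 1L, pick_other(first_u))
  # bait fragment: first-cutter site at the bait position
  flank1 <- substr_set(flank1, h$bait_position + 1L, "GATC")
  seq_full <- paste0(flank1, strrep(unit, h$copy_number), flank2)

  arrays <- tibble(start = h$array_start, unit_length = h$unit_length,
                   copy_number = h$copy_number, unit_sequence = unit)
  usr_full <- h$array_start + h$usr_offset
  features <- tibble(
    start = c(h$bait_position, h$array_start,
              usr_full, h$array_start + h$te1_offset,
              h$array_start + h$te2_offset),
    end = c(h$bait_position + 4L, h$array_start + array_len,
            usr_full + h$usr_length,
            h$array_start + h$te1_offset + h$te1_length,
            h$array_start + h$te2_offset + h$te2_length),
    strand = ".", type = c("bait", "tandem_array", "USR", "TE", "TE"),
    name = c("bait", "penta_array", "USR_copy1", "TE1_DNA7like",
             "TE2_PIFlike"))
  model <- haplotype_model("sim_haplotype", seq_full, features = features,
                           arrays = arrays)
  collapsed <- collapse_repeats(model)

  decoy <- random_dna(h$decoy_length)
  gap <- h$decoy_length %/% (h$n_te1_decoys + 1L)
  for (i in seq_len(h$n_te1_decoys)) {
    decoy <- substr_set(decoy, (i - 1L) * gap + 101L, te1)
  }
  structural <- c(rRNA_like = random_dna(2000L), tRNA_like = random_dna(500L))

  ca <- collapsed$arrays$collapsed_start[1]
  truth <- list(
    unit_length = h$unit_length, copy_number = h$copy_number,
    array_start = h$array_start,
    usr_full = c(usr_full, usr_full + h$usr_length),
    usr_collapsed = c(ca + h$usr_offset, ca + h$usr_offset + h$usr_length),
    te1_collapsed = c(ca + h$te1_offset, ca + h$te1_offset + h$te1_length),
    te2_collapsed = c(ca + h$te2_offset, ca + h$te2_offset + h$te2_length),
    bait_position = h$bait_position,
    fourc_usr_site = ca + h$usr_offset + h$fourc_site_usr_offset)
  structure(list(model = model, collapsed = collapsed, decoy = decoy,
                 structural = structural, truth = truth, cfg = cfg),
            class = "sim_haplotype")
}

#' @export
print.sim_haplotype <- function(x, ...) {
  cat(sprintf("<sim_haplotype> %d bp, array %d x %d bp, USR %d bp\n",
              nchar(x$model$sequence), x$truth$copy_number,
              x$truth$unit_length, diff(x$truth$usr_full)))
  invisible(x)
}

# genotype-specific emission model: per-locus read weights and 24mer shares
srna_emission <- function(hap, genotype, tissue) {
  cfg <- hap$cfg$srna
  t <- hap$truth
  cl <- nchar(hap$collapsed$sequence)
  ca <- hap$collapsed$arrays$collapsed_start[1]
  ul <- t$unit_length
  # background source loci spread outside the array region
  gap_lo <- ca - 500L
  gap_hi <- ca + ul + 500L
  pos <- round(seq(1500L, cl - 1500L, length.out = cfg$n_background_loci + 6L))
  pos <- pos[pos < gap_lo - cfg$locus_width | pos > gap_hi]
  pos <- head(pos, cfg$n_background_loci)
  loci <- tibble(origin = paste0("locus_", seq_along(pos)),
                 start = as.integer(pos),
                 end = as.integer(pos + cfg$locus_width),
                 weight = cfg$locus_rate, p24 = cfg$p24_locus)
  # the locus immediately before the USR (separate by > pad)
  pre <- tibble(origin = "pre_usr", start = ca + 400L, end = ca + 740L,
                weight = cfg$locus_rate, p24 = cfg$p24_locus)

  usr_base <- if (tissue == "cob") cfg$usr_rate_cob else cfg$usr_rate_seedling
  active_frac <- if (tissue == "cob") cfg$usr_active_frac_cob else
    cfg$usr_active_frac_seedling
  usr_w <- usr_base * switch(genotype,
    `Pl-Rh` = active_frac, `Pl'` = 1, het = 1,
    chd3a_het = 1, chd3a_mut = cfg$usr_frac_chd3a_mut,
    rpd1_het = 1, rpd1_mut = cfg$usr_frac_rddm_mut,
    rmr1_het = 1, rmr1_mut = cfg$usr_frac_rddm_mut,
    abort(sprintf("unknown genotype %s", genotype)))
  usr_p24 <- if (genotype == "chd3a_mut") cfg$p24_usr_chd3a_mut else cfg$p24_usr
  usr <- tibble(origin = "usr", start = t$usr_collapsed[1],
                end = t$usr_collapsed[2], weight = usr_w, p24 = usr_p24)

  te2_w <- switch(genotype,
                  chd3a_het = cfg$te2_rate_chd3a,
                  chd3a_mut = cfg$te2_rate_chd3a * cfg$te2_fold_chd3a_mut,
                  0)
  te2_p24 <- if (genotype == "chd3a_mut") cfg$p24_te2_chd3a_mut else cfg$p24_te2
  te2 <- tibble(origin = "te2", start = t$te2_collapsed[1],
                end = t$te2_collapsed[2], weight = te2_w, p24 = te2_p24)
  te1 <- tibble(origin = "te1", start = t$te1_collapsed[1],
                end = t$te1_collapsed[2], weight = cfg$te1_rate,
                p24 = cfg$p24_locus)

  retain24 <- switch(genotype, rpd1_mut = cfg$retain24_rpd1,
                     rmr1_mut = cfg$retain24_rmr1, 1)
  bind_rows(loci, pre, usr, te2, te1) |>
    mutate(retain24 = retain24)
}

# per-length emission probabilities given a 24mer share; 21mers fixed so
# mutant normalization has its anchor
length_probs <- function(p24, p21 = 0.05) {
  others <- c(`18` = 0.004, `19` = 0.006, `20` = 0.01, `22` = 0.04,
              `23` = 0.05, `25` = 0.03, `26` = 0.01, `27` = 0.004,
              `28` = 0.003, `29` = 0.002, `30` = 0.001)
  rest <- 1 - p24 - p21
  pr <- c(others / sum(others) * rest, `21` = p21, `24` = p24)
  pr[order(as.integer(names(pr)))]
}

#' Simulate small-RNA sequencing libraries
#'
#' Draws reads from the genotype-dependent emission model (USR 24-mers high
#' in repressed-state libraries, TE multi-mappers, 28 background loci, a
#' structural rRNA/tRNA fraction, and off-target background from the decoy
#' genome), decorates them per library protocol (`umi4n`: 4 random nt each
#' side of the insert plus 3' adapter; `plain`: adapter only), and records a
#' per-read truth table.
#'
#' @param hap a [generate_haplotype()] result.
#' @param libraries tibble with columns `name`, `genotype` (one of `Pl-Rh`,
#'   `Pl'`, `het`, `chd3a_het`, `chd3a_mut`, `rpd1_het`, `rpd1_mut`,
#'   `rmr1_het`, `rmr1_mut`), `tissue` (`cob`/`seedling`) and optionally
#'   `depth`, `protocol`.
#' @param seed RNG seed.
#' @return list with `reads` (named list of tibbles `read_id`, `read`,
#'   `quality`) and `truth` (one row per simulated read).
#' @export
simulate_srna_libraries <- function(hap, libraries, seed = hap$cfg$seed + 1L) {
  stopifnot(inherits(hap, "sim_haplotype"))
  set.seed(seed)
  cfg <- hap$cfg$srna
  cseq <- hap$collapsed$sequence
  if (!"depth" %in% names(libraries)) libraries$depth <- cfg$depth
  if (!"protocol" %in% names(libraries)) libraries$protocol <- "umi4n"
  reads_out <- list()
  truth_out <- list()
  for (i in seq_len(nrow(libraries))) {
    lb <- libraries[i, ]
    n <- as.integer(lb$depth)
    em <- srna_emission(hap, lb$genotype, lb$tissue)
    p_sources <- c(em$weight, structural = cfg$structural_rate)
    p_bg <- 1 - sum(p_sources)
    stopifnot(p_bg > 0)
    origin <- sample(c(em$origin, "structural", "background"), n,
                     replace = TRUE, prob = c(p_sources, p_bg))
    len <- integer(n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- rep(NA_integer_, n)
    insert <- character(n)
    retain24 <- em$retain24[1]

    # locus reads from the collapsed haplotype
    for (j in seq_len(nrow(em))) {
      idx <- which(origin == em$origin[j])
      if (!length(idx)) next
      pr <- length_probs(em$p24[j])
      if (retain24 < 1) {
        pr["24"] <- pr["24"] * retain24
        pr <- pr / sum(pr)
      }
      len[idx] <- sample(18:30, length(idx), replace = TRUE, prob = pr)
      start[idx] <- em$start[j] +
        floor(stats::runif(length(idx)) * (em$end[j] - em$start[j] - len[idx]))
      if (lb$tissue == "cob") {      # antisense bias for 23-mers
        a23 <- idx[len[idx] == 23L]
        strand[a23] <- ifelse(stats::runif(length(a23)) <
                                cfg$antisense_23mer_bias, "-", "+")
      }
      s <- substring(cseq, start[idx] + 1L, start[idx] + len[idx])
      neg <- strand[idx] == "-"
      s[neg] <- revcomp(s[neg])
      insert[idx] <- s
    }
    # structural reads
    idx <- which(origin == "structural")
    if (length(idx)) {
      pr <- length_probs(cfg$p24_background, cfg$p21_background)
      len[idx] <- sample(18:30, length(idx), replace = TRUE, prob = pr)
      src <- sample(names(hap$structural), length(idx), replace = TRUE)
      mx <- nchar(hap$structural[src]) - len[idx]
      st <- floor(stats::runif(length(idx)) * mx)
      insert[idx] <- substring(hap$structural[src], st + 1L, st + len[idx])
    }
    # genome background from the decoy
    idx <- which(origin == "background")
    if (length(idx)) {
      pr <- length_probs(cfg$p24_background, cfg$p21_background)
      if (retain24 < 1) {
        pr["24"] <- pr["24"] * retain24
        pr <- pr / sum(pr)
      }
      len[idx] <- sample(18:30, length(idx), replace = TRUE, prob = pr)
      st <- floor(stats::runif(length(idx)) * (nchar(hap$decoy) - len[idx]))
      s <- substring(hap$decoy, st + 1L, st + len[idx])
      neg <- strand[idx] == "-"
      s[neg] <- revcomp(s[neg])
      insert[idx] <- s
    }

    raw <- if (lb$protocol == "umi4n") {
      umi1 <- vapply(seq_len(n), function(k)
        paste(sample(c("A", "C", "G", "T"), 4L, TRUE), collapse = ""),
        character(1))
      umi2 <- vapply(seq_len(n), function(k)
        paste(sample(c("A", "C", "G", "T"), 4L, TRUE), collapse = ""),
        character(1))
      paste0(umi1, insert, umi2, cfg$adapter)
    } else {
      paste0(insert, cfg$adapter)
    }
    ids <- sprintf("%s_r%06d", lb$name, seq_len(n))
    reads_out[[lb$name]] <- tibble(read_id = ids, read = raw,
                                   quality = strrep("I", nchar(raw)))
    truth_out[[lb$name]] <- tibble(library = lb$name, read_id = ids,
                                   origin = origin, length = len,
                                   strand = strand, start = start)
  }
  list(reads = reads_out, truth = bind_rows(truth_out))
}

#' Simulate 4C sequencing reads
#'
#' Proper amplicons are `forward primer - DpnII site - interacting fragment`
#' (49 bp total; the interacting fragment is genomic sequence starting at a
#' first-cutter site drawn from the interaction weights, which are enriched
#' at the tandem array and highest at the USR site). Decoy reads lack the
#' primer/cutter anchor. Constant high base qualities by default.
#'
#' @param hap a [generate_haplotype()] result.
#' @param depth number of reads (default `cfg$fourc$depth`).
#' @param seed RNG seed.
#' @return list with `reads` (tibble `read_id`, `read`, `quality`), `truth`
#'   (per proper read: the captured site, collapsed coordinates), `sites`
#'   (eligible sites and weights), and `config` (a matching
#'   [fourc_config()]).
#' @export
simulate_4c_reads <- function(hap, depth = hap$cfg$fourc$depth,
                              seed = hap$cfg$seed + 2L) {
  stopifnot(inherits(hap, "sim_haplotype"))
  set.seed(seed)
  fc <- hap$cfg$fourc
  cseq <- hap$collapsed$sequence
  t <- hap$truth
  ca <- hap$collapsed$arrays$collapsed_start[1]
  ul <- t$unit_length
  flen <- fc$fragment_len

  # eligible first-cutter sites: GATC followed by fragment clean of cutters
  gatc <- Biostrings::matchPattern("GATC", Biostrings::DNAString(cseq))
  pos0 <- Biostrings::start(gatc) - 1L
  pos0 <- pos0[pos0 + flen <= nchar(cseq)]
  frag <- substring(cseq, pos0 + 1L, pos0 + flen)
  clean <- !grepl("GATC|CATG|N", substring(frag, 2L))
  sites <- tibble(position = pos0[clean], fragment = frag[clean]) |>
    mutate(weight = dplyr::case_when(
      .data$position == t$fourc_usr_site ~ fc$weight_usr,
      .data$position >= ca & .data$position < ca + ul ~ fc$weight_array,
      .default = fc$weight_baseline))

  n <- as.integer(depth)
  proper <- stats::runif(n) < fc$proper_fraction
  np <- sum(proper)
  pick <- sample(nrow(sites), np, replace = TRUE, prob = sites$weight)
  primer <- paste0(fc$forward_pad, "TACGCCGGCGGAGCTC")
  reads <- character(n)
  reads[proper] <- paste0(primer, sites$fragment[pick])
  # decoys: random 49-mers verified to lack the anchor
  nd <- n - np
  if (nd > 0) {
    dec <- character(0)
    while (length(dec) < nd) {
      cand <- vapply(seq_len(nd - length(dec) + 10L),
                     function(k) random_dna(nchar(primer) + flen),
                     character(1))
      ok <- !adapter_contains(cand, "CTCGATC", 7L, 7L, 1L)
      dec <- c(dec, cand[ok])
    }
    reads[!proper] <- dec[seq_len(nd)]
  }
  ids <- sprintf("fourc_r%06d", seq_len(n))
  truth <- tibble(read_id = ids[proper], position = sites$position[pick])
  cfgq <- fourc_config(bait_position = t$bait_position,
                       read_length = nchar(primer) + flen)
  list(reads = tibble(read_id = ids, read = reads,
                      quality = strrep("I", nchar(reads))),
       truth = truth, sites = sites, config = cfgq)
}

#' Simulate conversion-treated methylation amplicon clones
#'
#' Per genotype, clones of a USR interval are drawn with per-context
#' Bernoulli methylation at the configured rates; unmethylated cytosines are
#' converted C to T except at the conversion-failure rate. Unmethylated
#' lambda-like control clones accompany each set.
#'
#' @param hap a [generate_haplotype()] result.
#' @param genotypes genotype labels to simulate (default: those configured).
#' @param seed RNG seed.
#' @return list with `reference` (interval sequence), `interval` (full
#'   coordinates), `clones` (named list per genotype), `lambda`
#'   (`reference`, `clones`), and `truth` rates.
#' @export
simulate_methyl_clones <- function(hap, genotypes = NULL,
                                   seed = hap$cfg$seed + 3L) {
  stopifnot(inherits(hap, "sim_haplotype"))
  set.seed(seed)
  mc <- hap$cfg$methyl
  genotypes <- genotypes %||% names(mc$rates)
  t <- hap$truth
  start <- t$usr_full[1] + mc$region_offset
  reference <- substr(hap$model$sequence, start + 1L,
                      start + mc$region_length)
  ctx <- classify_contexts(reference)
  convert_clone <- function(rates) {
    cc <- strsplit(reference, "")[[1]]
    meth_p <- ifelse(is.na(ctx$context), 0, rates[ctx$context])
    meth <- stats::runif(nrow(ctx)) < meth_p
    fail <- stats::runif(nrow(ctx)) < mc$conversion_failure
    conv <- !meth & !fail
    cc[ctx$position[conv] + 1L] <- "T"
    paste(cc, collapse = "")
  }
  clones <- lapply(setNames(genotypes, genotypes), function(g) {
    out <- vapply(seq_len(mc$n_clones), function(i) convert_clone(mc$rates[[g]]),
                  character(1))
    setNames(out, sprintf("%s_clone%02d", g, seq_len(mc$n_clones)))
  })
  lam_ref <- random_dna(150L)
  lam_ctx <- classify_contexts(lam_ref)
  lam_clones <- vapply(seq_len(mc$n_clones), function(i) {
    cc <- strsplit(lam_ref, "")[[1]]
    fail <- stats::runif(nrow(lam_ctx)) < mc$conversion_failure
    cc[lam_ctx$position[!fail] + 1L] <- "T"
    paste(cc, collapse = "")
  }, character(1))
  names(lam_clones) <- sprintf("lambda_clone%02d", seq_len(mc$n_clones))
  list(reference = reference,
       interval = c(start, start + mc$region_length),
       clones = clones,
       lambda = list(reference = lam_ref, clones = lam_clones),
       truth = mc$rates[genotypes])
}

#' Simulate a raw Ct table
#'
#' `Ct = baseline - log2(expression) + sample effect + noise`; the reference
#' amplicon is unaffected by group, and the sample effect is shared between
#' target and reference (cancelling in dCt). Designs: `"usr_expression"`
#' (one USR amplicon vs a housekeeping reference, true fold `usr_fold` in
#' the active vs repressed state) and `"mnase"` (four tiled USR amplicons vs
#' a reference gene, 2-fold nucleosome protection at the two central
#' amplicons).
#'
#' @param cfg a [sim_config()].
#' @param design `"usr_expression"` or `"mnase"`.
#' @param seed RNG seed.
#' @return list with `table` (tibble `sample`, `group`, `amplicon`,
#'   `replicate`, `ct`) and `truth` folds.
#' @export
simulate_ct_table <- function(cfg, design = c("usr_expression", "mnase"),
                              seed = cfg$seed + 4L) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- match.arg(design)
  set.seed(seed)
  q <- cfg$qpcr
  if (design == "usr_expression") {
    folds <- tibble(amplicon = "P3",
                    `Pl-Rh` = q$usr_fold, `Pl'` = 1)
    ref <- "gapdh"; base_t <- 28; base_r <- 20
  } else {
    folds <- tibble(amplicon = names(q$mnase_folds),
                    `Pl-Rh` = unname(q$mnase_folds), `Pl'` = 1)
    ref <- "alt4"; base_t <- 26; base_r <- 22
  }
  folds <- folds |>
    tidyr::pivot_longer(-"amplicon", names_to = "group", values_to = "expr")
  rows <- list()
  for (g in c("Pl-Rh", "Pl'")) {
    for (s in seq_len(q$n_samples)) {
      sample_id <- sprintf("%s_s%d", g, s)
      u <- stats::rnorm(1, 0, q$sample_sd)
      for (a in c(unique(folds$amplicon), ref)) {
        expr <- if (a == ref) 1 else
          folds$expr[folds$amplicon == a & folds$group == g]
        mu <- (if (a == ref) base_r else base_t) - log2(expr) + u +
          stats::rnorm(1, 0, q$ct_sd)
        rows[[length(rows) + 1L]] <- tibble(
          sample = sample_id, group = g, amplicon = a,
          replicate = seq_len(q$n_tech),
          ct = mu + stats::rnorm(q$n_tech, 0, q$tech_sd))
      }
    }
  }
  list(table = bind_rows(rows),
       truth = folds |> rename(fold = "expr"))
}
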