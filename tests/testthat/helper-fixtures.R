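# One shared simulated haplotype (default conditions, seed 1), built once per
# test run. Index caches warm up as tests use them.
.fixtures <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixtures$hap)) {
    cfg <- sim_config(seed = 1)
    .fixtures$cfg <- cfg
    .fixtures$hap <- generate_haplotype(cfg)
    .fixtures$idx <- build_sim_indexes(.fixtures$hap)
  }
  list(cfg = .fixtures$cfg, hap = .fixtures$hap, idx = .fixtures$idx)
}

# two groups x two samples, two amplicons, duplicate technical reps;
# constructed so ctrl dCt = 5.0 and case dCt = 4.0 exactly
toy_ct <- function() {
  tibble::tibble(
    sample = rep(c("s1", "s2", "s3", "s4"), each = 4),
    group = rep(c("ctrl", "ctrl", "case", "case"), each = 4),
    amplicon = rep(c("tgt", "tgt", "ref", "ref"), times = 4),
    replicate = rep(1:2, times = 8),
    ct = c(25.0, 25.2, 20.0, 20.2,     # s1: dct 5.0
           25.6, 25.4, 20.5, 20.5,     # s2: dct 5.0
           24.1, 23.9, 20.0, 20.0,     # s3: dct 4.0
           23.4, 23.6, 19.6, 19.4))    # s4: dct 4.0
}

# build a proper 4C amplicon read from a config and a genomic fragment
proper_4c_read <- function(fragment, cfg, pad = "ACTGGTCCA") {
  paste0(pad, cfg$left_trim_adapter, fragment)
}
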