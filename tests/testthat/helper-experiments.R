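# Memoised experiment runs shared across acceptance-style tests. Depths are
# chosen for test runtime; the generator's structural conditions are fixed.

acc_cob <- function() {
  if (!is.null(.fixtures$acc_cob)) return(.fixtures$acc_cob)
  fx <- sim_fixture()
  libs <- tibble::tibble(
    name = c(paste0("cob_plrh_", 1:3), paste0("cob_plp_", 1:3)),
    genotype = rep(c("Pl-Rh", "Pl'"), each = 3),
    tissue = "cob", depth = 1e5)
  sim <- simulate_srna_libraries(fx$hap, libs, seed = 101)
  pl <- run_srna_pipeline(sim, fx$hap, fx$idx, libs)
  cl <- call_clusters(pl$alignments)
  diff <- quantify_and_test(cl, pl$alignments[libs$name[1:3]],
                            pl$alignments[libs$name[4:6]])
  .fixtures$acc_cob <- list(libs = libs, pl = pl, cl = cl, diff = diff,
                            truth = sim$truth)
  .fixtures$acc_cob
}

acc_seedling <- function() {
  if (!is.null(.fixtures$acc_seedling)) return(.fixtures$acc_seedling)
  fx <- sim_fixture()
  libs <- tibble::tibble(
    name = c(paste0("sdl_plrh_", 1:3), paste0("sdl_plp_", 1:3)),
    genotype = rep(c("Pl-Rh", "Pl'"), each = 3),
    tissue = "seedling", depth = 5e4)
  sim <- simulate_srna_libraries(fx$hap, libs, seed = 102)
  pl <- run_srna_pipeline(sim, fx$hap, fx$idx, libs)
  cob <- acc_cob()
  diff <- quantify_and_test(cob$cl, pl$alignments[libs$name[1:3]],
                            pl$alignments[libs$name[4:6]])
  .fixtures$acc_seedling <- list(libs = libs, pl = pl, diff = diff)
  .fixtures$acc_seedling
}

acc_chd3a <- function() {
  if (!is.null(.fixtures$acc_chd3a)) return(.fixtures$acc_chd3a)
  fx <- sim_fixture()
  libs <- tibble::tibble(
    name = c("chd3a_het_1", "chd3a_het_2",
             "chd3a_mut_1", "chd3a_mut_2", "chd3a_mut_3"),
    genotype = c("chd3a_het", "chd3a_het",
                 "chd3a_mut", "chd3a_mut", "chd3a_mut"),
    tissue = "seedling", depth = 1e5)
  sim <- simulate_srna_libraries(fx$hap, libs, seed = 103)
  pl <- run_srna_pipeline(sim, fx$hap, fx$idx, libs)
  .fixtures$acc_chd3a <- list(libs = libs, pl = pl)
  .fixtures$acc_chd3a
}

# mean rpm over a region for a set of library alignments
region_rpm <- function(alignments, region) {
  vals <- vapply(alignments, function(a) {
    n <- sum(a$start < region[2] & a$start + a$length > region[1])
    1e6 * n / attr(a, "clean_total")
  }, numeric(1))
  mean(vals)
}

# total read count over a region (for Poisson sampling-error bounds)
region_count <- function(alignments, region) {
  sum(vapply(alignments, function(a) {
    sum(a$start < region[2] & a$start + a$length > region[1])
  }, numeric(1)))
}
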