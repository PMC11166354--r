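#' Build the standard index set for a simulated haplotype
#'
#' The genome index holds the collapsed haplotype plus the decoy background
#' (so shared-TE reads multi-map and are discarded at the first pass); the
#' target index holds the collapsed haplotype alone; the structural index
#' holds the rRNA/tRNA-like references.
#'
#' @param hap a [generate_haplotype()] result.
#' @return list with `genome`, `target`, `structural` ([build_index()]
#'   objects).
#' @export
build_sim_indexes <- function(hap) {
  stopifnot(inherits(hap, "sim_haplotype"))
  cseq <- setNames(hap$collapsed$sequence, hap$collapsed$name)
  list(genome = build_index(c(cseq, decoy = hap$decoy)),
       target = build_index(cseq),
       structural = build_index(hap$structural))
}

#' Run the small-RNA pipeline on simulated libraries
#'
#' Preprocesses each raw library (adapter trim, dedup, UMI removal, length
#' filter), removes structural reads, and maps with the two-pass cascade.
#'
#' @param sim output of [simulate_srna_libraries()].
#' @param hap the matching [generate_haplotype()] result.
#' @param indexes optional [build_sim_indexes()] result (rebuilt if absent).
#' @param libraries the library sheet used for the simulation (for
#'   genotype/tissue metadata); optional.
#' @return list with `libs` (clean [srna_library()] objects) and
#'   `alignments` (named list of alignment tibbles).
#' @export
run_srna_pipeline <- function(sim, hap, indexes = NULL, libraries = NULL) {
  indexes <- indexes %||% build_sim_indexes(hap)
  adapter <- hap$cfg$srna$adapter
  libs <- list()
  alns <- list()
  for (nm in names(sim$reads)) {
    meta <- if (!is.null(libraries)) libraries[libraries$name == nm, ] else NULL
    lib <- preprocess_srna(sim$reads[[nm]], adapter = adapter,
                           protocol = "umi4n", name = nm,
                           genotype = meta$genotype %||% NA_character_,
                           tissue = meta$tissue %||% NA_character_)
    lib <- filter_structural(lib, indexes$structural)
    libs[[nm]] <- lib
    alns[[nm]] <- map_srna_library(lib, indexes$genome, indexes$target)
  }
  list(libs = libs, alignments = alns)
}
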