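# shared fixtures: small cohorts built in code at test time

small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(
    n_samples = 48L, n_snps = 200L, n_probes = 200L, fraction_cis_eqtl = 0.3, seed = seed, ...))
}

# a tiny hand-built map with controllable provenance for attribution tests
toy_map <- function() {
  records <- data.frame(
    sample_id = c("A", "B", "C", "D"),
    expression_array = c("E1", "E2", "E3", "E4"),
    genotype_array = c("G1", "G2", "G3", "G4"),
    tissue = "normal", trusted = FALSE,
    stringsAsFactors = FALSE)
  prov <- rbind(
    data.frame(sample_id = c("A", "B", "C", "D"), platform = "expression",
               stage = "hybridization", stage_index = 1L,
               plate_id = "RNAC1", well = paste0("A", 1:4), position = 1:4,
               stringsAsFactors = FALSE),
    data.frame(sample_id = c("A", "B", "C", "D"), platform = "genotype",
               stage = "hybridization", stage_index = 1L,
               plate_id = c("DNAP1", "DNAP2", "DNAP1", "DNAP2"),
               well = c("A1", "A1", "B5", "C7"), position = c(1L, 97L, 10L, 120L),
               stringsAsFactors = FALSE))
  sample_map(records, provenance = prov)
}
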