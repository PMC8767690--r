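# a reduced configuration keeps generator-heavy tests fast while exercising
# every structural feature (fragmentation, full-length ERVs, planted TcGTs)
small_cfg <- function(seed = 1) {
  plan <- default_te_plan()
  plan$n_solo <- c(12L, 8L, 8L, 6L, 6L, 8L, 4L)
  plan$n_full <- c(2L, 0L, 0L, 0L, 1L, 0L, 0L)
  sim_config(seed = seed, genome = c(chr1 = 2e6, chr2 = 2e6),
             n_genes = 25L, te_plan = plan,
             tcgt_groups = c("g1", "g2"), tcgts_per_group = 5L,
             n_decoys = 12L, n_background_transcripts = 6L,
             peak_plan = list(n_peaks = 150L, n_replicates = 3L,
                              width = 200L, enriched_subfamily = "LTR12C",
                              enrichment_fraction = 0.4, jitter = 20L,
                              replicate_presence = 0.9),
             expr_plan = list(stages = c("oocyte", "zygote", "twocell",
                                         "fourcell", "eightcell", "morula"),
                              replicates = 2L, n_maternal = 6L, n_zga = 6L,
                              amplitude_log2 = 5, baseline_log2 = log2(50),
                              noise_sd = 0.1, nb_size = 100),
             methyl_plan = list(set_size = 8L, mean_a = 0.7, mean_b = 0.4,
                                locus_concentration = 10,
                                cpg_concentration = 30, cpg_spacing = 40L,
                                replicates = 2L))
}
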