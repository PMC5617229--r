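# shared fixtures for the suite: everything is generated in code

# n replicate wells of one strain at a given true copy number
replicate_wells <- function(n, true_cn, seed, config = assay_config(), ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_well(well_spec(true_cn, config = config,
                            seed = seed + i, sample_id = "rep",
                            well = sprintf("W%02d", i), ...))
  }))
}

# copy-number estimates for n independent single wells
replicate_estimates <- function(n, true_cn, seed, config = assay_config()) {
  lapply(seq_len(n), function(i) {
    quantify_sample(simulate_well(well_spec(true_cn, config = config,
                                            seed = seed + i)),
                    config = config)
  })
}

# layout for several pooled null plates: every mutant at the wild-type CN
null_screen_layout <- function(n_plates, n_controls, n_mutants, wt_cn = 150) {
  do.call(rbind, lapply(seq_len(n_plates), function(p) {
    l <- plate_layout_96(n_controls = n_controls,
                         mutant_cn = rep(wt_cn, n_mutants), wt_cn = wt_cn)
    l$well <- sprintf("P%02d_%s", p, l$well)
    l$strain <- sprintf("P%02d_%s", p, l$strain)
    l
  }))
}
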