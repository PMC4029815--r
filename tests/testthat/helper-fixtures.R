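# Small shared fixtures: a desk-scale grid/atlas and quick simulated runs.

tiny_grid <- function() acquisition_grid(c(12L, 12L, 6L))

tiny_atlas <- function(seed = 1L) make_atlas(tiny_grid(), seed = seed)

quiet_state <- function(...) {
  args <- utils::modifyList(
    list(amp_tenderness = 1, amp_pride = 1, noise_sd = 0, ar_coeff = 0,
         drift_slope = 0, learning_rate = 0, rng_seed = 42L),
    list(...))
  do.call(subject_state, args)
}

# short legal design: neutral/emotional alternation with small blocks
short_design <- function(n_cycles = 2, emo_len = 6L, neut_len = 4L,
                         start = "tenderness") {
  other <- setdiff(c("tenderness", "pride"), start)
  emo <- rep(c(start, other), length.out = 2 * n_cycles)
  cond <- as.vector(rbind("neutral", emo))
  block_design(data.frame(condition = cond,
                          n_volumes = ifelse(cond == "neutral",
                                             neut_len, emo_len)),
               tr_seconds = 2, start_condition = start)
}
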