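# round half away from zero; base round() is banker's rounding, which
# would make ms -> sample conversion depend on parity
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# milliseconds -> sample offset at rate fs
ms_to_samples <- function(ms, fs) {
  as.integer(round_half_up(ms * fs / 1000))
}
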