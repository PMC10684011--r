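# shared fixtures: scaled-down generator configs and bare epochs builders

small_channels <- c("C4", "CP4", "C6", "CP6", "Cz", "FC2", "CP2", "Fp1",
                    "M1", "M2")

small_cfg <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, rate = 500, n_tms = 30, n_sham = 0,
                   eeg_channels = small_channels,
                   noise_sd = list(eeg = 3, ecg = 10, emg = 5))
  defaults[names(args)] <- args
  do.call(synth_config, defaults)
}

# epochs object straight from an array (trials x channels x time)
make_epochs <- function(arr, times, rate, channels,
                        roles = infer_roles(channels),
                        meta = data.frame(onset_s = seq_len(dim(arr)[1]))) {
  cardiomotor:::new_epochs(arr, times, rate, "test", channels, roles, meta)
}

# single-channel recording helper
one_ch_rec <- function(x, rate, label = "Cz") {
  recording(matrix(x, 1), rate, channels = label)
}
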