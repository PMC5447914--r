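# shared fixtures, all built in code

# reduced-grid study configuration: same sample structure, fewer wavelengths,
# so unit tests stay fast while exercising the full pipeline
small_config <- function(n_grid = 160) {
  sim_config(wavelengths = default_grid(n_grid))
}

# tiny hand-made spectra tibble
toy_spectra <- function(m, wl = seq(1000, by = 2, length.out = ncol(rbind(m))),
                        ...) {
  spectra_tbl(rbind(m), wl, sample_id = paste0("T", seq_len(nrow(rbind(m)))),
              ...)
}

# the seven selected wavelengths of the published model
wl7 <- c(1155, 1212, 1340, 1409, 1724, 1908, 2249)
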