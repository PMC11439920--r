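# Shared fixtures: small multi-subject cells with a known latent and mixing.

# one design cell: M subjects, a common band-limited latent, unit-norm random
# mixing per subject, optional band-pass of the summed recordings
make_cell <- function(M, snr, n_channels = 16, duration_s = 30, fs = 100,
                      seed = 1, bandpassed = FALSE) {
  lat <- make_latent_signal(duration_s, fs, c(0.5, 10), seed = seed)
  mix <- lapply(seq_len(M), function(i) {
    set.seed(seed * 1000 + i)
    g <- rnorm(n_channels)
    g / sqrt(sum(g^2))
  })
  recs <- lapply(seq_len(M), function(i) {
    m <- synthesize_subject(lat, mix[[i]], snr, noise_seed = seed * 100 + i)
    if (bandpassed) bandpass(m, fs) else m
  })
  names(recs) <- sprintf("s%02d", seq_len(M))
  list(recs = recs, latent = lat, mixing = mix)
}

# pure white-noise subject matrices (no latent at all)
make_noise_cell <- function(M, n_channels, t_len, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(M), function(i) matrix(rnorm(n_channels * t_len), n_channels))
  names(recs) <- sprintf("s%02d", seq_len(M))
  recs
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
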