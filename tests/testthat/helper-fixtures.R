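# Small cohort design for fast end-to-end tests.
tiny_config <- function(seed = 1, ...) {
  cohort_config(
    organs = list(
      colon   = list(patients = 3, n_normal = 5, n_tumour = 5),
      stomach = list(patients = 3, n_normal = 5, n_tumour = 5),
      rectum  = list(patients = 2, n_normal = 3, n_tumour = 3)),
    replicate_count = 2, seed = seed, ...)
}

# Metadata frame for ad-hoc blocks.
make_meta <- function(n, organ = "colon", classes = rep(c("N", "T"), length.out = n)) {
  data.frame(position = sprintf("%s_%03d", organ, seq_len(n)),
             patient = sprintf("%s_P%02d", organ, rep(1:3, length.out = n)),
             organ = organ, class = classes, stringsAsFactors = FALSE)
}

# Structure-free Gaussian-noise block with arbitrary channel count.
noise_block <- function(n, p, modality = "mir", seed = 1,
                        classes = rep(c("N", "T"), length.out = n)) {
  set.seed(seed)
  spectra_block(matrix(rnorm(n * p), n, p), seq_len(p) + 100, modality,
                make_meta(n, classes = classes))
}
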