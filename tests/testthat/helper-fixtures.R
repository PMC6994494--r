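# Shared fixtures: everything is generated in code at test time.

# A pure-noise movie: Poisson counts around a constant rate, no particles.
poisson_movie <- function(rate = 10, n_frames = 300, shape = c(16L, 16L),
                          seed = 1) {
  set.seed(seed)
  frames <- array(rpois(prod(shape) * n_frames, rate),
                  c(shape[1], shape[2], n_frames))
  nb_movie(frames, acquisition_config(n_frames, shape, 0.121, 13.5 / 64))
}

# Build a moment-map object directly from a given ratio image (unit tests of
# the frequency/profile logic need full control of the ratio values).
manual_map <- function(ratio_img, valid = !is.na(ratio_img),
                       pixel_size = 0.1) {
  structure(
    list(mean_img = matrix(10, nrow(ratio_img), ncol(ratio_img)),
         var_img = ratio_img * 10, ratio_img = ratio_img,
         valid_mask = valid, segment_range = c(1L, 2L),
         pixel_size = pixel_size),
    class = "nb_moment_map"
  )
}

# A uniform synthetic movie with hand-set ROI intensities per frame, for
# FRAP extraction arithmetic.
flat_movie <- function(values, timestamps, shape = c(8L, 8L)) {
  frames <- array(rep(values, each = prod(shape)),
                  c(shape[1], shape[2], length(values)))
  acq <- acquisition_config(length(values), shape, 0.121, 0.1)
  nb_movie(frames, acq, timestamps)
}

quick_acq <- function(n_frames, shape = c(32L, 32L)) {
  acquisition_config(n_frames, shape, 0.121, 13.5 / 64)
}
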