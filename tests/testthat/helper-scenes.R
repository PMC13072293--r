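# shared fixture builders: every fixture is generated in code at test time

# compact sample-ladder scene (smaller wells than the default bench)
small_sample_scene <- function(seed = 1L, well_radius = 14L) {
  render_sample_scene(sample_scene_spec(well_radius = well_radius), seed = seed)
}

# compact surgical scene spec for transfer-style tests
small_surgical_spec <- function(...) {
  surgical_scene_spec(image_size = c(120L, 160L), n_blobs = 2L,
                      blob_peaks = c(5, 1), blob_sigma = c(8, 16),
                      n_reflections = 2L, reflection_radius = c(3, 5),
                      dark_fraction = 0.3, ...)
}

# features of the pixels of a scene under a ground-truth condition mask
scene_features <- function(scene, mask) {
  idx <- which(mask)
  extract_features(scene$frame[, , 1][idx],
                   scene$frame[, , 2][idx],
                   scene$frame[, , 3][idx])
}

conc_map <- function(scene) scene$truth$concentration_map

# quick clVAE training config for tests (cycle length stays even)
test_vae_config <- function(epochs = 80L, cycles = 10L, ...) {
  vae_config(epochs = epochs, cycles = cycles, ...)
}

# brute-force AUC: tie-adjusted pairwise comparison probability
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# synthetic 10-d "normal" features clustered near a point in [0, 1]^10
toy_normal_features <- function(n, center = 0.3, sd = 0.03, seed = 1L) {
  set.seed(seed)
  matrix(pmin(pmax(stats::rnorm(n * 10, center, sd), 0), 1), n, 10,
         dimnames = list(NULL, pixel_feature_names))
}
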