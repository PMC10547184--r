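# Shared fixtures: small scenes and a reduced model so tests stay fast.

tiny_scene_params <- function(seed = 1L, ...) {
  defaults <- list(image_height = 96L, image_width = 96L,
                   n_nuclei_range = c(3L, 5L),
                   nucleus_radius_range = c(8, 14),
                   eccentricity_range = c(0, 0.5),
                   overlap_fraction = 0,
                   border_truncation_prob = 0,
                   impurity_count_range = c(0L, 2L),
                   blur_sigma_range = c(0.4, 0.8),
                   noise_sigma_range = c(0.003, 0.01),
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}

# noiseless, blur-free params so rendering is exactly Beer-Lambert
clean_scene_params <- function(seed = 1L, ...) {
  tiny_scene_params(seed = seed, blur_sigma_range = c(0, 0),
                    noise_sigma_range = c(0, 0),
                    impurity_count_range = c(0L, 0L), ...)
}

# reduced network used throughout the model tests
reduced_model <- function(seed = 3L, dropout = 0, n_layers = 3L) {
  cunet_model(
    encoder_config(levels = 7L, base_channels = 8L, channel_cap = 64L,
                   dropout_rate = dropout),
    csfi_config(n_layers = n_layers, fpn_channels = 16L),
    wcu_config(7L), seed = seed)
}

# smoke-training study conditions: 64 x 64 fields with 2-3 large nuclei
smoke_scene <- function(seed) {
  generate_scene(scene_params(
    image_height = 64L, image_width = 64L, n_nuclei_range = c(2L, 3L),
    nucleus_radius_range = c(14, 22), eccentricity_range = c(0, 0.5),
    overlap_fraction = 0, border_truncation_prob = 0,
    impurity_count_range = c(0L, 1L), blur_sigma_range = c(0.4, 0.7),
    noise_sigma_range = c(0.003, 0.008), seed = seed))
}

random_prob_map <- function(h, w) matrix(stats::runif(h * w), h, w)
random_binary_map <- function(h, w) matrix(stats::rbinom(h * w, 1, 0.5), h, w)
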