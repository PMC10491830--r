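# Shared fixtures: small, fast scene configurations for module tests.

small_scene_params <- function(target = 0.3, seed = 1, noise_sd = 0, ...) {
  scene_params(geometry = c(96L, 128L), target_colonization = target,
               noise_sd = noise_sd, seed = seed, ...)
}

# uniform grayscale frame
flat_gray <- function(value, h = 16, w = 16) {
  matrix(as.numeric(value), h, w)
}

# annotation set sampled from the ground truth of n sibling scenes
scene_annotations <- function(n_scenes, params_fn, n_per_class = 100,
                              seed_base = 100) {
  scenes <- lapply(seq_len(n_scenes), function(i)
    generate_scene(params_fn(seed_base + i)))
  anns <- lapply(seq_along(scenes), function(i)
    annotate_from_scene(scenes[[i]], n_per_class = n_per_class,
                        seed = seed_base + 50 + i))
  annotation_set(lapply(anns, `[[`, "image"),
                 lapply(anns, `[[`, "labels"))
}
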