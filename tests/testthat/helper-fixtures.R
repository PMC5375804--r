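# shared fixtures, all generated in code

default_protocol <- function() acquisition_protocol()

toy_protocol <- function() {
  # 5 s heat + 10 s cool at 1 fps, no buffers: 15-frame traces
  acquisition_protocol(front_buffer_s = 0, heat_s = 5, cool_s = 10,
                       rear_buffer_s = 0, fps = 1)
}

noiseless_config <- function(specs, h = 30, w = 30, fps = 10, seed = 1) {
  dataset_config(class_specs = specs, samples_per_class = 1,
                 protocol = acquisition_protocol(1, 5, 10, 1, fps),
                 frame_height = h, frame_width = w,
                 noise_sd = 0, background_temp = 25, seed = seed)
}

plain_spec <- function(name = "blobby", geometry = "blob",
                       size_range = c(10, 12), gain = 30, tau_heat = 2,
                       tau_cool = 4, jitter = 0, edge = 1, sample_cv = 0) {
  class_spec(name, geometry, size_range,
             material_params(ambient_temp = 25, gain = gain,
                             tau_heat = tau_heat, tau_cool = tau_cool,
                             pixel_jitter_cv = jitter,
                             edge_cooling_factor = edge),
             sample_cv = sample_cv)
}

# small gaussian-blob feature table for the stats/classify tests
gaussian_feature_table <- function(means, n_per = 20, p = 2, sd = 1,
                                   seed = 42) {
  set.seed(seed)
  rows <- lapply(seq_along(means), function(i) {
    x <- matrix(rnorm(n_per * p, 0, sd), n_per, p)
    x <- sweep(x, 2, rep_len(means[[i]], p), "+")
    df <- tibble::as_tibble(as.data.frame(x),
                            .name_repair = ~ paste0("f", seq_len(p)))
    df$class <- names(means)[i]
    df
  })
  dplyr::bind_rows(rows)
}
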