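# memoized small phantoms shared across test files (deterministic)

.phantom_cache <- new.env(parent = emptyenv())

small_phantom_config <- function(...) {
  phantom_config(grid_dim = c(128, 24, 160), voxel_size_um = 50,
                 mesh_nx = 48, mesh_ny = 10, ...)
}

small_phantom <- function(key = "default", ...) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(small_phantom_config(...))
  .phantom_cache[[key]]
}

# phantom smoothed with the default anisotropic configuration
small_phantom_smoothed <- function() {
  if (is.null(.phantom_cache[["sm"]]))
    .phantom_cache[["sm"]] <- anisotropic_smooth(small_phantom()$volume,
                                                 smoothing_config())
  .phantom_cache[["sm"]]
}

small_detection <- function() {
  if (is.null(.phantom_cache[["det"]])) {
    ph <- small_phantom()
    .phantom_cache[["det"]] <- detect_layers(small_phantom_smoothed(),
                                             ph$pair, ph$classification)
  }
  .phantom_cache[["det"]]
}
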