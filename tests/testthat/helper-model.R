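# Desk-scale training conditions shared by the learning and end-to-end
# tests: 200 synthetic patches, a width-multiplier-0.125 network on 32 x 32
# inputs, up to 30 epochs. Trained once per test run and reused.
desk_model_config <- function() {
  model_config(input_size = c(32L, 32L), width_multiplier = 0.125)
}

desk_train_once <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set <- generate_patchset(scene_params(seed = 1), n_per_class = 100L,
                             seed = 11)
    halves <- split_train_val(set, val_fraction = 0.2, seed = 5)
    # two augmented copies per training patch: rotation/zoom/photometric
    # variety bridges centred annotation crops and off-centre superpixel
    # fragments seen at inference
    set.seed(8)
    aug <- augment_params(zoom_range = c(0.5, 1.5))
    extra <- list()
    for (p in halves$train$patches)
      for (k in 1:2) extra[[length(extra) + 1L]] <- augment(p, aug)
    train_set <- new_patchset(c(halves$train$patches, extra))
    model <- build_model(desk_model_config(), seed = 3)
    model <- train_model(model, train_set, halves$val,
                         train_config(epochs = 30L, learning_rate = 1e-3,
                                      batch_size = 16L, seed = 7,
                                      target_val_accuracy = 0.985))
    cache <<- model
    model
  }
})

# The sparse non-overlapping fixture family (20 scenes).
sparse_family <- function(n = 20L) {
  lapply(seq_len(n), function(i) generate_scene(sparse_scene_params(i)))
}

cnn_scene_count <- function(model, scene, n_superpixels = 200L) {
  map <- slic_segment(scene$image, slic_params(n_superpixels))
  regions <- extract_regions(scene$image, map)
  maps <- lapply(regions, function(r) predict_region(model, r))
  prob <- stitch_predictions(regions, maps, dim(scene$image)[1:2])
  count_ears(binarize(prob))$count
}
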