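# Shared expensive fixtures, built lazily and cached for the whole test run.
# The stated desk-scale world: four heterogeneous synthetic cores of
# (100, 64, 64) -> ~400 surrogate-annotated slices, mini model, 80/20 split,
# early stopping. Training target is the soil-matrix band (class 3).

.fixtures <- new.env(parent = emptyenv())

fixture_volumes <- function() {
  if (is.null(.fixtures$vols))
    .fixtures$vols <- lapply(1:4, function(i)
      generate_volume(synthetic_spec("heterogeneous", seed = i))$volume)
  .fixtures$vols
}

fixture_split <- function(target_classes = 3L) {
  key <- paste0("split_", paste(target_classes, collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    ds <- assemble_dataset(fixture_volumes(), target_classes)
    .fixtures[[key]] <- split_dataset(ds, 0.8, seed = 42)
  }
  .fixtures[[key]]
}

fixture_train_config <- function(sp, seed = 11L) {
  train_config(epochs = 25L, batch_size = 32L, lr = 1e-3, patience = 8L,
               seed = seed, validation = sp$test)
}

# base model trained on class-3 porosity; reused by the training, transfer
# and grad-CAM acceptance criteria
fixture_base_fit <- function() {
  if (is.null(.fixtures$base_fit)) {
    sp <- fixture_split(3L)
    model <- build_model(dim(sp$train$x)[2:3], "mini", seed = 1L)
    .fixtures$base_fit <- train(model, sp$train, fixture_train_config(sp))
  }
  .fixtures$base_fit
}
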