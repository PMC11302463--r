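# The learnability experiment shared by the training and feature-importance
# acceptance checks: a noiseless 200-protein rule dataset (mirror-image
# helices + sequence motif) and a small model trained on it once per test
# session.

rule_experiment_config <- function() {
  model_config(d_model = 64, n_heads = 4, n_gvp_layers = 2,
               n_encoder_layers = 1, n_decoder_layers = 1,
               k_neighbors = 8, d_esm = 32, gvp_scalar_channels = 32,
               gvp_vector_channels = 4, d_ffn = 128,
               learning_rate = 1e-3, batch_size = 8, epochs = 30,
               patience = 10, seed = 101)
}

rule_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_synthetic_dataset(synthetic_spec(n_proteins = 200,
                                                  seed = 11))
      model <- gvpgo_train(ds, rule_experiment_config(), min_proteins = 10)
      prop <- propagate_annotations(ds$annotations, ds$dag)
      cache <<- list(dataset = ds, model = model, prop_ann = prop,
                     ic = information_content(prop, ds$dag))
    }
    cache
  }
})

split_truth <- function(exp, split) {
  ids <- names(exp$dataset$splits)[exp$dataset$splits == split]
  annotation_set(exp$prop_ann$annotations[ids], propagated = TRUE)
}

split_predictions <- function(exp, split) {
  ids <- names(exp$dataset$splits)[exp$dataset$splits == split]
  bundles <- gvpgo:::featurize_all(exp$dataset$structures[ids],
                                   exp$dataset$embeddings[ids],
                                   exp$model$config)
  propagate_predictions(predict(exp$model, bundles), exp$dataset$dag)
}
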