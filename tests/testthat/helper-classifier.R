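# Shared small trained classifier: tiny encoder driven to 100% training
# accuracy on the cue-word-separable fixture set. Trained once per test run.
separable_training_set <- function() make_separable_re_set(10L, seed = 7L)

trained_tiny_classifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_classifier(
        separable_training_set(), encoder_preset("tiny"),
        train_config(epochs = 30L, learning_rate = 1e-3,
                     optimizer = "adam", seed = 11L, batch_size = 8L))
    }
    cache
  }
})
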