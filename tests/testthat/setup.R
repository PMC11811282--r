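# Expensive shared fixtures, built once per test run: the desk-scale
# study with its trained model, assimilation trace of the regime-switch
# stream, condition-latent repertoire and discriminator.

DESK <- desk_study(seed = 1)
DESK_MODEL <- vrnn_model(DESK$spec, seed = 1)
DESK_MODEL <- train_vrnn(DESK_MODEL, DESK$train,
                         n_updates = DESK$n_updates,
                         trace_every = 2000, seed = 1)
DESK_REF <- training_reference(DESK_MODEL, DESK$train)
DESK_TRACE <- assimilate(DESK_MODEL, DESK$transition,
                         assimilation_config(H = DESK$H, K = DESK$K,
                                             seed = 1))

desk_all_sequences <- local({
  out <- list()
  for (ind in names(DESK$cohort$pools))
    for (cond in c("awake", "anesthetized"))
      for (sq in DESK$cohort$pools[[ind]][[cond]])
        out <- c(out, list(preprocess_sequence(sq)))
  out
})
DESK_STACKS <- build_stacks(desk_all_sequences,
                            segment_ms = DESK$disc$segment_ms,
                            fmax = DESK$disc$fmax)
DESK_CLF <- train_discriminator(DESK_STACKS$stacks, DESK_STACKS$labels,
                                n_filters = DESK$disc$n_filters,
                                kernel = DESK$disc$kernel,
                                n_updates = DESK$disc$n_updates,
                                spect_params = DESK_STACKS$spect_params,
                                seed = 1)

DESK_TEST_SEQS <- c(lapply(DESK$cohort$pools$I1$awake[5],
                           preprocess_sequence),
                    lapply(DESK$cohort$pools$I1$anesthetized[5],
                           preprocess_sequence),
                    lapply(DESK$cohort$pools$I2$awake[1],
                           preprocess_sequence),
                    lapply(DESK$cohort$pools$I2$anesthetized[1],
                           preprocess_sequence))
DESK_REP <- estimate_condition_latents(DESK_MODEL, DESK_TEST_SEQS,
                                       n_updates = 1500, seed = 1)
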