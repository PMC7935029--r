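# Small cohorts and models used by the harness tests (kept tiny for speed).

tiny_cohort <- function(seed = 1, n_classes = 2, n_sites = 1,
                        group_effect = 0.4, n_subjects = 8,
                        site_effect = 0) {
  generate_cohort(cohort_spec(
    n_subjects = n_subjects, n_sessions_per_subject = 2, n_rois = 20,
    n_frames = 80, n_networks = 2, within_network_corr = 0.4,
    fingerprint_strength = 0.1, group_effect = group_effect,
    n_classes = n_classes, n_sites = n_sites, site_effect = site_effect,
    seed = seed))
}

tiny_config <- function(n_classes = 2, ...) {
  cgcn_config(n_conv_layers = 2, features_per_layer = c(4, 8),
              n_classes = n_classes, node_pool = "flatten",
              l2_lambda = 0.001, ...)
}

tiny_train_config <- function(seed = 1, max_epochs = 4, clip_length = 20) {
  train_config(clip_length = clip_length, batch_size = 8,
               max_epochs = max_epochs, initial_lr = 0.01, seed = seed)
}

# build a trained-ish tiny model without real training (random weights)
tiny_model <- function(graph = build_random_graph(20, 3, seed = 5),
                       n_classes = 2, seed = 2, ...) {
  new_cgcn_model(tiny_config(n_classes = n_classes, ...), graph,
                 paste0("class", seq_len(n_classes)), seed = seed)
}

random_clip <- function(t_len = 10, n = 20, seed = 3) {
  set.seed(seed)
  matrix(rnorm(t_len * n), t_len, n)
}
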