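# shared fixtures and independent oracles for the suite

all_builtin_rulesets <- function() {
  list(ro5 = builtin_ruleset("ro5"),
       ro5_no_lower = builtin_ruleset("ro5", ro5_logp_lower = FALSE),
       bro5 = builtin_ruleset("bro5"),
       muegge_core6 = builtin_ruleset("muegge"),
       muegge_full = builtin_ruleset("muegge", muegge_variant = "full"))
}

# independent brute-force oracle: explicit per-criterion indicator loop
oracle_count <- function(dv, rs) {
  total <- 0L
  for (i in seq_len(nrow(rs$criteria))) {
    cr <- rs$criteria[i, ]
    x <- dv[[cr$descriptor_key]]
    violated <- FALSE
    if (!is.na(cr$lower) && x < cr$lower) violated <- TRUE
    if (!is.na(cr$upper) && x > cr$upper) violated <- TRUE
    if (violated) total <- total + 1L
  }
  total
}

random_descriptor_vector <- function() {
  ranges <- default_descriptor_ranges()
  dv <- vapply(names(ranges), function(k) {
    r <- ranges[[k]]
    stats::runif(1, r[1] - 10, r[2] + 10)   # deliberately overshoot ranges
  }, 0)
  names(dv) <- names(ranges)
  dv
}

# small labelled dataset for model tests (stratified so every class occurs)
small_ro5_dataset <- function(n = 1000L, seed = 3L) {
  cfg <- sampler_config(n, seed = seed, stratify_rule = "ro5")
  build_dataset_from_descriptor_table(sample_descriptor_vectors(cfg),
                                      builtin_ruleset("ro5"))
}

# shared cache so the study-scale datasets/models are built once per run
acc_cache <- new.env(parent = emptyenv())

acc_parts <- function(rule, n = 200000L, sampler_seed = 7L) {
  key <- paste0(rule, "_", n, "_", sampler_seed)
  if (is.null(acc_cache[[key]])) {
    rs <- builtin_ruleset(rule)
    cfg <- sampler_config(n, seed = sampler_seed, stratify_rule = rs)
    ds <- build_dataset_from_descriptor_table(
      sample_descriptor_vectors(cfg), rs)
    acc_cache[[key]] <- split_dataset(ds, split_spec(0.2, 42L))
  }
  acc_cache[[key]]
}

acc_classifier <- function(rule, n_trees, n = 200000L, sampler_seed = 7L) {
  key <- paste0("clf_", rule, "_", n_trees, "_", n, "_", sampler_seed)
  if (is.null(acc_cache[[key]])) {
    parts <- acc_parts(rule, n, sampler_seed)
    acc_cache[[key]] <- train_model(
      parts$train, model_spec("classifier", rule, n_trees = n_trees,
                              seed = 1L))
  }
  acc_cache[[key]]
}

# rows of a descriptor table farther than delta = 0.5% of each sampled range
# from every threshold the rule references
off_margin_rows <- function(features, rs,
                            ranges = default_descriptor_ranges()) {
  ok <- rep(TRUE, nrow(features))
  for (i in seq_len(nrow(rs$criteria))) {
    cr <- rs$criteria[i, ]
    delta <- 0.005 * diff(ranges[[cr$descriptor_key]])
    x <- features[[cr$descriptor_key]]
    if (!is.na(cr$lower)) ok <- ok & abs(x - cr$lower) > delta
    if (!is.na(cr$upper)) ok <- ok & abs(x - cr$upper) > delta
  }
  ok
}
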