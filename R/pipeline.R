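# End-to-end orchestration: ingest -> first-pass measures + filters ->
# observer entropies (both priors) -> LM features -> assembly and
# standardization -> cross-validated fits for every model combination ->
# variation partitions -> bootstrap statistics -> effect sizes -> observer
# comparison.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions: perceptual span sigma = 3 and
#' Lambda = 1, observer T = 50 samples averaged over 3 repeats, nucleus
#' mass 0.95, 10 cross-validation folds, 1e4 bootstrap resamples, launch
#' cap 24 characters and a 70-900 ms gaze-duration window.
#'
#' @param ... overrides of the defaults.
#' @return list of class `readobs_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(sigma = 3, Lambda = 1, noise_exponent = -0.5,
              T_samples = 50L, repeats = 3L, nucleus_mass = 0.95,
              k_folds = 10L, n_boot = 1e4L, max_launch = 24,
              gaze_window = c(70, 900), conf_level = 0.95,
              grouping_skipping = "fig2", grouping_duration = "fig3",
              compare_priors = TRUE, master_seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_readobs(paste("unknown config field(s):", paste(bad, collapse = ", ")),
                 "readobs_bad_config")
  cfg[names(over)] <- over
  structure(cfg, class = "readobs_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml (requires the yaml package) or
#'   .json.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_readobs("yaml package not available; use a JSON config",
                   "readobs_bad_config")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

# Explanation-set presets. Membership follows the main grouping
# descriptions: fig2 skipping contrasts prediction / preview / oculomotor;
# fig3 durations contrasts prediction / preview / non-contextual baseline;
# fig4 contrasts purely oculomotor vs lexical-processing sets, with a
# variant adding word length to the oculomotor duration set.
grouping_sets <- function(preset, table) {
  wc <- grep("^word_class_", names(table), value = TRUE)
  switch(preset,
    fig2 = list(prediction = "predictive_entropy",
                preview = "parafoveal_entropy",
                oculomotor = c("length", "launch_distance")),
    fig3 = list(prediction = c("surprisal", "surprisal_lag1",
                               "surprisal_lag2"),
                preview = "parafoveal_entropy",
                noncontextual = c(wc, "length", "log_frequency",
                                  "log_frequency_lag1", "log_frequency_lag2",
                                  "landing_offset_chars",
                                  "landing_offset_frac")),
    fig4_skipping = list(
      oculomotor = c("length", "launch_distance"),
      lexical = c("predictive_entropy", "parafoveal_entropy")),
    fig4_durations = list(
      oculomotor = c("landing_offset_chars", "landing_offset_frac"),
      lexical = c("surprisal", "surprisal_lag1", "surprisal_lag2",
                  "parafoveal_entropy", "log_frequency",
                  "log_frequency_lag1", "log_frequency_lag2", wc)),
    fig4_durations_with_length = list(
      oculomotor = c("landing_offset_chars", "landing_offset_frac",
                     "length"),
      lexical = c("surprisal", "surprisal_lag1", "surprisal_lag2",
                  "parafoveal_entropy", "log_frequency",
                  "log_frequency_lag1", "log_frequency_lag2", wc)),
    stop_readobs(sprintf("unknown grouping preset '%s'", preset),
                 "readobs_bad_config"))
}

# full-model predictor list per analysis (union of all sets)
full_model_predictors <- function(analysis, table) {
  preset <- if (analysis == "skipping") "fig2" else "fig3"
  unlist(grouping_sets(preset, table), use.names = FALSE)
}

#' Partition cross-validated variation for every participant
#'
#' @param table standardized analysis table (all participants).
#' @param outcome outcome column (`"skip"` or `"gaze_duration"`).
#' @param sets named list of predictor sets (2 or 3).
#' @param family model family.
#' @param k_folds,master_seed CV settings; fold seeds are shared across
#'   the model combinations of a participant.
#' @return data.frame: participant, partition, value, plus attribute
#'   `joint` (per-participant joint scores).
#' @export
partition_by_participant <- function(table, outcome, sets,
                                     family = "gaussian", k_folds = 10L,
                                     master_seed = 1L) {
  parts <- list(); scores <- list(); joint <- c()
  for (pp in unique(table$participant)) {
    tab <- table[table$participant == pp, , drop = FALSE]
    seed <- derive_seed(master_seed, "cv", pp)
    sc <- score_model_combinations(tab, outcome, sets, family, k_folds, seed)
    pr <- if (length(sets) == 2L)
      partition_two(sc[["A"]], sc[["B"]], sc[["AB"]], names(sets))
    else partition_three(sc, names(sets))
    df <- pr$partitions
    df$participant <- pp
    parts[[length(parts) + 1L]] <- df
    scores[[length(scores) + 1L]] <- data.frame(
      participant = pp, model_label = names(sc),
      metric = if (family == "binomial") "mcfadden_r2" else "r2",
      score = unname(sc), n_rows = nrow(tab), stringsAsFactors = FALSE)
    joint[as.character(pp)] <- pr$joint
  }
  out <- as.data.frame(data.table::rbindlist(parts))
  attr(out, "joint") <- joint
  attr(out, "scores") <- as.data.frame(data.table::rbindlist(scores))
  out
}

#' Run the full analysis pipeline on a corpus
#'
#' @param corpus list with `words` and `fixations` (canonical schema), as
#'   from [read_corpus()] or [generate_study()]`$corpus`.
#' @param lexicon a `readobs_lexicon`.
#' @param lm_features per-text-token table with `surprisal_bits`,
#'   `entropy_bits` and (for the contextual observer) a `nucleus`
#'   list-column of named probability vectors, e.g. from
#'   [lm_token_features()] or [read_nucleus()].
#' @param config a [pipeline_config()].
#' @return report list: exclusion log, observer tables, partitions and
#'   bootstrap tests per analysis, effect sizes, and (when nuclei are
#'   available and `compare_priors` is set) the contextual vs
#'   non-contextual observer comparison.
#' @export
run_pipeline <- function(corpus, lexicon, lm_features,
                         config = pipeline_config()) {
  span <- perceptual_span(config$sigma, config$Lambda, config$noise_exponent)
  ocfg <- observer_config(config$T_samples, config$repeats)

  measures <- first_pass_measures(corpus$fixations, corpus$words)
  filtered <- apply_exclusions(measures, config$max_launch,
                               config$gaze_window[1], config$gaze_window[2],
                               lexicon)

  tokens <- filtered$skipping[, c("participant", "text_id", "word_index",
                                  "word", "launch_distance")]
  freq_prior <- frequency_prior_logodds(lexicon)
  obs_freq <- observe_tokens(tokens, lexicon, span, ocfg, freq_prior,
                             config$master_seed)

  have_nucleus <- "nucleus" %in% names(lm_features)
  obs_ctx <- NULL
  if (have_nucleus && isTRUE(config$compare_priors)) {
    key <- paste(lm_features$text_id, lm_features$word_index)
    nuc_of <- match(paste(tokens$text_id, tokens$word_index), key)
    # contextual prior of token i: nucleus of its own position (the
    # distribution predicting this word from its context)
    prior_fun <- function(i) build_contextual_prior(
      lm_features$nucleus[[nuc_of[i]]], lexicon, config$nucleus_mass)
    obs_ctx <- observe_tokens(tokens, lexicon, span, ocfg, prior_fun,
                              config$master_seed)
  }

  tabs <- assemble_predictors(filtered, obs_freq, lm_features, lexicon)
  skip_std <- standardize_within_participant(tabs$skipping)
  dur_std <- standardize_within_participant(tabs$duration)

  skip_sets <- grouping_sets(config$grouping_skipping, skip_std)
  dur_sets <- grouping_sets(config$grouping_duration, dur_std)
  skip_parts <- partition_by_participant(
    skip_std, "skip", skip_sets, "binomial", config$k_folds,
    config$master_seed)
  dur_parts <- partition_by_participant(
    dur_std, "gaze_duration", dur_sets, "gaussian", config$k_folds,
    config$master_seed)

  boot_of <- function(parts, tag) {
    out <- list()
    for (lbl in unique(parts$partition)) {
      v <- parts$value[parts$partition == lbl]
      out[[lbl]] <- if (length(v) >= 2 && stats::sd(v) > 0)
        bootstrap_t_test(v, config$n_boot,
                         derive_seed(config$master_seed, "boot", tag, lbl),
                         config$conf_level)
      else NULL
    }
    out
  }

  effects <- effect_sizes(dur_std, tabs$duration, obs_freq,
                          config$master_seed, config$k_folds)

  comparison <- NULL
  if (!is.null(obs_ctx)) {
    comparison <- compare_prior_fits(tabs, filtered, obs_ctx, lm_features,
                                     lexicon, config)
  }

  list(exclusions = filtered$log,
       observer = list(noncontextual = obs_freq, contextual = obs_ctx),
       tables = list(skipping = skip_std, duration = dur_std),
       partitions = list(skipping = skip_parts, duration = dur_parts),
       bootstrap = list(skipping = boot_of(skip_parts, "skip"),
                        duration = boot_of(dur_parts, "dur")),
       effect_sizes = effects,
       observer_comparison = comparison,
       config = config)
}

# per-participant full-duration-model coefficients (OLS on standardized
# predictors) -> preview and predictability benefits in ms.
effect_sizes <- function(dur_std, dur_raw, obs_freq, master_seed, k_folds) {
  moments <- attr(dur_std, "moments")
  preds <- full_model_predictors("duration", dur_std)
  out <- list()
  for (pp in unique(dur_std$participant)) {
    tab <- dur_std[dur_std$participant == pp, , drop = FALSE]
    X <- cbind(1, as.matrix(tab[, preds, drop = FALSE]))
    fit <- stats::lm.fit(X, tab$gaze_duration)
    beta <- stats::setNames(fit$coefficients, c("(Intercept)", preds))
    mm <- moments[[as.character(pp)]]
    raw <- dur_raw[dur_raw$participant == pp, , drop = FALSE]
    prior_H <- mean(obs_freq$prior_entropy_bits[obs_freq$participant == pp],
                    na.rm = TRUE)
    pb <- preview_benefit(
      beta[["parafoveal_entropy"]],
      mm$mean[mm$predictor == "parafoveal_entropy"],
      prior_H, mm$sd[mm$predictor == "parafoveal_entropy"])
    db <- tryCatch(predictability_benefit(
      beta[["surprisal"]], raw$surprisal,
      mm$mean[mm$predictor == "surprisal"],
      mm$sd[mm$predictor == "surprisal"]),
      readobs_empty_bin = function(e) NA_real_)
    out[[as.character(pp)]] <- data.frame(
      participant = pp, preview_benefit_ms = pb,
      predictability_benefit_ms = db)
  }
  as.data.frame(data.table::rbindlist(out))
}

# full-model CV scores with contextual vs non-contextual parafoveal
# entropy, per participant and analysis; paired bootstrap comparison.
compare_prior_fits <- function(tabs, filtered, obs_ctx, lm_features,
                               lexicon, config) {
  swap_entropy <- function(analysis_tab, obs) {
    key_obs <- paste(obs$participant, obs$text_id, obs$word_index)
    ix <- match(paste(analysis_tab$participant, analysis_tab$text_id,
                      analysis_tab$word_index), key_obs)
    analysis_tab$parafoveal_entropy <- obs$posterior_entropy_bits[ix]
    analysis_tab[!is.na(analysis_tab$parafoveal_entropy), , drop = FALSE]
  }
  res <- list()
  for (analysis in c("skipping", "duration")) {
    outcome <- if (analysis == "skipping") "skip" else "gaze_duration"
    family <- if (analysis == "skipping") "binomial" else "gaussian"
    tab_ctx <- standardize_within_participant(
      swap_entropy(tabs[[analysis]], obs_ctx))
    tab_non <- standardize_within_participant(tabs[[analysis]])
    preds_ctx <- full_model_predictors(analysis, tab_ctx)
    preds_non <- full_model_predictors(analysis, tab_non)
    participants <- intersect(unique(tab_ctx$participant),
                              unique(tab_non$participant))
    s_ctx <- s_non <- stats::setNames(numeric(length(participants)),
                                      participants)
    for (pp in participants) {
      seed <- derive_seed(config$master_seed, "cmp", analysis, pp)
      s_ctx[pp] <- cv_score(tab_ctx[tab_ctx$participant == pp, ],
                            outcome, preds_ctx, family, config$k_folds, seed)
      s_non[pp] <- cv_score(tab_non[tab_non$participant == pp, ],
                            outcome, preds_non, family, config$k_folds, seed)
    }
    res[[analysis]] <- list(
      scores_contextual = s_ctx, scores_noncontextual = s_non,
      test = compare_observers(s_ctx, s_non, config$n_boot,
                               derive_seed(config$master_seed, "cmpboot",
                                           analysis)))
  }
  res
}

#' Write the pipeline report to disk
#'
#' Serializes the partition and bootstrap results, exclusion log, effect
#' sizes and observer comparison as JSON plus TSV tables.
#'
#' @param report output of [run_pipeline()].
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (analysis in c("skipping", "duration")) {
    utils::write.table(report$partitions[[analysis]],
                       file.path(dir, paste0("partitions_", analysis, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc <- attr(report$partitions[[analysis]], "scores")
    if (!is.null(sc))
      utils::write.table(sc,
                         file.path(dir, paste0("scores_", analysis, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$tables[[analysis]],
                       file.path(dir, paste0("tokens_", analysis, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$observer$noncontextual,
                     file.path(dir, "observer_noncontextual.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$observer$contextual))
    utils::write.table(report$observer$contextual,
                       file.path(dir, "observer_contextual.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$effect_sizes,
                     file.path(dir, "effect_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  boot_json <- lapply(report$bootstrap, function(an)
    lapply(an, function(b) if (is.null(b)) NULL else
      list(mean = b$mean, t = b$t, p = b$p, ci = b$ci, n = b$n,
           n_boot = b$n_boot)))
  js <- list(exclusions = as.list(report$exclusions),
             bootstrap = boot_json,
             config = unclass(report$config))
  if (!is.null(report$observer_comparison)) {
    js$observer_comparison <- lapply(report$observer_comparison,
      function(x) list(mean_difference = x$test$mean, p = x$test$p,
                       ci = x$test$ci))
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
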