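#' End-to-end OFF-detection pipeline on a synthetic cohort
#'
#' Runs the complete processing chain on simulated data, one participant-day
#' at a time so sensor signals never accumulate in memory: simulate the
#' three sensor days, detect worn minutes with the 0.002 g rule, keep
#' continuous questionnaires that were fully completed, opened within the
#' 15-minute deadline and covered by worn data on all three sensors for the
#' full pre-questionnaire window, extract the window, compute the 144-
#' dimensional feature vector, label OFF from the designated Likert item,
#' and evaluate stratified k-fold logistic regression with ROC/AUC.
#'
#' @param cfg A [sim_config()]; `cfg$rng_seed` drives all simulation.
#' @param start_date First protocol day.
#' @param window_min Pre-questionnaire window, minutes.
#' @param w_s Feature sub-window length, seconds.
#' @param label_cutoff Inclusive Likert cutoff for the OFF label.
#' @param k Cross-validation folds.
#' @param max_instances Optional cap; a seeded subsample of exactly this
#'   many instances is kept when more are available.
#' @param cv_seed Seed for fold assignment (and the instance subsample).
#' @return List: `features` (matrix), `labels`, `truth_off` (latent state at
#'   opening, diagnostics only), `probs` (out-of-fold), `roc`
#'   (`roc_result`), `auc`, `n_instances`.
#' @export
run_off_pipeline <- function(cfg, start_date = "2020-01-06",
                             window_min = 15, w_s = 60,
                             label_cutoff = 5, k = 10,
                             max_instances = Inf, cv_seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  feat_rows <- list()
  labels <- integer(0)
  truth_off <- integer(0)
  item_col <- answer_cols()[cfg$off_item_index]
  for (p in seq_len(cfg$n_participants)) {
    meta <- simulate_participant_meta(cfg, p, start_date)
    ev <- meta$events
    resp <- meta$responses
    comp <- is_complete(resp) &
      !is.na(resp$opened_ms) & resp$opened_ms <= ev$deadline_ms[match(resp$event_id, ev$event_id)]
    for (d in seq_len(cfg$n_days)) {
      sel <- which(ev$kind == "continuous" & ev$day_index == d &
                     comp[match(ev$event_id, resp$event_id)])
      if (!length(sel)) next
      db <- day_bounds_ms(cfg, start_date, d)
      day_sessions <- lapply(seq_along(SENSOR_IDS), function(s) {
        simulate_imu_day(cfg, meta$states[[d]], meta$nonwear[[d]],
                         SENSOR_IDS[s], meta$participant_id,
                         db["start"], db["end"],
                         seed = mix_seed(cfg$rng_seed, p, d, 10 + s))
      })
      names(day_sessions) <- SENSOR_IDS
      worn_iv <- lapply(day_sessions, function(sess) {
        ms <- minute_std(sess)
        worn_intervals(classify_worn(ms$std_x), ms$minute_start_ms)
      })
      recs <- lapply(day_sessions, `[[`, "recording")
      for (i in sel) {
        ri <- match(ev$event_id[i], resp$event_id)
        opened <- resp$opened_ms[ri]
        if (!has_sensor_coverage(opened, worn_iv, window_min)) next
        seg <- extract_segment(opened, recs, window_min,
                               started_ms = resp$started_ms[ri])
        feat_rows[[length(feat_rows) + 1]] <- build_instance(seg, w_s)
        labels <- c(labels, label_off(resp[[item_col]][ri], label_cutoff))
        truth_off <- c(truth_off, state_at(meta$states[[d]], opened))
      }
      rm(day_sessions, recs)
    }
  }
  x <- do.call(rbind, feat_rows)
  if (is.null(x) || nrow(x) < k) stop("too few labelled instances for cross-validation")
  if (is.finite(max_instances) && nrow(x) > max_instances) {
    keep <- with_seed(mix_seed(cv_seed, 4242),
                      sort(sample(nrow(x), max_instances)))
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
    truth_off <- truth_off[keep]
  }
  probs <- crossval_off(x, labels, k = k, seed = cv_seed)
  roc <- roc_auc(probs, labels)
  list(features = x, labels = labels, truth_off = truth_off, probs = probs,
       roc = roc, auc = roc$auc, n_instances = nrow(x))
}
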