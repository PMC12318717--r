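# -- pipeline orchestration --------------------------------------------
# simulate -> preprocess -> spectra -> bursts -> hmm -> nabb -> stats,
# driven by one configuration and one seed, with a manifest recording
# what ran. The stage functions remain usable on their own; this
# wrapper wires the conventional end-to-end analysis.

#' Pipeline configuration
#'
#' @param burst a [burst_config()].
#' @param hmm_K number of HMM states.
#' @param hmm_runs number of EM initialisations.
#' @param hmm_max_iter,hmm_tol EM controls.
#' @param lags embedding half-width.
#' @param n_pca principal components (default 2 x parcels).
#' @param n_perm permutations for group statistics.
#' @param n_perm_shift permutations for the overlap shift null.
#' @param beta_band Hz band for beta-power summaries (default 16-25.5).
#' @param welch_window,welch_overlap Welch settings in samples.
#' @param preprocess apply band-pass (1-45 Hz) and outlier-segment
#'   rejection before analysis.
#' @param confounds confound column names for the group GLMs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(burst = burst_config(),
                            hmm_K = 8, hmm_runs = 3,
                            hmm_max_iter = 40, hmm_tol = 1e-6,
                            lags = 7, n_pca = NULL,
                            n_perm = 1000, n_perm_shift = 200,
                            beta_band = c(16, 25.5),
                            welch_window = 500, welch_overlap = 250,
                            preprocess = TRUE,
                            confounds = c("dataset", "age", "sex",
                                          "education", "handedness")) {
  structure(list(burst = burst, hmm_K = hmm_K, hmm_runs = hmm_runs,
                 hmm_max_iter = hmm_max_iter, hmm_tol = hmm_tol,
                 lags = lags, n_pca = n_pca, n_perm = n_perm,
                 n_perm_shift = n_perm_shift, beta_band = beta_band,
                 welch_window = welch_window,
                 welch_overlap = welch_overlap,
                 preprocess = preprocess, confounds = confounds),
            class = "pipeline_config")
}

#' Run the burst-network analysis pipeline on a cohort
#'
#' Stages: `preprocess` (band-pass, outlier segments, z-score),
#' `spectra` (Welch motor spectra + group cluster contrast), `bursts`
#' (motor beta bursts + metrics + group GLMs), `hmm` (TDE-HMM, state
#' metrics, state beta power, group max-t GLMs), `nabb` (overlap,
#' shift-null test, NABB metrics and group GLMs). Later stages require
#' earlier ones. The sensorimotor state is identified as the state
#' with the largest cohort-mean motor beta-power change.
#'
#' @param cohort a [generate_cohort()] result (or compatible list).
#' @param config a [pipeline_config()].
#' @param seed global seed; per-stage seeds are derived from it.
#' @param stages subset of stages to run (prerequisites enforced).
#' @return A `pipeline_result` with one element per stage and a
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), seed = 1L,
                         stages = c("preprocess", "spectra", "bursts",
                                    "hmm", "nabb")) {
  all_stages <- c("preprocess", "spectra", "bursts", "hmm", "nabb")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(stage, result) {
    if (is.null(result))
      stop("stage '", stage, "' output missing; run it first")
    result
  }
  fs <- cohort$subjects[[1]]$ts$fs
  n_sub <- length(cohort$subjects)
  res <- list(config = config, seed = seed)
  dm <- build_design(cohort$covariates, config$confounds)
  res$design <- dm
  stage_seed <- function(i) (seed * 100003L + i * 7919L) %% 2147483647L

  ts_list <- lapply(cohort$subjects, `[[`, "ts")
  masks <- lapply(ts_list, function(ts) rep(TRUE, n_samples(ts)))

  if ("preprocess" %in% stages) {
    for (i in seq_len(n_sub)) {
      ts <- ts_list[[i]]
      if (config$preprocess) {
        ts <- bandpass_downsample(ts, 1, min(45, fs / 2 - 5), fs)
        masks[[i]] <- tryCatch(as.logical(detect_bad_segments(ts)),
                               error = function(e) rep(TRUE, n_samples(ts)))
      }
      ts_list[[i]] <- zscore_parcels(ts)
    }
    res$preprocess <- list(masks = masks,
                           retained = vapply(masks, mean, numeric(1)))
  }

  motor <- config$burst$motor_parcels
  if ("spectra" %in% stages) {
    need("preprocess", res$preprocess)
    psds <- lapply(ts_list, function(ts)
      welch_psd(subset_parcels(ts, motor),
                window_len = config$welch_window,
                overlap = config$welch_overlap))
    freq <- psds[[1]]$freq
    motor_spec <- t(vapply(psds, function(ps)
      rowMeans(ps$power), numeric(length(freq))))
    beta_power <- vapply(psds, motor_band_power, numeric(1),
                         motor_parcels = seq_along(motor),
                         band = config$beta_band)
    cluster <- cluster_permutation_spectra(
      dm, motor_spec[, freq >= 1 & freq <= 45, drop = FALSE],
      freq = freq[freq >= 1 & freq <= 45],
      n_perm = config$n_perm, seed = stage_seed(2L))
    res$spectra <- list(freq = freq, motor_spectra = motor_spec,
                        beta_power = beta_power, cluster = cluster)
  }

  if ("bursts" %in% stages) {
    need("preprocess", res$preprocess)
    bursts <- lapply(seq_len(n_sub), function(i)
      detect_motor_bursts(ts_list[[i]], config$burst, masks[[i]]))
    burst_tracks <- lapply(bursts, `[[`, "combined")
    met <- do.call(rbind, lapply(seq_len(n_sub), function(i)
      track_metrics(burst_tracks[[i]], mask = masks[[i]])))
    # beta power is a motor-parcel quantity; restrict the multitaper
    # to those parcels
    met$beta_power_change <- vapply(seq_len(n_sub), function(i)
      burst_beta_power(subset_parcels(ts_list[[i]], motor),
                       burst_tracks[[i]], seq_along(motor),
                       config$beta_band), numeric(1))
    glms <- maxt_permutation(
      dm, as.matrix(met[, c("fo", "mean_lifetime", "mean_interval",
                            "rate", "beta_power_change")]),
      n_perm = config$n_perm, seed = stage_seed(3L))
    res$bursts <- list(tracks = burst_tracks, metrics = met,
                       interparcel_overlap =
                         vapply(bursts, `[[`, numeric(1), "overlap"),
                       glms = glms)
  }

  if ("hmm" %in% stages) {
    need("preprocess", res$preprocess)
    K <- config$hmm_K
    hmm <- tde_hmm(ts_list, K = K, lags = config$lags,
                   n_pca = config$n_pca, n_runs = config$hmm_runs,
                   seeds = stage_seed(4L) %% 10000L + seq_len(config$hmm_runs),
                   max_iter = config$hmm_max_iter, tol = config$hmm_tol)
    # run ensemble: keep runs whose free energy is comparable to the
    # best (grossly worse runs are degenerate local optima); dynamics
    # metrics are averaged over kept runs after state matching, which
    # suppresses run-to-run segmentation noise in event-count metrics
    fe <- hmm$runs$free_energy
    kept <- which(fe <= min(fe) + 0.005 * abs(min(fe)))
    best_idx <- which.min(fe)
    run_post <- lapply(kept, function(r) {
      if (r == best_idx) hmm$posteriors
      else lapply(hmm$reduced, function(x)
        state_timecourses(hmm$fits[[r]], x, lags = config$lags, fs = fs))
    })
    # match each kept run's states to the best run on pooled,
    # subsampled posteriors
    pool <- function(post) do.call(rbind, lapply(
      post[seq_len(min(10L, n_sub))],
      function(sp) sp$gamma[seq(1L, nrow(sp$gamma), by = 5L), ,
                            drop = FALSE]))
    g_best <- pool(hmm$posteriors)
    maps <- lapply(run_post, function(post)
      match_states(g_best, pool(post)))

    per_run_met <- lapply(seq_along(kept), function(ri) {
      m <- do.call(rbind, lapply(seq_len(n_sub), function(i)
        cbind(subject = i,
              state_metrics(run_post[[ri]][[i]], mask = masks[[i]]))))
      # reorder into the best run's state labels
      idx <- order(m$subject, match(m$state, maps[[ri]]))
      m2 <- m[idx, ]
      m2$state <- rep(seq_len(K), n_sub)
      m2
    })
    avg_cols <- c("fo", "mean_lifetime", "mean_interval", "rate",
                  "n_events", "fo_soft")
    met <- per_run_met[[1]]
    for (cc in avg_cols) {
      vals <- vapply(per_run_met, function(m) m[[cc]],
                     numeric(nrow(met)))
      met[[cc]] <- rowMeans(as.matrix(vals), na.rm = TRUE)
    }

    per_run_beta <- lapply(seq_along(kept), function(ri) {
      b <- t(vapply(seq_len(n_sub), function(i)
        state_beta_power_change(
          state_spectra(subset_parcels(ts_list[[i]], motor),
                        run_post[[ri]][[i]]),
          seq_along(motor), config$beta_band), numeric(K)))
      b[, maps[[ri]], drop = FALSE]
    })
    beta_change <- Reduce(`+`, per_run_beta) / length(per_run_beta)
    sm_state <- which.max(colMeans(beta_change, na.rm = TRUE))
    endpoint <- function(col) {
      m <- matrix(met[[col]], n_sub, K, byrow = TRUE)
      colnames(m) <- paste0("state", seq_len(K))
      m
    }
    glms <- lapply(c(fo = "fo", mean_lifetime = "mean_lifetime",
                     mean_interval = "mean_interval", rate = "rate"),
                   function(col) maxt_permutation(dm, endpoint(col),
                                                  n_perm = config$n_perm,
                                                  seed = stage_seed(5L)))
    glms$beta_power_change <- maxt_permutation(dm, beta_change,
                                               n_perm = config$n_perm,
                                               seed = stage_seed(5L))
    fo_mat <- endpoint("fo")
    res$hmm <- list(model = hmm, metrics = met, fo = fo_mat,
                    beta_change = beta_change, sm_state = sm_state,
                    glms = glms,
                    ensemble = list(kept = kept, maps = maps,
                                    posteriors = run_post))
    if (!is.null(res$spectra)) {
      res$hmm$fo_beta_cor <- pearson_r(fo_mat[, sm_state],
                                       res$spectra$beta_power)
      res$hmm$fo_projection <- fo_spectrum_projection(
        fo_mat[, sm_state], res$spectra$motor_spectra,
        confounds = dm$X[, -(1:2), drop = FALSE],
        freq = res$spectra$freq)
    }
  }

  if ("nabb" %in% stages) {
    need("bursts", res$bursts)
    need("hmm", res$hmm)
    sps <- res$hmm$model$posteriors
    overlap <- if (config$n_perm_shift > 0)
      shift_null_test(res$bursts$tracks, sps,
                      n_perm = config$n_perm_shift,
                      seed = stage_seed(6L), masks = masks)
    else NULL
    K <- config$hmm_K
    sm <- res$hmm$sm_state
    ens <- res$hmm$ensemble
    per_run_nabb <- vector("list", length(ens$kept))
    per_run_other <- vector("list", length(ens$kept))
    for (ri in seq_along(ens$kept)) {
      post <- ens$posteriors[[ri]]
      map <- ens$maps[[ri]]
      nm <- vector("list", n_sub)
      om <- vector("list", n_sub)
      for (i in seq_len(n_sub)) {
        tracks <- segment_nabbs(res$bursts$tracks[[i]], post[[i]])
        tracks <- tracks[map]        # best-run state order
        use <- masks[[i]] & !post[[i]]$padded
        nm[[i]] <- cbind(subject = i, nabb_metrics(tracks, mask = use))
        om[[i]] <- cbind(subject = i,
                         other_nabb_aggregate(tracks, sm, mask = use))
      }
      per_run_nabb[[ri]] <- do.call(rbind, nm)
      per_run_other[[ri]] <- do.call(rbind, om)
    }
    avg_cols <- c("fo", "mean_lifetime", "mean_interval", "rate",
                  "n_events")
    nabb_met <- per_run_nabb[[1]]
    other_met <- per_run_other[[1]]
    for (cc in avg_cols) {
      nabb_met[[cc]] <- rowMeans(as.matrix(
        vapply(per_run_nabb, function(m) m[[cc]],
               numeric(nrow(nabb_met)))), na.rm = TRUE)
      other_met[[cc]] <- rowMeans(as.matrix(
        vapply(per_run_other, function(m) m[[cc]],
               numeric(nrow(other_met)))), na.rm = TRUE)
    }
    endpoint <- function(col) {
      m <- matrix(nabb_met[[col]], n_sub, K, byrow = TRUE)
      colnames(m) <- paste0("state", seq_len(K))
      m
    }
    glms <- lapply(c(fo = "fo", mean_lifetime = "mean_lifetime",
                     mean_interval = "mean_interval", rate = "rate"),
                   function(col) maxt_permutation(dm, endpoint(col),
                                                  n_perm = config$n_perm,
                                                  seed = stage_seed(7L)))
    other_glm <- maxt_permutation(dm, cbind(other_fo = other_met$fo),
                                  n_perm = config$n_perm,
                                  seed = stage_seed(8L))
    res$nabb <- list(overlap = overlap, metrics = nabb_met,
                     other_metrics = other_met, glms = glms,
                     other_glm = other_glm, sm_state = sm)
  }

  res$manifest <- list(
    stages = stages, seed = seed, n_subjects = n_sub, fs = fs,
    hmm_K = config$hmm_K, n_perm = config$n_perm,
    package_version = as.character(utils::packageVersion("burstnet")),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:",
      paste(x$manifest$stages, collapse = ", "), "\n")
  if (!is.null(x$hmm))
    cat(sprintf("  sensorimotor state: %d (of %d)\n",
                x$hmm$sm_state, x$config$hmm_K))
  invisible(x)
}

# -- plain-text cohort container ---------------------------------------

#' Write a cohort to a directory
#'
#' Plain-text layout: one TSV matrix per subject plus a JSON sidecar
#' holding the sampling rate and parcel labels, a covariates CSV, and
#' the planted ground truth (state sequences and per-state metrics) as
#' JSON.
#'
#' @param cohort a `cohort`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    base <- file.path(path, s$id)
    utils::write.table(s$ts$data, paste0(base, "_data.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(fs = s$ts$fs, labels = s$ts$labels,
                              group = s$group, states = s$states),
                         paste0(base, "_meta.json"), auto_unbox = TRUE)
  }
  write.csv(cohort$covariates, file.path(path, "covariates.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(cohort$ground_truth$metrics, function(m) as.list(m)),
    file.path(path, "ground_truth.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path directory.
#' @return A `cohort`-shaped list (without the generating spec).
#' @export
read_cohort <- function(path) {
  metas <- sort(list.files(path, "_meta\\.json$", full.names = TRUE))
  subjects <- lapply(metas, function(mf) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    dataf <- sub("_meta\\.json$", "_data.tsv", mf)
    x <- as.matrix(utils::read.table(dataf, sep = "\t"))
    dimnames(x) <- NULL
    list(id = sub("_meta\\.json$", "", basename(mf)),
         group = meta$group,
         ts = parcel_ts(x, meta$fs, meta$labels),
         states = as.integer(meta$states))
  })
  structure(list(subjects = subjects,
                 covariates = read.csv(file.path(path, "covariates.csv"))),
            class = "cohort")
}
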