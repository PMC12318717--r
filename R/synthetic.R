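# -- synthetic cohort generator ----------------------------------------
# Markov-switching parcel time courses with state-specific band-limited
# oscillatory signatures, planted group effects, and covariates. Gives
# every downstream stage a ground truth to be tested against.

#' Stationary distribution of a transition matrix
#'
#' @param P row-stochastic K x K matrix.
#' @return Length-K stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  validate_transition_matrix(P)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

validate_transition_matrix <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square")
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > 1e-10 | apply(P < 0, 1, any))
  if (length(bad) > 0)
    stop("transition matrix row(s) ", paste(bad, collapse = ", "),
         " are not stochastic")
  invisible(P)
}

#' Build a transition matrix from dwell time and entry weights
#'
#' Diagonal entries follow from the requested mean state lifetime
#' (geometric dwell: `stay = 1 - 1/(lifetime * fs)`); off-diagonal mass
#' is distributed proportionally to `entry_weights`, so scaling one
#' state's weight down makes that state rarer (lower FO and rate,
#' longer intervals) without changing lifetimes.
#'
#' @param K number of states.
#' @param mean_lifetime target mean state lifetime in seconds.
#' @param fs sampling rate in Hz.
#' @param entry_weights positive length-K vector of relative entry
#'   propensities (default uniform).
#' @return K x K row-stochastic matrix.
#' @export
make_transition_matrix <- function(K, mean_lifetime = 0.06, fs = 250,
                                   entry_weights = rep(1, K)) {
  stopifnot(K >= 2, length(entry_weights) == K, all(entry_weights > 0))
  stay <- 1 - 1 / (mean_lifetime * fs)
  if (stay <= 0 || stay >= 1) stop("mean_lifetime incompatible with fs")
  P <- matrix(0, K, K)
  for (j in seq_len(K)) {
    w <- entry_weights
    w[j] <- 0
    P[j, ] <- (1 - stay) * w / sum(w)
    P[j, j] <- stay
  }
  P
}

# entry-weight scale that multiplies a state's stationary FO by `f`
# relative to the uniform chain (exact for the uniform-stay chain):
# pi_1/(1-pi_1) = r/(r+K-2) with target pi_1 = f/K.
entry_scale_for_fo <- function(K, f) {
  stopifnot(K >= 3, f > 0, f < K / 2)
  f * (K - 2) / (K - 2 * f)
}

# numerically find the factor on state 1's entry weight that multiplies
# its stationary FO by `f`, for arbitrary base entry weights
entry_scale_for_fo_general <- function(K, f, mean_lifetime, fs,
                                       entry_weights) {
  base_fo <- stationary_distribution(
    make_transition_matrix(K, mean_lifetime, fs, entry_weights))[1]
  target <- f * base_fo
  g <- function(s) {
    w <- entry_weights
    w[1] <- w[1] * s
    stationary_distribution(
      make_transition_matrix(K, mean_lifetime, fs, w))[1] - target
  }
  stats::uniroot(g, c(1e-4, 1), tol = 1e-10)$root
}

#' Oscillatory state signature
#'
#' Defines what one hidden state looks like in the signal: a
#' band-limited Gaussian oscillation (centre +/- bandwidth/2) projected
#' onto parcels with non-negative weights. A fraction `shared_frac` of
#' the oscillatory variance comes from a carrier shared across parcels
#' (creating within-state coherence); the rest is parcel-specific.
#'
#' @param centre centre frequency in Hz.
#' @param bandwidth bandwidth in Hz.
#' @param weights non-negative parcel weight vector.
#' @param amplitude oscillation standard deviation at weight 1, in
#'   units of the background-noise SD.
#' @param shared_frac shared-carrier variance fraction in \[0, 1\].
#' @return A `state_signature` list.
#' @export
state_signature <- function(centre, bandwidth, weights, amplitude = 2,
                            shared_frac = 0.7) {
  if (any(weights < 0)) stop("parcel weights must be non-negative")
  stopifnot(centre > 0, bandwidth > 0, amplitude >= 0,
            shared_frac >= 0, shared_frac <= 1)
  structure(list(centre = centre, bandwidth = bandwidth,
                 weights = weights, amplitude = amplitude,
                 shared_frac = shared_frac),
            class = "state_signature")
}

# default signature set: state 1 = bilateral sensorimotor beta state
# (16-25.5 Hz on the motor parcels), state 2 = widespread broadband
# state that also covers motor cortex, remaining states = narrowband
# activity on disjoint non-motor parcel blocks.
default_signatures <- function(K, P, motor_parcels = c(1L, 2L),
                               amplitude = 2) {
  centres <- c(20.75, 17, 10, 4, 7, 12.5, 30, 35, 16, 6, 25, 9)
  bws <- c(9.5, 26, 4, 3, 3, 4, 8, 8, 5, 3, 6, 4)
  sigs <- vector("list", K)
  w1 <- numeric(P)
  w1[motor_parcels] <- 1
  near <- setdiff(seq_len(min(P, max(motor_parcels) + 4L)), motor_parcels)
  w1[near] <- 0.35
  sigs[[1]] <- state_signature(centres[1], bws[1], w1, amplitude)
  if (K >= 2) {
    w2 <- rep(0.5, P)
    sigs[[2]] <- state_signature(centres[2], bws[2], w2, amplitude)
  }
  if (K >= 3) {
    others <- setdiff(seq_len(P), motor_parcels)
    blocks <- split(others, rep(seq_len(K - 2), length.out = length(others)))
    for (k in 3:K) {
      w <- numeric(P)
      w[blocks[[k - 2]]] <- 1
      ci <- ((k - 1) %% length(centres)) + 1
      sigs[[k]] <- state_signature(centres[ci], bws[ci], w, amplitude)
    }
  }
  sigs
}

#' Cohort specification
#'
#' The defaults emulate the study conditions this generator is built
#' for: 36 healthy controls and 28 patients, 39 parcels at 250 Hz,
#' 8-minute recordings, 8 Markov states with mean lifetimes of tens of
#' milliseconds, and a planted reduction of sensorimotor-state
#' occupancy in the patient group (`pd_fo_scale = 0.8`, i.e. -20%)
#' achieved by lowering the entry probability into state 1.
#'
#' @param n_hc,n_pd group sizes.
#' @param n_parcels number of parcels.
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param n_states number of hidden states K.
#' @param mean_lifetime target mean state lifetime in seconds.
#' @param pd_fo_scale multiplicative change of the sensorimotor-state
#'   stationary FO in the patient group (1 = no planted effect).
#' @param entry_weights length-K relative entry propensities shaping
#'   the stationary occupancies (default uniform, FO = 1/K each). With
#'   few states, down-weighting state 1 keeps its occupancy and
#'   interval times in the empirically observed range (FO of order
#'   10-16%, intervals of hundreds of ms).
#' @param transition_matrices optional list with elements `hc` and `pd`
#'   overriding the constructed matrices.
#' @param signatures optional list of [state_signature]s (length K).
#' @param motor_parcels indices of the two motor parcels.
#' @param amplitude oscillation amplitude passed to the default
#'   signatures.
#' @param noise_sd background white-noise SD.
#' @param subject_jitter_sd SD of the per-subject log-normal jitter on
#'   entry weights (between-subject FO variability).
#' @param symptom_fo_coupling slope linking patients'
#'   Bradykinesia/Rigidity scores to their planted sensorimotor FO
#'   (z-scaled); 0 = independent.
#' @param seed integer seed governing the whole cohort.
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 36, n_pd = 28, n_parcels = 39, fs = 250,
                        duration = 480, n_states = 8,
                        mean_lifetime = 0.06, pd_fo_scale = 0.8,
                        entry_weights = NULL,
                        transition_matrices = NULL, signatures = NULL,
                        motor_parcels = c(1L, 2L), amplitude = 2,
                        noise_sd = 1, subject_jitter_sd = 0.2,
                        symptom_fo_coupling = 0, seed = 1L) {
  stopifnot(n_hc > 0, n_pd > 0, n_parcels > 0, fs > 0, duration > 0,
            n_states >= 2, noise_sd >= 0)
  K <- n_states
  if (is.null(entry_weights)) entry_weights <- rep(1, K)
  if (is.null(transition_matrices)) {
    hc_mat <- make_transition_matrix(K, mean_lifetime, fs, entry_weights)
    if (pd_fo_scale == 1) {
      pd_mat <- hc_mat
    } else if (K == 2) {
      # entry weights are degenerate with two states: plant the FO
      # change through state 1's dwell time instead
      f0 <- stationary_distribution(hc_mat)[1]
      target <- pd_fo_scale * f0
      d1 <- mean_lifetime * target * (1 - f0) / (f0 * (1 - target))
      pd_mat <- hc_mat
      pd_mat[1, 1] <- 1 - 1 / (d1 * fs)
      pd_mat[1, 2] <- 1 - pd_mat[1, 1]
    } else {
      w_pd <- entry_weights
      w_pd[1] <- w_pd[1] * entry_scale_for_fo_general(
        K, pd_fo_scale, mean_lifetime, fs, entry_weights)
      pd_mat <- make_transition_matrix(K, mean_lifetime, fs, w_pd)
    }
    transition_matrices <- list(hc = hc_mat, pd = pd_mat)
  }
  lapply(transition_matrices, validate_transition_matrix)
  if (is.null(signatures))
    signatures <- default_signatures(K, n_parcels, motor_parcels,
                                     amplitude)
  if (length(signatures) != K)
    stop("need one signature per state")
  for (s in signatures)
    if (length(s$weights) != n_parcels)
      stop("signature weight vectors must have length n_parcels")
  structure(list(n_hc = n_hc, n_pd = n_pd, n_parcels = n_parcels,
                 fs = fs, duration = duration, n_states = K,
                 mean_lifetime = mean_lifetime,
                 pd_fo_scale = pd_fo_scale,
                 entry_weights = entry_weights,
                 transition_matrices = transition_matrices,
                 signatures = signatures,
                 motor_parcels = motor_parcels,
                 noise_sd = noise_sd,
                 subject_jitter_sd = subject_jitter_sd,
                 symptom_fo_coupling = symptom_fo_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a hidden-state sequence from a Markov chain
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_dist length-K initial distribution; defaults to the
#'   stationary distribution.
#' @param n_samples sequence length.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return Integer state labels in `1..K`.
#' @export
sample_state_sequence <- function(transition_matrix, initial_dist = NULL,
                                  n_samples, seed = NULL) {
  validate_transition_matrix(transition_matrix)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (is.null(initial_dist))
    initial_dist <- stationary_distribution(transition_matrix)
  if (abs(sum(initial_dist) - 1) > 1e-8 || any(initial_dist < 0))
    stop("initial_dist must be a probability vector")
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n_samples)
  .sample_markov_cpp(transition_matrix, initial_dist, u)
}

# band-limited unit-SD Gaussian noise via frequency-domain shaping
# (ideal band with 1-Hz raised-cosine edges); cheap enough to draw one
# series per state and parcel
band_noise <- function(n, fs, low, high, taper_hz = 1) {
  x <- rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1L)[seq_len(n)])
  f <- pmin(f, fs - f)  # two-sided frequency axis
  H <- numeric(n)
  H[f >= low & f <= high] <- 1
  rise <- f >= low - taper_hz & f < low
  H[rise] <- 0.5 * (1 + cos(pi * (low - f[rise]) / taper_hz))
  fall <- f > high & f <= high + taper_hz
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - high) / taper_hz))
  y <- Re(fft(fft(x) * H, inverse = TRUE) / n)
  s <- sd(y)
  if (s == 0) stop("degenerate band")
  y / s
}

#' Render parcel signals from a state sequence
#'
#' During visits to state k, parcels carry that state's band-limited
#' oscillation (shared carrier plus parcel-specific component, weighted
#' by the signature), superimposed on white background noise.
#'
#' @param state_sequence integer labels in `1..K`.
#' @param signatures list of K [state_signature]s.
#' @param fs sampling rate in Hz.
#' @param noise_sd background white-noise SD.
#' @param seed optional seed.
#' @return A [parcel_ts].
#' @export
render_signals <- function(state_sequence, signatures, fs, noise_sd = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(signatures)
  if (max(state_sequence) > K) stop("state labels exceed signature list")
  P <- length(signatures[[1]]$weights)
  n <- length(state_sequence)
  x <- matrix(rnorm(n * P, sd = noise_sd), n, P)
  for (k in seq_len(K)) {
    sig <- signatures[[k]]
    if (length(sig$weights) != P) stop("signature ", k,
                                       ": weight length mismatch")
    if (sig$amplitude == 0) next
    on <- as.numeric(state_sequence == k)
    if (!any(on > 0)) next
    lo <- max(sig$centre - sig$bandwidth / 2, 0.5)
    hi <- min(sig$centre + sig$bandwidth / 2, fs / 2 - 0.5)
    carrier <- band_noise(n, fs, lo, hi)
    active <- which(sig$weights > 0)
    a_sh <- sqrt(sig$shared_frac)
    a_in <- sqrt(1 - sig$shared_frac)
    for (p in active) {
      comp <- a_sh * carrier
      if (a_in > 0) comp <- comp + a_in * band_noise(n, fs, lo, hi)
      x[, p] <- x[, p] + on * sig$amplitude * sig$weights[p] * comp
    }
  }
  parcel_ts(x, fs, c(sprintf("motor_%s", c("l", "r")),
                     sprintf("parcel_%d", seq_len(max(P - 2, 0)) + 2))[seq_len(P)])
}

#' Generate a synthetic cohort
#'
#' Draws one state sequence and parcel recording per subject (patients
#' use the patient-group transition matrix, with per-subject entry
#' jitter), covariates, and symptom scores for patients. The ground
#' truth stores each subject's planted state sequence and the planted
#' per-state dynamics metrics recomputed with [track_metrics()].
#'
#' @param spec a [cohort_spec].
#' @return A `cohort`: list with `spec`, `subjects` (each holding `id`,
#'   `group`, `ts`, `states`), `covariates` data frame, and
#'   `ground_truth` (per-subject planted metrics and FO matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_sub <- spec$n_hc + spec$n_pd
  groups <- c(rep("HC", spec$n_hc), rep("PD", spec$n_pd))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)
  n <- as.integer(round(spec$duration * spec$fs))
  K <- spec$n_states

  subjects <- vector("list", n_sub)
  planted_fo <- matrix(0, n_sub, K)
  planted_metrics <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(sub_seeds[i])
    P0 <- spec$transition_matrices[[tolower(groups[i])]]
    # per-subject entry-weight jitter: rebuild rows with perturbed
    # off-diagonal allocation, keeping the dwell probability
    if (spec$subject_jitter_sd > 0) {
      jit <- exp(rnorm(K, sd = spec$subject_jitter_sd))
      Pj <- P0
      for (j in seq_len(K)) {
        off <- P0[j, ]
        off[j] <- 0
        off <- off * jit
        off[j] <- 0
        Pj[j, ] <- (1 - P0[j, j]) * off / sum(off)
        Pj[j, j] <- P0[j, j]
      }
      P0 <- Pj
    }
    states <- sample_state_sequence(P0, NULL, n)
    ts <- render_signals(states, spec$signatures, spec$fs, spec$noise_sd)
    met <- do.call(rbind, lapply(seq_len(K), function(k)
      cbind(state = k, track_metrics(states == k, fs = spec$fs))))
    planted_fo[i, ] <- met$fo
    planted_metrics[[i]] <- met
    subjects[[i]] <- list(id = sprintf("sub-%03d", i), group = groups[i],
                          ts = ts, states = states)
  }

  set.seed(sub_seeds[n_sub] + 1L)
  covariates <- data.frame(
    subject = vapply(subjects, `[[`, character(1), "id"),
    group = groups,
    dataset = sample(c(0L, 1L), n_sub, replace = TRUE),
    age = round(pmin(pmax(rnorm(n_sub, 68, 6), 50), 85), 1),
    sex = sample(c(0L, 1L), n_sub, replace = TRUE, prob = c(0.56, 0.44)),
    education = round(pmin(pmax(rnorm(n_sub, 15, 3), 8), 24)),
    handedness = sample(c(1L, 0L), n_sub, replace = TRUE,
                        prob = c(0.92, 0.08)))
  covariates$bradykinesia_rigidity <- NA_real_
  covariates$tremor <- NA_real_
  pd_idx <- which(groups == "PD")
  fo_z <- as.numeric(scale(planted_fo[pd_idx, 1]))
  covariates$bradykinesia_rigidity[pd_idx] <-
    pmax(rnorm(length(pd_idx), 15, 6) +
           spec$symptom_fo_coupling * fo_z, 0)
  covariates$tremor[pd_idx] <- pmax(rnorm(length(pd_idx), 5, 3), 0)

  structure(list(spec = spec, subjects = subjects,
                 covariates = covariates,
                 ground_truth = list(metrics = planted_metrics,
                                     fo = planted_fo,
                                     groups = groups)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (%d HC / %d PD), %d parcels @ %g Hz, %g s, K = %d\n",
    length(x$subjects), x$spec$n_hc, x$spec$n_pd, x$spec$n_parcels,
    x$spec$fs, x$spec$duration, x$spec$n_states))
  invisible(x)
}
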