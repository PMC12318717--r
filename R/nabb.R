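# -- network-associated beta bursts ------------------------------------
# Quantify burst / network-state co-occurrence, test it against a
# circular-shift null, and segment bursts by co-occurring state.

valid_samples <- function(sp, mask = NULL) {
  v <- !sp$padded
  if (!is.null(mask)) v <- v & mask
  v
}

#' Burst-state overlap percentages
#'
#' For each state k, the percentage of burst samples that co-occur with
#' state k on the hard (argmax) state path. Because the hard path
#' partitions time, the overlaps across states sum to 100.
#'
#' @param burst burst [binary_track].
#' @param sp the subject's `state_probs`.
#' @param mask optional retention mask.
#' @return Length-K vector of percentages; all `NA` when the subject
#'   has no burst samples.
#' @export
burst_state_overlap <- function(burst, sp, mask = NULL) {
  if (length(burst$on) != length(sp$path))
    stop("burst track and state path are misaligned")
  v <- valid_samples(sp, mask)
  b <- burst$on & v
  nb <- sum(b)
  if (nb == 0L) return(rep(NA_real_, sp$K))
  vapply(seq_len(sp$K), function(k) 100 * sum(b & sp$path == k) / nb,
         numeric(1))
}

#' Circular-shift permutation test of burst-state overlap
#'
#' Generates null overlaps by circularly shifting each subject's state
#' path by an independent uniform offset (at least `min_shift` samples
#' away from identity at both ends), recomputing overlaps, and
#' contrasting the empirical overlap against the subject-wise mean null
#' overlap with a directed (empirical greater) paired t-test per state.
#' P-values are Bonferroni-multiplied by the number of states. The
#' circular shift preserves each subject's state FOs exactly, so the
#' null disrupts only the temporal alignment.
#'
#' @param bursts list of burst [binary_track]s (one per subject).
#' @param sps list of `state_probs` (one per subject).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param masks optional list of retention masks.
#' @param min_shift minimum shift in samples (default one second's
#'   worth, using each subject's sampling rate).
#' @return List with `empirical` (subjects x K), `null` (subjects x K
#'   x n_perm), `t` (per state), `p` (one-sided), `p_bonferroni`.
#' @export
shift_null_test <- function(bursts, sps, n_perm = 1000, seed = 1L,
                            masks = NULL, min_shift = NULL) {
  n_sub <- length(bursts)
  if (n_sub < 2L) stop("need at least 2 subjects")
  if (length(sps) != n_sub) stop("bursts and posteriors differ in length")
  K <- sps[[1]]$K
  set.seed(seed)
  empirical <- t(vapply(seq_len(n_sub), function(i)
    burst_state_overlap(bursts[[i]], sps[[i]],
                        if (is.null(masks)) NULL else masks[[i]]),
    numeric(K)))
  null <- array(NA_real_, dim = c(n_sub, K, n_perm))
  for (i in seq_len(n_sub)) {
    sp <- sps[[i]]
    Tn <- length(sp$path)
    ms <- if (is.null(min_shift)) round(if (is.null(sp$fs)) 0.04 * Tn
                                        else sp$fs) else min_shift
    if (2 * ms >= Tn) stop("recording too short for the minimum shift")
    v <- valid_samples(sp, if (is.null(masks)) NULL else masks[[i]])
    b <- bursts[[i]]$on & v
    nb <- sum(b)
    shifts <- sample(ms:(Tn - ms), n_perm, replace = TRUE)
    for (pm in seq_len(n_perm)) {
      path_s <- circular_shift(sp$path, shifts[pm])
      if (nb > 0L)
        null[i, , pm] <- vapply(seq_len(K), function(k)
          100 * sum(b & path_s == k) / nb, numeric(1))
    }
  }
  null_mean <- apply(null, c(1, 2), mean)
  t_stat <- p <- numeric(K)
  for (k in seq_len(K)) {
    d <- empirical[, k] - null_mean[, k]
    d <- d[!is.na(d)]
    t_stat[k] <- mean(d) / (sd(d) / sqrt(length(d)))
    p[k] <- pt(t_stat[k], df = length(d) - 1, lower.tail = FALSE)
  }
  list(empirical = empirical, null = null, t = t_stat, p = p,
       p_bonferroni = pmin(p * K, 1), n_perm = n_perm, seed = seed)
}

#' Segment bursts into network-associated beta bursts
#'
#' NABB track k is the per-sample intersection of the burst track with
#' state k's occupancy on the hard path, so the union of the NABB
#' tracks recovers the burst track and NABB occupancies are additive.
#'
#' @param burst burst [binary_track].
#' @param sp `state_probs`.
#' @return List of K [binary_track]s.
#' @export
segment_nabbs <- function(burst, sp) {
  if (length(burst$on) != length(sp$path))
    stop("burst track and state path are misaligned")
  lapply(seq_len(sp$K), function(k)
    binary_track(burst$on & sp$path == k, burst$fs,
                 sprintf("NABB_%d", k)))
}

#' NABB dynamics metrics
#'
#' Per-state [track_metrics()] of the NABB tracks.
#'
#' @param nabb_tracks list of K NABB [binary_track]s.
#' @param mask optional retention mask (padded posterior samples should
#'   be excluded via this mask).
#' @return `data.frame`, one row per state.
#' @export
nabb_metrics <- function(nabb_tracks, mask = NULL) {
  do.call(rbind, lapply(seq_along(nabb_tracks), function(k)
    cbind(state = k, track_metrics(nabb_tracks[[k]], mask = mask))))
}

#' Aggregate metrics of all non-sensorimotor NABBs
#'
#' Union of every NABB track except the designated state, then the
#' shared metrics engine — the "other NABBs" endpoint.
#'
#' @param nabb_tracks list of K NABB [binary_track]s.
#' @param excluded_state state index to leave out (the sensorimotor
#'   state).
#' @param mask optional retention mask.
#' @return One-row metrics `data.frame`.
#' @export
other_nabb_aggregate <- function(nabb_tracks, excluded_state,
                                 mask = NULL) {
  keep <- setdiff(seq_along(nabb_tracks), excluded_state)
  on <- Reduce(`|`, lapply(nabb_tracks[keep], `[[`, "on"))
  track_metrics(binary_track(on, nabb_tracks[[1]]$fs, "NABB_other"),
                mask = mask)
}
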