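# Synthetic longitudinal cohort generator. The generator instantiates
# exactly the structures the model's three regularizers target: correlated
# feature blocks, subjects drawn from a common covariance (hence similar
# subjects get similar scores), correlated score types, plus a sparse
# feature support shared by every time point with temporally smooth weights.

#' Specification of a synthetic longitudinal cohort
#'
#' Defaults mirror a desk-scale version of a typical AD progression cohort:
#' 93 ROI volumetric features, 2 cognitive score types, 4 time points
#' (baseline plus three follow-ups), 10 truly predictive features.
#'
#' @param n_subjects number of subjects S (default 200).
#' @param n_features number of baseline features F (default 93).
#' @param n_scores number of score types C (default 2).
#' @param n_timepoints number of time points T (default 4).
#' @param support_size number k of features with nonzero weights, shared by
#'   all time points and scores (default 10).
#' @param feature_block_corr within-block feature correlation rho in [0, 1)
#'   (default 0.3); features are grouped in consecutive blocks of
#'   `block_size`.
#' @param block_size features per correlated block (default 10).
#' @param temporal_drift per-step weight growth delta: weights at time t are
#'   scaled by `1 + delta * (t - 1)` (default 0.1), so later time points
#'   carry larger signal.
#' @param score_corr target correlation between score columns (default 0.6),
#'   induced exactly in the noiseless signals and matched in the noise.
#' @param noise_sd additive Gaussian noise sd on every score (default 0.5;
#'   signals are calibrated to unit variance, so this is a signal-to-noise
#'   ratio of 2).
#' @param signal_sd sd of each score's noiseless signal (default 1).
#' @param seed default seed used by [simulate_cohort()].
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 200, n_features = 93, n_scores = 2,
                            n_timepoints = 4, support_size = 10,
                            feature_block_corr = 0.3, block_size = 10,
                            temporal_drift = 0.1, score_corr = 0.6,
                            noise_sd = 0.5, signal_sd = 1, seed = 1) {
  if (support_size > n_features) stop("support_size must be <= n_features")
  if (feature_block_corr < 0 || feature_block_corr >= 1)
    stop("feature_block_corr must be in [0, 1)")
  if (score_corr < 0 || score_corr >= 1) stop("score_corr must be in [0, 1)")
  if (noise_sd < 0 || signal_sd <= 0) stop("invalid variance parameters")
  if (n_subjects < 2 || n_scores < 1 || n_timepoints < 1)
    stop("invalid cohort dimensions")
  structure(as.list(environment()), class = "simulation_spec")
}

mat_sqrt <- function(M, inverse = FALSE) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  if (inverse) {
    if (any(v < 1e-12 * max(v))) stop("matrix not invertible")
    v <- 1 / v
  }
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

default_time_labels <- function(Tn) {
  if (Tn <= 4) c("baseline", "M06", "M12", "M24")[seq_len(Tn)]
  else paste0("T", seq_len(Tn))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a block-correlated Gaussian feature matrix (z-normalized), plants a
#' `support_size`-row weight matrix whose support is identical at every time
#' point, scales weights by `1 + temporal_drift * (t - 1)` with a small
#' N(0, 0.05) on-support perturbation per time point, calibrates the t = 1
#' weight columns so the noiseless score signals have exactly unit variance
#' (`signal_sd`) and pairwise correlation `score_corr`, and adds Gaussian
#' noise with the same correlation so the observed score correlation matches
#' the target in expectation. Group labels (NC/MCI/AD) are terciles of the
#' first score's baseline signal.
#'
#' @param spec a [simulation_spec()].
#' @param seed overrides `spec$seed`.
#' @return list of class `smtl_cohort` with `x` (S x F, z-normalized, with
#'   subject/feature names), `y` (T x S x C array), `w_true` (list
#'   `per_time` + `unfolded`), `support` (increasing indices),
#'   `group_labels`, `time_labels`, `score_names`, `spec`.
#' @export
simulate_cohort <- function(spec = simulation_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(seed, {
    S <- spec$n_subjects; F_ <- spec$n_features; C <- spec$n_scores
    Tn <- spec$n_timepoints; k <- spec$support_size
    rho <- spec$feature_block_corr

    block <- ceiling(seq_len(F_) / spec$block_size)
    Z <- matrix(rnorm(S * F_), S, F_)
    shared <- matrix(rnorm(S * max(block)), S, max(block))
    X <- sqrt(rho) * shared[, block, drop = FALSE] + sqrt(1 - rho) * Z
    colnames(X) <- sprintf("ROI_%03d", seq_len(F_))
    rownames(X) <- sprintf("subj_%04d", seq_len(S))
    Xz <- z_normalize(X)

    support <- sort(sample.int(F_, k))
    W0 <- matrix(0, F_, C)
    W0[support, ] <- rnorm(k * C)
    # calibrate: noiseless signals get sd = signal_sd and pairwise
    # correlation = score_corr exactly (empirically, not just in expectation)
    R <- matrix(spec$score_corr, C, C); diag(R) <- 1
    if (C > 1) {
      G <- crossprod(Xz %*% W0) / (S - 1)
      W1 <- W0 %*% (mat_sqrt(G, inverse = TRUE) %*% mat_sqrt(R)) *
        spec$signal_sd
    } else {
      s0 <- sd(Xz %*% W0)
      W1 <- W0 / s0 * spec$signal_sd
    }

    W <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      Wt <- (1 + spec$temporal_drift * (t - 1)) * W1
      if (t > 1)
        Wt[support, ] <- Wt[support, ] + matrix(rnorm(k * C, sd = 0.05), k, C)
      W[[t]] <- Wt
    }

    noise_chol <- chol(R) * spec$noise_sd
    y <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      E <- if (spec$noise_sd > 0)
        matrix(rnorm(S * C), S, C) %*% noise_chol else matrix(0, S, C)
      y[[t]] <- Xz %*% W[[t]] + E
    }
    time_labels <- default_time_labels(Tn)
    score_names <- paste0("score_", seq_len(C))
    names(y) <- time_labels
    for (t in seq_len(Tn)) colnames(y[[t]]) <- score_names

    s1 <- drop(Xz %*% W1[, 1])
    qs <- stats::quantile(s1, c(1 / 3, 2 / 3))
    groups <- cut(s1, c(-Inf, qs, Inf), labels = c("NC", "MCI", "AD"))

    structure(list(
      x = Xz,
      y = as_score_array(y, time_labels, rownames(X), score_names),
      w_true = list(per_time = W, unfolded = unfold_weights(W)),
      support = support,
      group_labels = stats::setNames(as.character(groups), rownames(X)),
      time_labels = time_labels, score_names = score_names,
      spec = spec, seed = seed), class = "smtl_cohort")
  })
}

#' Write a cohort as the CSV fixtures the readers consume
#'
#' Emits `features.csv` (wide: `subject_id` + one column per feature) and
#' `scores.csv` (long: `subject_id`, `time_label`, `score_name`, `value`),
#' plus `truth.json` recording the planted support and group labels.
#'
#' @param cohort an `smtl_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "smtl_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fpath <- file.path(dir, "features.csv")
  spath <- file.path(dir, "scores.csv")
  tpath <- file.path(dir, "truth.json")
  fx <- data.frame(subject_id = rownames(cohort$x), cohort$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(fx, fpath, row.names = FALSE, quote = FALSE)
  y <- cohort$y
  long <- expand.grid(subject_id = rownames(cohort$x),
                      time_label = cohort$time_labels,
                      score_name = cohort$score_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- mapply(function(s, t, c) {
    y[match(t, cohort$time_labels), match(s, rownames(cohort$x)),
      match(c, cohort$score_names)]
  }, long$subject_id, long$time_label, long$score_name)
  utils::write.csv(long, spath, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    support = cohort$support, group_labels = as.list(cohort$group_labels),
    seed = cohort$seed,
    spec = unclass(cohort$spec)), tpath, auto_unbox = TRUE, digits = NA)
  invisible(c(features = fpath, scores = spath, truth = tpath))
}
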