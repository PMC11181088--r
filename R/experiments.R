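# Packaged validation experiments: each runs one of the study's synthetic
# benchmarks end to end and returns the summary quantities.  The analysis
# drivers and the acceptance script are thin wrappers over these.

#' Family-wise error calibration of the cluster permutation test
#'
#' Simulates null map stacks (exchangeable, symmetric about zero), runs the
#' max-sum sign-flip cluster permutation on each, and reports the fraction
#' of replicates with any cluster significant at `alpha` — the empirical
#' family-wise type-I error.
#'
#' @param n_replicates Number of null datasets (default 200).
#' @param n_subjects Subjects per dataset (default 8).
#' @param grid Map grid (default 20^3).
#' @param n_perm Permutations per test (default 500).
#' @param initial_p Cluster-forming threshold.
#' @param alpha Cluster significance level.
#' @param seed Integer seed.
#' @return List with `fwer`, `n_replicates`, and the per-replicate minimum
#'   cluster p-values (`Inf` where no cluster formed).
#' @export
calibrate_cluster_fwer <- function(n_replicates = 200L, n_subjects = 8L,
                                   grid = c(20L, 20L, 20L), n_perm = 500L,
                                   initial_p = 0.001, alpha = 0.05,
                                   seed = 1L) {
  min_p <- vapply(seq_len(n_replicates), function(r) {
    st <- generate_subject_maps(n_subjects, grid, blob = NULL, noise_sd = 1,
                                seed = seed + 1000L * r)
    cr <- cluster_permutation(st, initial_p = initial_p, n_perm = n_perm,
                              seed = seed + 1000L * r + 1L)
    if (nrow(cr$clusters)) min(cr$clusters$p) else Inf
  }, numeric(1))
  list(fwer = mean(min_p < alpha), n_replicates = n_replicates,
       min_p = min_p)
}

#' Power check: detection of a planted high-amplitude blob
#'
#' @param amplitude_sd_ratio Blob amplitude in units of the map noise SD.
#' @param n_subjects,grid,n_perm,seed As in [calibrate_cluster_fwer()].
#' @return List with `p` (cluster p-value of the blob cluster) and the
#'   [cluster_permutation()] result.
#' @export
planted_blob_detection <- function(amplitude_sd_ratio = 5, n_subjects = 8L,
                                   grid = c(20L, 20L, 20L), n_perm = 500L,
                                   seed = 1L) {
  ctr <- round(grid / 2)
  st <- generate_subject_maps(n_subjects, grid,
                              blob = list(center = ctr, radius = 3,
                                          amplitude = amplitude_sd_ratio),
                              noise_sd = 1, seed = seed)
  cr <- cluster_permutation(st, initial_p = 0.001, n_perm = n_perm,
                            seed = seed + 1L)
  lab <- cr$cluster_labels[ctr[1], ctr[2], ctr[3]]
  p <- if (lab > 0) cr$clusters$p[cr$clusters$label == lab] else 1
  list(p = p, result = cr)
}

#' Model recovery on synthetic poses with planted geometry
#'
#' Per replicate: generates poses, builds the five pose/viewpoint model
#' RDMs, plants the view-independent 3D geometry in voxel responses, and
#' runs ROI RSA with every model; records whether the planted model attains
#' the highest correlation, and the partial correlation of the planted
#' model controlling for the viewpoint and view-dependent models.
#'
#' @param n_replicates Number of replicates (default 100).
#' @param n_items Poses per replicate (default 60).
#' @param noise_sd Trial noise SD (default 0.5 on the unit signal scale).
#' @param n_voxels Voxels (default 300).
#' @param seed Integer seed.
#' @return List with `recovery_rate`, `rank_first` (logical vector),
#'   `partial_r` (per-replicate partial correlations), `mean_partial`, and
#'   `partial_p` (one-sided t test of partial r > 0).
#' @export
model_recovery_experiment <- function(n_replicates = 100L, n_items = 60L,
                                      noise_sd = 0.5, n_voxels = 300L,
                                      seed = 1L) {
  models <- c("view_dep_3d", "view_dep_2d", "view_indep_3d", "viewpoint",
              "joint_rotation")
  rank_first <- logical(n_replicates)
  partial_r <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    g <- generate_poses(n_items, seed = seed + 17L * r)
    rdms <- lapply(models, function(m) build_model_rdm(g$poses, m))
    names(rdms) <- models
    out <- generate_responses(rdms["view_indep_3d"], 1,
                              synthetic_config(n_voxels = n_voxels,
                                               n_repeats = 2L,
                                               noise_sd = noise_sd,
                                               seed = seed + 17L * r + 1L))
    rd <- roi_dataset("sim", out$dataset$betas,
                      out$dataset$trial_image_ids)
    nrdm <- neural_rdm(prepare_patterns(neural_dataset(
      rd$betas, rd$trial_image_ids)))
    rs <- vapply(rdms, function(m)
      rsa_correlation(nrdm, normalize_rdm(m)), numeric(1))
    rank_first[r] <- names(which.max(rs)) == "view_indep_3d"
    partial_r[r] <- partial_rsa(nrdm, normalize_rdm(rdms$view_indep_3d),
                                lapply(rdms[c("viewpoint", "view_dep_3d",
                                              "view_dep_2d")],
                                       normalize_rdm))
  }
  tt <- stats::t.test(partial_r, alternative = "greater")
  list(recovery_rate = mean(rank_first), rank_first = rank_first,
       partial_r = partial_r, mean_partial = mean(partial_r),
       partial_p = tt$p.value)
}

#' Noise-ceiling benchmark against the generative oracle
#'
#' Generates a two-repeat dataset from known signal and noise Gaussians,
#' estimates the ceiling blind (from the data alone), and computes the
#' oracle ceiling by the same Monte Carlo using the true generating
#' distributions.
#'
#' @param n_items Images (default 100).
#' @param n_voxels Voxels (default 40).
#' @param noise_scale Multiplier on the noise covariance (default 1).
#' @param n_sim Simulations for both estimates (default 500).
#' @param seed Integer seed.
#' @return List with `estimate`, `oracle`, and their difference.
#' @export
noise_ceiling_benchmark <- function(n_items = 100L, n_voxels = 40L,
                                    noise_scale = 1, n_sim = 500L,
                                    seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- n_voxels
  A <- matrix(stats::rnorm(p * p), p); sigma_s <- crossprod(A) / p
  B <- matrix(stats::rnorm(p * p), p)
  sigma_n <- noise_scale * 0.8 * crossprod(B) / p
  Ls <- chol(sigma_s); Ln <- chol(sigma_n)
  draw <- function(L) matrix(stats::rnorm(n_items * p), n_items) %*% L
  sig <- draw(Ls)
  rd <- roi_dataset("sim", rbind(sig + draw(Ln), sig + draw(Ln)),
                    rep(sprintf("i%04d", seq_len(n_items)), 2))
  est <- estimate_noise_ceiling(rd, n_sim = n_sim, seed = seed + 1L)
  tri <- function(m) m[lower.tri(m)]
  oracle <- mean(vapply(seq_len(n_sim), function(i) {
    s <- draw(Ls)
    noisy <- (s + draw(Ln) + s + draw(Ln)) / 2
    stats::cor(tri(rsm_from_patterns(s)), tri(rsm_from_patterns(noisy)))
  }, numeric(1)))
  list(estimate = est$ceiling, oracle = oracle,
       difference = est$ceiling - oracle, detail = est)
}
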