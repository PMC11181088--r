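# Group inference on stacks of subject maps: per-voxel one-sample t on
# Fisher-z values and family-wise error control by a max-sum cluster-based
# sign-flip Monte Carlo permutation test.

#' Stack aligned subject brain maps
#'
#' @param maps List of [brain_map()]s on one shared grid (>= 2 subjects).
#' @param subject_ids Optional subject labels.
#' @return A `map_stack`: list with `data` (subject x voxel matrix over the
#'   full grid, NaN outside mask), `dim`, `subject_ids`, `voxel_size_mm`.
#' @export
map_stack <- function(maps, subject_ids = NULL) {
  stopifnot(length(maps) >= 2L,
            all(vapply(maps, inherits, logical(1), "brain_map")))
  dims <- unique(lapply(maps, `[[`, "dim"))
  if (length(dims) != 1L) stop("subject maps differ in grid shape",
                               call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_along(maps))
  data <- do.call(rbind, lapply(maps, function(m) as.vector(m$volume)))
  structure(list(data = data, dim = dims[[1]],
                 subject_ids = subject_ids,
                 voxel_size_mm = maps[[1]]$voxel_size_mm),
            class = "map_stack")
}

# One-sample t per column of an n x v matrix; columns with < 2 finite values
# or zero variance give NaN. Returns list(t, n_eff).
column_t <- function(x) {
  fin <- is.finite(x)
  n_eff <- colSums(fin)
  xz <- ifelse(fin, x, 0)
  s1 <- colSums(xz)
  s2 <- colSums(xz^2)
  mu <- s1 / n_eff
  varv <- (s2 - n_eff * mu^2) / (n_eff - 1)
  varv[varv < 0] <- 0
  t <- mu / sqrt(varv / n_eff)
  t[n_eff < 2 | varv == 0] <- NaN
  list(t = t, n_eff = n_eff)
}

#' Group one-sample t map
#'
#' Per-voxel one-sample t statistic (`mean / (sd / sqrt(n))`, n-1 sd
#' denominator) over subjects, excluding NaN subject values voxel-wise with
#' adjusted n.  Voxels with fewer than 2 finite subject values, or zero
#' across-subject variance, are NaN (never +/- Inf).
#'
#' @param stack A [map_stack()].
#' @return A [brain_map()] of t values.
#' @export
group_t_map <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  ct <- column_t(stack$data)
  brain_map(array(ct$t, dim = stack$dim),
            voxel_size_mm = stack$voxel_size_mm, space = "shared")
}

neighbor_offsets <- function(connectivity = c(26L, 18L, 6L)) {
  connectivity <- as.integer(connectivity[1])
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be 6, 18 or 26", call. = FALSE))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D logical array
#'
#' Breadth-first flood over the chosen voxel connectivity; labels are
#' assigned in first-encounter (linear index) order starting at 1, with 0
#' as background.
#'
#' @param x Logical 3D array.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners).
#' @return Integer array of the same shape.
#' @export
label_components <- function(x, connectivity = 26L) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  dm <- dim(x)
  off <- neighbor_offsets(connectivity)
  loff <- off[, 1] + off[, 2] * dm[1] + off[, 3] * dm[1] * dm[2]
  # pad guard: work on the padded array so linear-offset moves cannot wrap
  pd <- dm + 2L
  padded <- array(FALSE, pd)
  padded[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- x
  ploff <- off[, 1] + off[, 2] * pd[1] + off[, 3] * pd[1] * pd[2]
  labels <- array(0L, pd)
  nextlab <- 0L
  todo <- which(padded)
  for (seed in todo) {
    if (labels[seed] != 0L) next
    nextlab <- nextlab + 1L
    queue <- seed
    labels[seed] <- nextlab
    while (length(queue)) {
      frontier <- unique(as.vector(outer(queue, ploff, "+")))
      frontier <- frontier[padded[frontier] & labels[frontier] == 0L]
      labels[frontier] <- nextlab
      queue <- frontier
    }
  }
  labels[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
}

max_cluster_sum <- function(tvec, supra, dm, connectivity) {
  if (!any(supra)) return(0)
  lab <- label_components(array(supra, dm), connectivity)
  sums <- rowsum(tvec[supra], as.vector(lab)[supra])
  max(sums)
}

#' Max-sum cluster-based sign-flip permutation test
#'
#' Thresholds the observed group t map at one-tailed `p < initial_p` (right
#' tail, df = n-1), labels supra-threshold clusters, and compares each
#' cluster's sum-of-t statistic against the null distribution of the
#' maximum cluster sum over `n_perm` random whole-map sign flips of the
#' subjects (the exchangeable one-sample null of maps symmetric about
#' zero).  Cluster p-values use the never-zero `(1 + k) / (1 + n_perm)`
#' estimator.
#'
#' @param stack A [map_stack()].
#' @param initial_p Cluster-forming threshold (one-tailed voxel p), in
#'   (0, 0.5); classic choice 0.001.
#' @param n_perm Number of sign-flip permutations (>= 100; classic 10000).
#' @param seed Integer seed for the sign flips.
#' @param connectivity 6, 18 or 26 (default).
#' @return A `cluster_result`: list with `t_map` ([brain_map()]),
#'   `cluster_labels` (integer array), `clusters` (data.frame: label, size,
#'   sum_t, p), `null_max` (length `n_perm`), plus threshold parameters and
#'   the seed.
#' @export
cluster_permutation <- function(stack, initial_p = 0.001, n_perm = 10000L,
                                seed = 1L, connectivity = 26L) {
  stopifnot(inherits(stack, "map_stack"))
  if (nrow(stack$data) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (initial_p <= 0 || initial_p >= 0.5) {
    stop("initial_p must be in (0, 0.5)", call. = FALSE)
  }
  X <- stack$data
  n_sub <- nrow(X)
  dm <- stack$dim
  inmask <- colSums(is.finite(X)) == n_sub
  Xm <- X[, inmask, drop = FALSE]
  t_crit <- stats::qt(1 - initial_p, df = n_sub - 1)

  obs <- column_t(Xm)$t
  obs_supra <- is.finite(obs) & obs > t_crit
  tfull <- rep(NaN, length(inmask)); tfull[inmask] <- obs
  supra_full <- rep(FALSE, length(inmask)); supra_full[inmask] <- obs_supra
  lab <- label_components(array(supra_full, dm), connectivity)
  labs <- sort(unique(as.vector(lab)[as.vector(lab) > 0]))
  clusters <- data.frame(label = integer(0), size = integer(0),
                         sum_t = numeric(0), p = numeric(0))
  # null distribution of the max cluster sum; sum of squares is invariant
  # under sign flips so only the per-permutation means need recomputing
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); code
  }
  null_max <- withr_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                    n_perm, n_sub)
    ss <- colSums(Xm^2)
    M <- signs %*% Xm / n_sub
    V <- sweep(-n_sub * M^2, 2, ss, "+") / (n_sub - 1)
    V[V < 0] <- 0
    Tp <- M / sqrt(V / n_sub)
    vapply(seq_len(n_perm), function(p) {
      tp <- Tp[p, ]
      sp <- is.finite(tp) & tp > t_crit
      spf <- rep(FALSE, length(inmask)); spf[inmask] <- sp
      tpf <- rep(0, length(inmask)); tpf[inmask][sp] <- tp[sp]
      max_cluster_sum(tpf, spf, dm, connectivity)
    }, numeric(1))
  })
  if (length(labs)) {
    sums <- vapply(labs, function(l) sum(tfull[as.vector(lab) == l]),
                   numeric(1))
    sizes <- vapply(labs, function(l) sum(as.vector(lab) == l), integer(1))
    pvals <- vapply(sums, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                    numeric(1))
    clusters <- data.frame(label = labs, size = sizes, sum_t = sums,
                           p = pvals)
  }
  structure(list(
    t_map = brain_map(array(tfull, dm), voxel_size_mm = stack$voxel_size_mm,
                      space = "shared"),
    cluster_labels = lab, clusters = clusters, null_max = null_max,
    initial_p = initial_p, t_crit = t_crit, n_perm = n_perm, seed = seed,
    connectivity = connectivity), class = "cluster_result")
}
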