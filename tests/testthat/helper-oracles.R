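# Independent oracles and small constructors shared across tests.

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

# pose with given joints (defaults to the template), rotation, id
make_pose <- function(id = "a", joints = template_skeleton(), R = diag(3),
                      joint_rotations = NULL) {
  pose_record(id, joints, R, joint_rotations)
}

# brute-force fixed-count neighborhoods: per center, full distance vector,
# ordered by distance then lexicographic (i, j, k) via explicit sort keys
brute_force_neighborhoods <- function(mask, voxel_size, count) {
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(c_i) {
    d <- sqrt(colSums((t(idx) - idx[c_i, ])^2)) * voxel_size
    ord <- order(d, idx[, 1], idx[, 2], idx[, 3])
    ord[seq_len(count)]
  })
}

# brute-force connected-component labeling by depth-first flood fill with
# explicit neighbor scanning in array coordinates
flood_fill_labels <- function(x, connectivity = 26L) {
  dm <- dim(x)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off)
  lab <- array(0L, dm)
  nxt <- 0L
  for (lin in which(x)) {
    if (lab[lin] != 0L) next
    nxt <- nxt + 1L
    stack <- lin
    lab[lin] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(cur, dm)
      for (o in seq_len(nrow(off))) {
        nb <- ci + off[o, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (x[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          nlin <- nb[1] + (nb[2] - 1L) * dm[1] + (nb[3] - 1L) * dm[1] * dm[2]
          lab[nlin] <- nxt
          stack <- c(stack, nlin)
        }
      }
    }
  }
  lab
}

# label arrays agree up to renaming of the labels
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  pos <- a > 0
  length(unique(paste(a[pos], b[pos]))) == length(unique(a[pos])) &&
    length(unique(a[pos])) == length(unique(b[pos]))
}

random_rdm <- function(n, seed, model = "rand") {
  set.seed(seed)
  d <- as.matrix(stats::dist(matrix(stats::rnorm(n * 4), n)))
  rdm(d, sprintf("img%04d", seq_len(n)), model = model)
}
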