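# shared fixtures: kept small so the default test run stays fast

# noiseless phantom on a 32^3 grid, geometry scaled down proportionally
small_phantom_spec <- function(noise_sd = 0, seed = 1L) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), waist_radius = 5, end_radius = 9,
               axial_margin = 3, spine_length = 9, spine_radius = 2,
               spine_angle_deg = 25, shell_thickness = 2,
               noise_sd = noise_sd, seed = seed)
}

small_phantom_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      v <- generate_vertebra_phantom(small_phantom_spec())
      m <- segment_bone(v, threshold = 100)
      cache <<- attach_attenuation(voxels_to_tets(m), v)
    }
    cache
  }
})

# solid block mesh of nx x ny x nz voxels
block_mesh <- function(nx, ny, nz, spacing = 1) {
  voxels_to_tets(array(TRUE, c(nx, ny, nz)), spacing = spacing)
}

# independent 26-connectivity labeling oracle: plain BFS in R
cc_label_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  nl <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nl <- nl + 1L
    queue <- start
    lab[start] <- nl
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (r in seq_len(nrow(nbr))) {
        q <- p + nbr[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nl
          queue <- c(queue, (q[3] - 1) * d[1] * d[2] + (q[2] - 1) * d[1] + q[1])
        }
      }
    }
  }
  attr(lab, "n_components") <- nl
  lab
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
mw_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) sum(ranks[ix]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# pooled-variance t statistic, closed form
pooled_t_oracle <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
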