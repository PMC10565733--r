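# Independent oracles used by the tests. These deliberately re-derive results
# from first principles (naive O(n^3) agglomeration, explicit 3-D vector
# algebra) rather than calling the package's own code paths.

# Brute-force Lance-Williams agglomerative clustering. Works in squared
# distance space for ward/centroid/median (reporting square-rooted heights),
# plain distance space otherwise. Returns merge heights in merge order plus
# the member sets created by each merge.
lw_linkage_oracle <- function(D, method) {
  n <- nrow(D)
  squared <- method %in% c("ward", "centroid", "median")
  W <- if (squared) D^2 else D
  diag(W) <- Inf
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  merged_members <- vector("list", n - 1)

  for (step in seq_len(n - 1)) {
    Wa <- W
    Wa[!active, ] <- Inf
    Wa[, !active] <- Inf
    ij <- which(Wa == min(Wa), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    dij <- W[i, j]
    heights[step] <- if (squared) sqrt(dij) else dij
    ni <- sizes[i]; nj <- sizes[j]
    for (k in seq_len(n)) {
      if (!active[k] || k == i || k == j) next
      nk <- sizes[k]
      co <- switch(method,
        single   = c(0.5, 0.5, 0, -0.5),
        complete = c(0.5, 0.5, 0, 0.5),
        average  = c(ni / (ni + nj), nj / (ni + nj), 0, 0),
        weighted = c(0.5, 0.5, 0, 0),
        centroid = c(ni / (ni + nj), nj / (ni + nj),
                     -ni * nj / (ni + nj)^2, 0),
        median   = c(0.5, 0.5, -0.25, 0),
        ward     = c((ni + nk) / (ni + nj + nk), (nj + nk) / (ni + nj + nk),
                     -nk / (ni + nj + nk), 0)
      )
      W[i, k] <- W[k, i] <- co[1] * W[i, k] + co[2] * W[j, k] +
        co[3] * dij + co[4] * abs(W[i, k] - W[j, k])
    }
    sizes[i] <- ni + nj
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    merged_members[[step]] <- members[[i]]
    active[j] <- FALSE
    W[j, ] <- Inf
    W[, j] <- Inf
  }
  list(heights = heights, members = merged_members)
}

# Random symmetric distance matrix with zero diagonal (entries in (0, 2)).
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0.05, 2)
  M + t(M)
}

# d-spacing from explicit reciprocal-basis construction (vector algebra),
# independent of the metric-tensor route.
d_spacing_oracle <- function(cell, h, k, l) {
  deg <- pi / 180
  ca <- cos(cell$alpha * deg); cb <- cos(cell$beta * deg)
  cg <- cos(cell$gamma * deg); sg <- sin(cell$gamma * deg)
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz <- sqrt(cell$c^2 - cx^2 - cy^2)
  cv <- c(cx, cy, cz)
  V <- sum(av * pracma_cross(bv, cv))
  astar <- pracma_cross(bv, cv) / V
  bstar <- pracma_cross(cv, av) / V
  cstar <- pracma_cross(av, bv) / V
  g <- h * astar[1] + k * bstar[1] + l * cstar[1]
  g2 <- h * astar[2] + k * bstar[2] + l * cstar[2]
  g3 <- h * astar[3] + k * bstar[3] + l * cstar[3]
  1 / sqrt(g^2 + g2^2 + g3^2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# A random valid triclinic cell (rejection-sampled for positive-definite
# metric).
random_triclinic_cell <- function(seed) {
  set.seed(seed)
  repeat {
    cand <- try(unit_cell(runif(1, 20, 120), runif(1, 20, 120),
                          runif(1, 20, 120),
                          runif(1, 70, 110), runif(1, 70, 110),
                          runif(1, 70, 110)),
                silent = TRUE)
    if (!inherits(cand, "try-error")) return(cand)
  }
}

# Small deterministic chunk built from explicit records.
make_chunk <- function(id, hkl, intensity, sigma = rep(1, length(intensity)),
                       cell = NULL, label = NULL) {
  reflection_chunk(
    tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   intensity = intensity, sigma = sigma),
    chunk_id = id, cell = cell, label = label
  )
}

# Index matrix for n reflections along a simple deterministic pattern.
simple_hkl <- function(n) {
  cbind(seq_len(n), seq_len(n) %% 5, seq_len(n) %% 7)
}
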