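# shared fixture builders; everything is generated in code

# random open polyline with n vertices
random_polyline <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(cumsum(runif(n, 0.2, 2)), cumsum(rnorm(n)))
}

# brute-force arc-length resampling oracle: walk the polyline at a fine
# step and pick the nearest walked point to each target arc length
resample_oracle <- function(polyline, k, step = 1e-6) {
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  targets <- seq(0, total, length.out = k)
  cum <- c(0, cumsum(seg_len))
  out <- matrix(NA_real_, k, 2)
  for (j in seq_len(k)) {
    t <- min(targets[j], total)
    i <- max(1L, min(findInterval(t, cum, rightmost.closed = TRUE),
                     length(seg_len)))
    frac <- if (seg_len[i] > 0) (t - cum[i]) / seg_len[i] else 0
    out[j, ] <- polyline[i, ] + frac * seg[i, ]
  }
  out
}

# random non-degenerate configuration of p landmarks
random_config <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(2 * p), p, 2)
}

# apply a random similarity transform (rotation + scale + translation)
random_similarity <- function(config) {
  ang <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  sc <- exp(runif(1, -1, 1))
  tr <- rnorm(2, sd = 3)
  sweep(sc * config %*% R, 2, -tr)
}

# closed-form full Procrustes distance between two planar configurations
# (complex Hermitian inner product of centred unit vectors); independent
# of the package's alignment code path
full_procrustes_oracle <- function(A, B) {
  zA <- complex(real = A[, 1], imaginary = A[, 2])
  zB <- complex(real = B[, 1], imaginary = B[, 2])
  zA <- zA - mean(zA); zB <- zB - mean(zB)
  zA <- zA / sqrt(sum(Mod(zA)^2)); zB <- zB / sqrt(sum(Mod(zB)^2))
  sqrt(max(0, 1 - Mod(sum(Conj(zA) * zB))^2))
}

# random DNA sequence
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stochastic K2P sequence pair at expected divergence d, ts/tv ratio kappa
mutate_pair <- function(d, L = 614, kappa = 2) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  pq <- fleamorph:::.k2pInvert(d, kappa)
  u <- runif(L)
  mut <- anc
  ts <- u < pq["P"]
  tv <- u >= pq["P"] & u < pq["P"] + pq["Q"]
  mut[ts] <- c(A = "G", G = "A", C = "T", T = "C")[mut[ts]]
  for (s in which(tv))
    mut[s] <- sample(if (mut[s] %in% c("A", "G")) c("C", "T")
                     else c("A", "G"), 1)
  c(paste(anc, collapse = ""), paste(mut, collapse = ""))
}
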