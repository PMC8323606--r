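# Independent oracles used across the test files.

# Brute-force propagation of dc/dt = L c + b by classic RK4 with a fine
# fixed step; independent of the matrix-exponential path under test.
rk4_propagate <- function(L, b, c0, t_s, n_steps = 4000) {
  h <- t_s / n_steps
  x <- c0
  f <- function(x) L %*% x + b
  for (i in seq_len(n_steps)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(x)
}

# Direct (loop) masked mean/sd
masked_stats_oracle <- function(img, roi, excl) {
  vals <- c()
  for (i in seq_along(img))
    if (roi[i] && !excl[i]) vals <- c(vals, img[i])
  list(mean = mean(vals), sd = sd(vals), n = length(vals))
}

# Dense spatial-domain convolution oracle (no FFT), kernel normalized to
# unit sum, kernel center aligned with the output voxel.
dense_convolve_oracle <- function(vol, kernel) {
  k <- kernel / sum(kernel)
  nv <- dim(vol); nk <- dim(k); ctr <- floor(nk / 2) + 1
  out <- array(0, nv)
  nz <- which(vol != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    v <- vol[nz[r, 1], nz[r, 2], nz[r, 3]]
    for (a in seq_len(nk[1])) for (b in seq_len(nk[2])) for (cc in seq_len(nk[3])) {
      i <- nz[r, 1] + a - ctr[1]; j <- nz[r, 2] + b - ctr[2]
      l <- nz[r, 3] + cc - ctr[3]
      if (i >= 1 && i <= nv[1] && j >= 1 && j <= nv[2] && l >= 1 && l <= nv[3])
        out[i, j, l] <- out[i, j, l] + v * k[a, b, cc]
    }
  }
  out
}

# Closed-form spoiled saturation steady state (mono-exponential, ideal
# pulse, TE = 0): |S| = sin(theta) (1 - E1) / (1 - cos(theta) E1)
saturation_formula <- function(theta_deg, TR_ms, R1) {
  th <- theta_deg * pi / 180
  E1 <- exp(-TR_ms / 1000 * R1)
  sin(th) * (1 - E1) / (1 - cos(th) * E1)
}

reference_weighting_values <- function() {
  matrix(c(0.95, 0.95, 0.85, 0.96,
           0.35, 0.35, 0.01, 0.40,
           0.45, 0.45, 0.61, 0.10),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("NaDW", "NaPACMAN", "NaSIRFLA"),
                         c("intra", "extra", "myelin", "edema")))
}
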