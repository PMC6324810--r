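# Independent brute-force oracles used to cross-check the implementation.

# literal per-pixel Phansalkar: loops over every pixel and its disc window
oracle_phansalkar <- function(image8, radius = 5, k = 0.25, r = 0.5,
                              p = 2, q = 10) {
  I8 <- round(image8$pixels)
  ny <- nrow(I8)
  nx <- ncol(I8)
  pad <- groovealign:::mirror_pad(I8, radius)
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  n <- nrow(off)
  out <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      vals <- pad[cbind(y + radius + off$dy, x + radius + off$dx)]
      mu <- sum(vals) / (n * 255)
      va <- max(sum(vals * vals) / (n * 255^2) - mu^2, 0)
      t <- mu * (1 + p * exp(-q * mu) + k * (sqrt(va) / r - 1))
      out[y, x] <- I8[y, x] / 255 > t
    }
  }
  out
}

# 8-connected component labeling by breadth-first flood fill
oracle_label_flood <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      y <- (i - 1) %% ny + 1
      x <- (i - 1) %/% ny + 1
      for (dy in -1:1) for (dx in -1:1) {
        y2 <- y + dy
        x2 <- x + dx
        if (y2 >= 1 && y2 <= ny && x2 >= 1 && x2 <= nx) {
          j <- (x2 - 1) * ny + y2
          if (m[j] && lab[j] == 0) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# circular variance of orientations on the half-circle (degrees)
circular_variance <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  1 - Mod(mean(exp(1i * a)))
}

# small synthetic filament image for directionality tests
filament_test_image <- function(seed, kappa, n = 512, n_filaments = 15,
                                snr = 8) {
  sim <- generate_coculture_stack(
    "flat", n_filaments = n_filaments, alignment_kappa = kappa,
    containment_prob = 0, image_size_px = c(n, n), n_slices = 3,
    snr = snr, seed = seed
  )
  rolling_ball_subtract(max_projection(sim$stack), 50)
}
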