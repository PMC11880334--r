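# fixture builders shared across test files; everything is generated in code

random_rgb <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

# two well-separated intensity blobs with ground-truth labels
two_blob_values <- function(n_per = 500, means = c(10, 200), sd = 1, seed = 1) {
  set.seed(seed)
  list(values = c(rnorm(n_per, means[1], sd), rnorm(n_per, means[2], sd)),
       truth = rep(1:2, each = n_per), means = means)
}

# brute-force GLCM oracle: double loop over all pixel pairs
glcm_bruteforce <- function(indices, d, angle, symmetric, G) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  h <- nrow(indices); w <- ncol(indices)
  counts <- matrix(0, G, G)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        i <- indices[r, c] + 1; j <- indices[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts / sum(counts)
}

# moment-based stats oracle on a plain vector
moments_oracle <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  list(skew = mean((x - m)^3) / m2^1.5, kurt = mean((x - m)^4) / m2^2)
}

# small dark wound-filling phantom: the enhancement operator's design regime
dark_phantom_luv <- function(seed = 42, size = c(96, 96)) {
  sp <- phantom_spec(size = size,
                     fractions = c(superficial = 0.1, dermal = 0, deep = 0.9),
                     geometry = "exact", seed = seed)
  rgb_to_luv(generate_phantom(sp)$image)
}

total_variation <- function(m) {
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}
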