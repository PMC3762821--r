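# Shared fixture builders; everything is generated in code under fixed seeds.

rmse <- function(a, b) sqrt(mean((unlist(a) - unlist(b))^2))

rel_frob <- function(A, B) sqrt(sum((A - B)^2)) / sqrt(sum(B^2))

# Low-rank matrix with sparse sign corruption: the canonical robust-PCA
# recovery instance.
corrupted_lowrank <- function(m = 200, n = 50, rank = 2, frac = 0.02,
                              magnitude = 50, seed = 1) {
  set.seed(seed)
  A0 <- matrix(rnorm(m * rank), m, rank) %*% t(matrix(rnorm(n * rank), n, rank))
  E0 <- matrix(0, m, n)
  idx <- sample(m * n, round(frac * m * n))
  E0[idx] <- sample(c(-magnitude, magnitude), length(idx), replace = TRUE)
  list(D = A0 + E0, A0 = A0, E0 = E0, support = sort(idx))
}

# Random matrix with geometrically decaying spectrum.
decaying_spectrum_matrix <- function(m = 100, n = 40, decay = 0.5, seed = 1) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(m * n), m, n)))
  V <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  d <- decay^(0:(n - 1))
  U %*% (d * t(V))
}

# Small sequence of noisy variations around one shared frame.
tiny_sequence <- function(n = 4, h = 8, w = 8, seed = 1) {
  set.seed(seed)
  base <- matrix(runif(h * w, 0, 255), h, w)
  image_sequence(lapply(seq_len(n), function(i) base))
}

# Published reference (SD, IQMFV) value pairs shipped with the package.
reference_quality_pairs <- function() {
  path <- system.file("extdata", "reference_quality_pairs.csv",
                      package = "ctrestore")
  read.csv(path, stringsAsFactors = FALSE)
}
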