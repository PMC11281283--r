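# Independent brute-force oracles; deliberately naive double-loop code that
# shares no helpers with the package implementation.

# co-occurrence counts by exhaustive pair enumeration
bf_glcm <- function(window, offset, gray_levels, symmetric = FALSE) {
  dx <- offset[1]; dy <- offset[2]
  P <- matrix(0, gray_levels, gray_levels)
  for (r in seq_len(nrow(window))) {
    for (c in seq_len(ncol(window))) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= nrow(window) && c2 >= 1 && c2 <= ncol(window)) {
        i <- window[r, c] + 1; j <- window[r2, c2] + 1
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

# Haralick metrics by explicit double loop over matrix cells
bf_haralick <- function(P) {
  g <- nrow(P)
  mu_i <- 0; mu_j <- 0
  for (i in 1:g) for (j in 1:g) {
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  var_i <- 0; var_j <- 0; hom <- 0; con <- 0; dis <- 0; ent <- 0
  asm <- 0; cov <- 0
  for (i in 1:g) for (j in 1:g) {
    p <- P[i, j]
    di <- (i - 1) - mu_i; dj <- (j - 1) - mu_j; d <- (i - 1) - (j - 1)
    var_i <- var_i + di^2 * p
    var_j <- var_j + dj^2 * p
    hom <- hom + p / (1 + d^2)
    con <- con + d^2 * p
    dis <- dis + abs(d) * p
    if (p > 0) ent <- ent - p * log(p)
    asm <- asm + p^2
    cov <- cov + di * dj * p
  }
  sig <- sqrt(var_i * var_j)
  c(mean = mu_i, variance = var_i, homogeneity = hom, contrast = con,
    dissimilarity = dis, entropy = ent, secondmoment = asm,
    correlation = if (sig == 0) 1 else cov / sig)
}

# nearest-center index mapping by exhaustive distance search
bf_nearest_index <- function(n_in, n_out, factor) {
  vapply(seq_len(n_out), function(i) {
    x <- (i - 0.5) * factor
    d <- abs(x - (seq_len(n_in) - 0.5))
    which(d == min(d))[1]  # tie toward the smaller index
  }, integer(1))
}

# a scene with arbitrary band content and a single full-frame plot
make_flat_scene <- function(bands_list, mask = NULL, gsd = 1) {
  dims <- dim(bands_list[[1]])
  mask <- if (is.null(mask)) matrix(1L, dims[1], dims[2]) else mask
  multiband_scene(bands_list, mask, gsd = gsd)
}

# full 72-plot synthetic chain at a coarse GSD (fast test-scale scenes)
make_test_inputs <- function(seed = 1, base_gsd = 5, noise_sd = 0.01,
                             sigma_plot = 1.5) {
  design <- generate_design(seed)
  truth <- simulate_true_spad(
    design, spad_effect_params(sigma_plot = sigma_plot), seed = seed + 1
  )
  spad <- simulate_measured_spad(truth, spad_protocol(), seed = seed + 2)
  nm <- c(B = noise_sd, G = noise_sd, R = noise_sd, RE = noise_sd,
          NIR = noise_sd)
  scene <- render_scene(design, truth,
                        scene_params(base_gsd = base_gsd, noise_sd = nm,
                                     seed = seed + 3))
  list(design = design, truth = truth, spad = spad, scene = scene)
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  x[sample(length(x))]
}

constant_band_list <- function(value, nr, nc) {
  setNames(
    replicate(5, matrix(value, nr, nc), simplify = FALSE),
    c("B", "G", "R", "RE", "NIR")
  )
}
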