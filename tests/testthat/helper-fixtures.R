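# Shared fixtures and independent oracles, all built in code.

# Closed-form KL between two Gaussians: the independent oracle for the
# numerical quadrature.
kl_gaussian_closed <- function(mu1, sd1, mu2, sd2) {
  log(sd2 / sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 * sd2^2) - 0.5
}

# Small hand-built dataset: 5 materials, mixed measurement counts, two
# base features carrying a clean linear signal.
tiny_dataset <- function() {
  mk <- function(id, x1, x2, y) {
    list(material_id = id,
         base_features = c(temp = x1, dose = x2),
         measurements = y)
  }
  material_dataset(list(
    mk("a", 1, 0.5, c(10, 12, 14)),
    mk("b", 2, 1.0, c(18, 22, 20, 24)),
    mk("c", 3, 1.5, c(30, 28, 32)),
    mk("d", 4, 2.0, c(41, 39)),
    mk("e", 5, 2.5, 50)))
}

# Noiseless linear dataset: y = 3 * x1 + 1 exactly, one measurement each.
linear_dataset <- function(n = 38, seed = 42) {
  withr::with_seed(seed, {
    x1 <- runif(n, 0, 10)
    x2 <- runif(n, 0, 1)
    samples <- lapply(seq_len(n), function(i) {
      list(material_id = sprintf("L%02d", i),
           base_features = c(x1 = x1[i], x2 = x2[i]),
           measurements = 3 * x1[i] + 1)
    })
    material_dataset(samples)
  })
}

linear_sub <- function(n = 38, seed = 42) {
  ds <- linear_dataset(n, seed)
  ft <- assemble_feature_matrix(ds, method_combo("A"))
  generate_subdatasets(ds, 1, seed = 1, feature_table = ft)[[1]]
}

# Fast zoo for pipeline-level tests.
fast_zoo <- function() {
  model_zoo(c("ridge", "tree"),
            grids = list(tree = list(list(maxdepth = 5L))))
}

# A small synthetic configuration for pipeline tests that do not need the
# full 38-material default.
small_config <- function(seed = 1) {
  synthetic_config(
    n_materials = 14L,
    count_histogram = c("1" = 5L, "2" = 4L, "3" = 3L, "4" = 2L),
    image_size = 32L,
    seed = seed)
}
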