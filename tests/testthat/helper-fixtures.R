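# Shared fixture builders.  Everything is generated in code under fixed
# seeds; moderately expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small set of noisy copies of a base configuration, as a k x 3 x n array
noisy_array <- function(n = 6L, k = 10L, sd = 0.1, seed = 42L) {
  set.seed(seed)
  base <- matrix(rnorm(k * 3L, sd = 2), k, 3L)
  arr <- array(NA_real_, c(k, 3L, n),
               dimnames = list(paste0("L", seq_len(k)), c("x", "y", "z"),
                               paste0("spec", seq_len(n))))
  for (i in seq_len(n)) arr[, , i] <- base + matrix(rnorm(k * 3L, sd = sd), k, 3L)
  arr
}

# apply a random similarity transform (rotation + translation + scale)
similarity_transform <- function(m) {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  (m %*% q) * runif(1L, 0.3, 4) +
    matrix(runif(3L, -100, 100), nrow(m), 3L, byrow = TRUE)
}

# default small study-like dataset: 30 species, 40 specimens
small_sim <- function() cached("small_sim", function() {
  spec <- simulation_spec(n_species = 30L, n_specimens = 40L, seed = 7L)
  simulate_landmark_dataset(spec)
})

# its one-per-species GPA with species row names
small_gpa <- function() cached("small_gpa", function() {
  sim <- small_sim()
  sub <- phylogenetic_subset(sim$configs, seed = 1L)
  g <- gpa(sub)
  Y <- flatten_coords(g)
  rownames(Y) <- names(sub)
  list(gpa = g, Y = Y, sub = sub, tree = sim$tree,
       species_table = sim$species_table)
})

# the full 141/96 study-sized fixture (used by io validation + pipeline)
study_sim <- function() cached("study_sim", function() {
  simulate_landmark_dataset(simulation_spec(seed = 99L))
})
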