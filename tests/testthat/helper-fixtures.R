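# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_mesh <- function() fixture("small_mesh", function() {
  generate_disk_mesh(12.5, 300, seed = 5)
})

std_mesh <- function() fixture("std_mesh", function() {
  generate_disk_mesh(12.5, 852, seed = 11)
})

tiny_mesh <- function() fixture("tiny_mesh", function() {
  generate_disk_mesh(10, 40, seed = 3)
})

uniform_optics <- function(mesh, mua = 0.01, musp = 0.8) {
  optical_map(rep(mua, mesh$n_nodes), rep(musp, mesh$n_nodes))
}

# A tiny separable tile-classification problem: positives carry a bright
# square blob over low-amplitude noise.
toy_tiles <- function(n = 300, w = 16, p_pos = 0.4, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(w * w * n, 0, 0.05), w * w, n)
  lab <- rbinom(n, 1, p_pos)
  for (i in which(lab == 1)) {
    cx <- sample(4:(w - 4), 1); cy <- sample(4:(w - 4), 1)
    img <- matrix(X[, i], w, w)
    img[(cx - 2):(cx + 2), (cy - 2):(cy + 2)] <-
      img[(cx - 2):(cx + 2), (cy - 2):(cy + 2)] + 1
    X[, i] <- as.vector(img)
  }
  list(X = X, labels = lab)
}
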