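# Shared fixtures, generated in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a mid-sized phantom with every artifact class
full_phantom <- function() {
  fixture("full", generate_phantom(phantom_spec(seed = 1)))
}

# small clean phantom (no artifacts) for io/cluster tests
clean_phantom <- function() {
  fixture("clean", generate_phantom(phantom_spec(image_size = 300, seed = 2,
                                                 artifacts = "none")))
}

# two well-separated Gaussian blobs in 2-D with labels
two_blobs <- function(n = 500, sep = 10, sd = 1, seed = 7) {
  withr::with_seed(seed, {
    x <- rbind(cbind(rnorm(n, 0, sd), rnorm(n, 0, sd)),
               cbind(rnorm(n, sep, sd), rnorm(n, sep, sd)))
    list(x = x, labels = rep(0:1, each = n))
  })
}

# a tiny multiplex image made from explicit channel matrices
toy_image <- function(..., pixel_size = 0.65) {
  chans <- list(...)
  arr <- array(unlist(chans), c(dim(chans[[1]]), length(chans)))
  multiplex_image(arr, names(chans), pixel_size,
                  cycle_of = seq_along(chans),
                  dna_channels = names(chans)[1])
}
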