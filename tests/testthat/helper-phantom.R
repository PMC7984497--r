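# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_phantom <- function() cached("phantom", build_phantom(phantom_spec()))

noiseless_dixon <- function() {
  cached("dixon0", simulate_dixon(default_phantom(), noise_sigma = 0,
                                  seed = 1))
}

# smaller grid for the registration-heavy tests
small_phantom <- function() {
  cached("small_phantom", build_phantom(phantom_spec(shape = c(48, 64, 64))))
}

dice <- function(a, b) {
  if (is_vol3d_like(a)) a <- a$data
  if (is_vol3d_like(b)) b <- b$data
  2 * sum(a & b) / (sum(a) + sum(b))
}

is_vol3d_like <- function(x) is.list(x) && !is.null(x$data)

# random grid-compatible dixon + masks for oracle comparisons
random_case <- function(seed, shape = c(8, 8, 8)) {
  set.seed(seed)
  n <- prod(shape)
  w <- vol3d(array(runif(n, 0, 120), shape))
  f <- vol3d(array(runif(n, 0, 120), shape))
  body <- array(runif(n) < 0.8, shape)
  bone <- body & array(runif(n) < 0.3, shape)
  masks <- mask_set(vol3d(body), vol3d(bone))
  model <- hu_model(water_center = c(100, 5), fat_center = c(10, 95))
  list(dixon = dixon_volume(w, f), masks = masks, model = model)
}
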