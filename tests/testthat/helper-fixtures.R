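# Phantom builds are the slow part of the suite; cache them across tests.
.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

clean_phantom <- function() {
  cached_phantom("clean", function()
    build_phantom(default_phantom_spec(psf_fwhm = 0, noise_sd = 0)))
}

# A small random SUV volume plus a random VOI, for brute-force oracles.
random_suv_volume <- function(n = 12, seed = 1, spacing = c(4, 4, 2)) {
  set.seed(seed)
  v <- pet_volume(array(stats::runif(n^3, 0, 20), dim = rep(n, 3)), spacing)
  voi <- voi_mask(array(stats::runif(n^3) < 0.5, dim = rep(n, 3)),
                  "LEFT_KIDNEY")
  list(volume = v, voi = voi)
}
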