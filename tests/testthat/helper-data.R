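# Shared fixtures, memoized so expensive objects are built once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_spec <- function() memo("spec64", phantom_spec())

spec32 <- function() memo("spec32", phantom_spec(image_size = 32))

# small 32x32 model for cheap architecture tests
model32 <- function() memo("model32", dsclp_model(image_size = 32, seed = 1))

phantoms64 <- function(n, seed) {
  memo(sprintf("ph64_%d_%d", n, seed), make_dataset(default_spec(), n, seed))
}

phantoms32 <- function(n, seed) {
  memo(sprintf("ph32_%d_%d", n, seed), make_dataset(spec32(), n, seed))
}

# the desk-preset smoke model: 256 phantoms at 64x64, 5 epochs, batch 16
smoke_state <- function(seed) {
  memo(sprintf("smoke_%d", seed), {
    dat <- memo("smoke_data", make_dataset(default_spec(), 256, 11))
    fit(dat, train_config(preset = "desk", seed = seed))
  })
}

# phantoms for the augmentation-utility experiments
eval_split <- function() {
  memo("eval_split", {
    ds <- make_dataset(default_spec(), 200, 33)
    list(train = ds[1:128], test = ds[129:200])
  })
}
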