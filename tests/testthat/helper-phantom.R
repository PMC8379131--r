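# Shared fixtures, built in code and cached per test run.

# small phantom (fast) reused across files
tiny_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, shape = c(48L, 48L, 48L), spacing = c(4, 4, 4), ...) {
    key <- paste(seed, paste(shape, collapse = "x"), paste(spacing, collapse = "x"),
                 sep = "|")
    extras <- list(...)
    if (length(extras) == 0 && !is.null(cache[[key]])) return(cache[[key]])
    ph <- generate_phantom(do.call(phantom_spec, c(
      list(shape = shape, spacing = spacing, seed = seed), extras)))
    if (length(extras) == 0) cache[[key]] <- ph
    ph
  }
})

# convenience: constant scalar volume
const_volume <- function(value, shape = c(8, 8, 8), spacing = c(1, 1, 1),
                         unit = "dimensionless") {
  scalar_volume(array(value, shape), spacing = spacing, unit = unit)
}

# displacement field from a vectorized function of world coordinates
field_from_fun <- function(geom, fun) {
  u <- eval_on_grid_test(geom, fun)
  displacement_field(u, geom$spacing, geom$origin)
}

eval_on_grid_test <- function(geom, fun) {
  co <- lapply(1:3, function(a)
    (seq_len(geom$shape[a]) - 1) * geom$spacing[a] + geom$origin[a])
  nx <- geom$shape[1]; ny <- geom$shape[2]; nz <- geom$shape[3]
  X <- array(rep(co[[1]], times = ny * nz), geom$shape)
  Y <- array(rep(rep(co[[2]], each = nx), times = nz), geom$shape)
  Z <- array(rep(co[[3]], each = nx * ny), geom$shape)
  res <- fun(X, Y, Z)
  array(c(res[[1]], res[[2]], res[[3]]), c(geom$shape, 3L))
}

# full-size (96^3) default phantom + decomposition, shared by the phantom
# physics tests and the acceptance criteria; generated once per run
full_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$ph)) {
      cache$ph <- generate_phantom(phantom_spec(seed = 1L))
      cache$dec <- pbv_pair(
        list(low = cache$ph$insp_low_kv, high = cache$ph$insp_high_kv),
        list(low = cache$ph$exp_low_kv, high = cache$ph$exp_high_kv),
        cache$ph$spec$basis)
    }
    list(ph = cache$ph, dec = cache$dec)
  }
})

# python with nibabel, used as an independent NIfTI format oracle
python_bin <- Sys.which("python")
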