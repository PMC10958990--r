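# small phantom builders shared across test files

# circular annulus tube (shell only unless bvtv > 0)
annulus_phantom <- function(d_mm = 20, t_mm = 2, L_mm = 2, h = 0.25,
                            ratio = 1, bvtv = 0, seed = 1,
                            pattern = "stochastic") {
  build_fn_volume(
    fn_geometry(neck_length = L_mm, si_outer_diameter = d_mm,
                ap_si_ratio = ratio, cortical_thickness = t_mm,
                trabecular_bvtv = bvtv),
    voxel_size = h, seed = seed, pattern = pattern)
}

# tiny asymmetric intensity block for rotation tests
block_volume <- function(d = c(3, 4, 2)) {
  fn_volume(array(seq_len(prod(d)), dim = d), spacing = 1, kind = "intensity")
}

# central crop of array `a` to dims `d`
crop_center <- function(a, d) {
  s <- mapply(function(n, m) {
    i0 <- floor((n - m) / 2)
    (i0 + 1):(i0 + m)
  }, dim(a), d, SIMPLIFY = FALSE)
  a[s[[1]], s[[2]], s[[3]], drop = FALSE]
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value - truth) / abs(truth), tol)
}
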