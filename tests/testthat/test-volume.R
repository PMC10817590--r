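participant <- function(id = "F001", sex = "female", age = 40) {
  list(participant_id = id, sex = sex, age = age)
}

test_that("interface surfaces are ordered at every en-face pixel", {
  for (seed in 1:5) {
    vc <- reduced_vconfig()
    ifc <- with(list(), {set.seed(seed); generate_interfaces(vc)})
    z <- ifc$z
    for (k in seq_len(dim(z)[3] - 1)) {
      expect_true(all(z[, , k] <= z[, , k + 1]))
    }
    expect_true(min(z) >= 0)
    expect_true(max(z) <= vc$n_depth)
  }
})

test_that("degenerate smoothness gives flat surfaces at the nominal thickness", {
  vc <- tiny_vconfig(interface_sd = 0, thickness_sd = 0, foveal_dip_depth = 0)
  set.seed(1)
  ifc <- generate_interfaces(vc)
  expect_equal(max(abs(ifc$z[, , 1] - vc$top_margin)), 0)
  thick_gcl <- ifc$z[, , 2] - ifc$z[, , 1]
  expect_true(all(thick_gcl == vc$layer_mean_thickness[["GCL"]]))
})

test_that("the foveal dip thins the inner layers at the grid centre", {
  vc <- volume_config(layers = c("GCL", "IPL", "INL"), n_depth = 32)
  set.seed(2)
  ifc <- generate_interfaces(vc)
  inner_thickness <- ifc$z[, , 4] - ifc$z[, , 1]
  centre <- inner_thickness[64, 256]
  periphery <- inner_thickness[5, 20]
  expect_lt(centre, periphery)
  expect_lt(centre, 0.15 * periphery)  # near-total collapse at the pit
})

test_that("layer stacks that cannot fit the depth range are rejected", {
  expect_error(volume_config(n_depth = 16), "fit")
})

test_that("zero-noise volumes are piecewise constant at the layer means", {
  vc <- tiny_vconfig(texture_sd = 0, noise_sd = 0, interface_sd = 0,
                     thickness_sd = 0, foveal_dip_depth = 0)
  scan <- generate_eye_volume(participant(), "OD", vc, seed = 3)
  v <- scan$volume$intensity
  z <- scan$interfaces$z
  top <- ceiling(z[1, 1, 1]); bot <- ceiling(z[1, 1, 2])
  gcl_vox <- v[, (top + 1):bot, ]  # 0-based span -> 1-based slices
  expect_true(all(gcl_vox == vc$intensity_base[["GCL"]]))
  expect_true(all(v[, 1:top, ] == vc$background))
})

test_that("volumes are deterministic per (seed, participant, eye) substream", {
  vc <- tiny_vconfig()
  a <- generate_eye_volume(participant(), "OS", vc, seed = 9)
  b <- generate_eye_volume(participant(), "OS", vc, seed = 9)
  expect_identical(a, b)
  other_eye <- generate_eye_volume(participant(), "OD", vc, seed = 9)
  expect_false(identical(a$volume$intensity, other_eye$volume$intensity))
  other_pid <- generate_eye_volume(participant(id = "F002"), "OS", vc, seed = 9)
  expect_false(identical(a$volume$intensity, other_pid$volume$intensity))
})

test_that("a zero-delta effect is a no-op and effects respect sex/eye targeting", {
  vc <- reduced_vconfig()
  noop <- list(effect_spec("female", "OS", "IPL", "Q4"))
  plain <- generate_eye_volume(participant(), "OS", vc, seed = 4)
  with_noop <- generate_eye_volume(participant(), "OS", vc, noop, seed = 4)
  expect_identical(plain, with_noop)

  eff <- list(effect_spec("female", "OS", "IPL", "Q4", delta_sd = 10))
  male_os <- generate_eye_volume(participant(id = "M001", sex = "male"),
                                 "OS", vc, eff, seed = 4)
  male_plain <- generate_eye_volume(participant(id = "M001", sex = "male"),
                                    "OS", vc, seed = 4)
  expect_identical(male_os, male_plain)
})

test_that("an injected sd effect raises variance only inside the target footprint", {
  vc <- reduced_vconfig()
  eff <- list(effect_spec("female", "OS", "IPL", "Q4", delta_sd = 10))
  os <- generate_eye_volume(participant(), "OS", vc, eff, seed = 6)
  od <- generate_eye_volume(participant(), "OD", vc, eff, seed = 6)
  os_plain <- generate_eye_volume(participant(), "OS", vc, seed = 6)

  # IPL mean-value image variance inside the Q4 footprint: OS >> OD
  ipl_mvf <- function(scan) {
    m <- compute_mvf(scan$volume, scan$interfaces, "IPL")
    standardise_orientation(m)
  }
  fp_rows <- 73:126 * (vc$n_bscan / 128)      # Q4 rows on the native grid
  fp_cols <- (289:504)                        # Q4 columns after flipping
  v_os <- var(as.vector(ipl_mvf(os)$values[fp_rows, fp_cols]))
  v_od <- var(as.vector(ipl_mvf(od)$values[fp_rows, fp_cols]))
  expect_gt(v_os, 2 * v_od)

  # outside the footprint (and outside IPL) the OS volume is bit-identical
  # to the no-effect volume under the same substream
  q4 <- oculotex:::quadrant_footprint("Q4", "OS", vc$n_bscan, vc$n_ascan)
  outside_cols <- setdiff(seq_len(vc$n_ascan), q4$cols)
  expect_identical(os$volume$intensity[, , outside_cols],
                   os_plain$volume$intensity[, , outside_cols])
  expect_identical(os$interfaces, os_plain$interfaces)
})

test_that("effects targeting a layer absent from the volume are rejected", {
  vc <- tiny_vconfig()  # GCL + IPL only
  eff <- list(effect_spec("female", "OS", "ONL", "Q1", delta_sd = 5))
  expect_error(generate_eye_volume(participant(), "OS", vc, eff, seed = 1),
               "absent")
})

test_that("raising texture sd raises the variance of the layer's fundus image", {
  vc_lo <- reduced_vconfig(texture_sd = 5)
  vc_hi <- reduced_vconfig(texture_sd = 15)
  lo <- generate_eye_volume(participant(), "OD", vc_lo, seed = 12)
  hi <- generate_eye_volume(participant(), "OD", vc_hi, seed = 12)
  v <- function(scan) {
    m <- compute_mvf(scan$volume, scan$interfaces, "IPL")
    var(m$values[m$mask])
  }
  expect_gt(v(hi), v(lo))
})
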