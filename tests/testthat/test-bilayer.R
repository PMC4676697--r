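test_that("area per molecule follows the two-leaflet volume identity", {
  expect_equal(area_per_molecule(27, 0.12, 937), 78.9, tolerance = 1e-3)
  # 2V = d * A0 with no solvent recovers A0 exactly
  a0 <- 63
  expect_equal(area_per_molecule(2 * 937 / a0, 0, 937), a0)
  expect_equal(area_per_molecule(27, 0.12, 2 * 937),
               2 * area_per_molecule(27, 0.12, 937))
  expect_error(area_per_molecule(27, 1), "no lipid")
  expect_error(area_per_molecule(0, 0.1), "> 0")
})

test_that("coupled headgroup hydration fills the non-lipid volume", {
  expect_equal(coupled_head_solvent(7, 78.9, 319), 0.4224, tolerance = 1e-3)
  a <- 70
  expect_equal(coupled_head_solvent(7, a, 7 * a), 0)
  expect_equal(coupled_head_solvent(7, a, 0), 1)
  expect_warning(phi <- coupled_head_solvent(3, 40, 319), "clamped")
  expect_equal(phi, 0)
})

test_that("three-layer stacks honour symmetry, totals and the area constraint", {
  truth <- ground_truth_presets()[["hEcoli_50C"]]
  for (f in c(0, 0.4, 1)) {
    st <- build_slab_stack(truth, contrast = contrast_spec(f))
    layers <- st$name
    expect_identical(layers,
                     c("fronting", "SiO2", "water*", "head", "tail", "head",
                       "backing"))
    heads <- st[st$name == "head", c("d", "sld", "solvent_fraction",
                                     "roughness")]
    expect_identical(heads[1, ], heads[2, ], ignore_attr = TRUE)
    # total film thickness is derived: d_h + d_t + d_h
    expect_identical(sum(st$d[4:6]), 7 + 27 + 7)
    # water gap is pure solvent
    expect_identical(st$solvent_fraction[3], 1)
    # equal-area identity recomputed from the emitted slabs
    a_tail <- 2 * truth$volumes$tails /
      (st$d[5] * (1 - st$solvent_fraction[5]))
    a_head <- truth$volumes$head /
      (st$d[4] * (1 - st$solvent_fraction[4]))
    expect_equal(a_head, a_tail, tolerance = 1e-15)
    expect_identical(attr(st, "constraint_violation"), 0)
  }
})

test_that("contrasts change only solvent-dependent SLDs", {
  truth <- ground_truth_presets()[["hEcoli_50C"]]
  st_h <- build_slab_stack(truth, contrast = contrast_spec(0))
  st_d <- build_slab_stack(truth, contrast = contrast_spec(1))
  expect_identical(st_h$d, st_d$d)
  expect_identical(st_h$solvent_fraction, st_d$solvent_fraction)
  expect_identical(st_h$roughness, st_d$roughness)
  i_head <- which(st_h$name == "head")
  expect_equal(st_h$sld[i_head], rep(1.55, 2))
  expect_equal(st_d$sld[i_head], rep(2.16, 2))
  # tails and substrate identical
  expect_identical(st_h$sld[-i_head][1:4], st_d$sld[-i_head][1:4])
})

test_that("one-layer model gains vesicle slabs per the contrast rule", {
  truth <- ground_truth_presets()[["dEcoli_50C"]]
  st_h2o <- build_slab_stack(truth, contrast = contrast_spec(0))
  st_d2o <- build_slab_stack(truth, contrast = contrast_spec(1))
  expect_identical(st_h2o$name,
                   c("fronting", "SiO2", "water*", "bilayer", "water(ves)",
                     "bilayer(ves)", "backing"))
  expect_identical(st_d2o$name,
                   c("fronting", "SiO2", "water*", "bilayer", "backing"))
  # vesicle bilayer: 4% coverage = 96% solvent, d and SLD tied to the SLB
  i <- which(st_h2o$name == "bilayer(ves)")
  expect_equal(st_h2o$solvent_fraction[i], 0.96)
  expect_identical(st_h2o$d[i], st_h2o$d[st_h2o$name == "bilayer"])
  expect_identical(st_h2o$sld[i], st_h2o$sld[st_h2o$name == "bilayer"])
  # 25C preset keeps vesicles in every contrast
  st_25 <- build_slab_stack(ground_truth_presets()[["dEcoli_25C"]],
                            contrast = contrast_spec(1))
  expect_true("bilayer(ves)" %in% st_25$name)
})

test_that("zero vesicle coverage reproduces the plain one-layer curve", {
  m_ves <- slb_model("one_layer_vesicles", params = list(coverage = 0),
                     vesicles_in = "all")
  m_plain <- slb_model("one_layer_vesicles", vesicles_in = "none")
  q <- 10^seq(log10(0.005), log10(0.3), length.out = 80)
  for (f in c(0, 1)) {
    ct <- contrast_spec(f)
    r_ves <- abeles_reflectivity(build_slab_stack(m_ves, contrast = ct),
                                 ct$water_sld, q)
    r_plain <- abeles_reflectivity(build_slab_stack(m_plain, contrast = ct),
                                   ct$water_sld, q)
    expect_equal(r_ves, r_plain, tolerance = 1e-10)
  }
})

test_that("constraint violations are flagged, not fatal", {
  # a tiny head layer cannot hold the headgroup volume at the coupled area
  m <- slb_model("three_layer", params = list(d_head = list(init = 3)))
  st <- build_slab_stack(m, contrast = contrast_spec(1))
  expect_gt(attr(st, "constraint_violation"), 0)
  expect_identical(st$solvent_fraction[st$name == "head"], rep(0, 2))
})

test_that("fast fitting path matches the slab-stack forward model", {
  for (preset in names(ground_truth_presets())) {
    m <- ground_truth_presets()[[preset]]
    for (f in c(0, 0.4, 1)) {
      ct <- contrast_spec(f)
      lv <- slabnr:::.layer_vectors(m, slabnr:::.par_vector(m), ct)
      st <- build_slab_stack(m, contrast = ct)
      v <- stack_vectors(st, ct$water_sld)
      expect_equal(lv$d, v$d)
      expect_equal(lv$rho, v$rho)
      expect_equal(lv$sigma, v$sigma)
      expect_equal(lv$violation, attr(st, "constraint_violation"))
    }
  }
})

test_that("model construction validates parameters and bounds", {
  expect_error(slb_model("three_layer", params = list(nope = 1)), "unknown")
  expect_error(slb_model("three_layer",
                         params = list(d_head = list(init = 99))),
               "bounds")
  expect_error(slb_model("three_layer", vesicles_in = "all"), "one-layer")
  expect_error(slb_model("three_layer",
                         params = list(d_head = list(min = -Inf))),
               "finite")
})

test_that("layer tables mirror the conventional reporting format", {
  truth <- ground_truth_presets()[["hEcoli_50C"]]
  tab <- layer_table(truth)
  expect_identical(tab$layer, c("Water*", "Head", "Tail", "Head", "TOTAL"))
  expect_equal(tab$d_A, c(8, 7, 27, 7, 41))
  expect_equal(tab$solvent_pct[3], 12)
  tab_b <- layer_table(ground_truth_presets()[["dEcoli_50C"]])
  expect_identical(tab_b$layer,
                   c("Water*", "Bilayer", "Water(ves)", "Bilayer(ves)",
                     "TOTAL"))
  expect_equal(tab_b$solvent_pct[4], 96)
  expect_equal(tab_b$d_A[5], 41)
})
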