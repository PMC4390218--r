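mat <- material()

test_that("bilateral cases on the symmetric fixture split the bite evenly", {
  sk <- test_skull(order = 1)
  mus <- skull_muscles(sk, 0.3)
  r <- run_case(sk, mus, load_case("A", "bilateral", "anterior"), mat)
  ps <- r$bite_force$per_side
  expect_equal(ps[[1]]$magnitude, ps[[2]]$magnitude,
               tolerance = 1e-6)
  # mirror-paired region means agree
  for (p in c("AME", "AMI", "quadrate"))
    expect_equal(r$region_mean[[paste0(p, "_left")]],
                 r$region_mean[[paste0(p, "_right")]], tolerance = 1e-6)
  # mediolateral bite component vanishes
  expect_lt(abs(r$bite_force$force[3]), 1e-6 * r$bite_force$magnitude)
})

test_that("unilateral cases leave the balancing side unconstrained", {
  sk <- test_skull(order = 1)
  mus <- skull_muscles(sk, 0.3)
  r <- run_case(sk, mus, load_case("C", "unilateral", "anterior",
                                   side = "left"), mat)
  right <- patch_nodes(sk, "prehension_anterior_right")
  expect_false(any(r$solution$fixed[right, ]))
  expect_true(all(r$solution$reactions[right, ] == 0))
  # the biting side carries the whole bite force
  expect_length(r$bite_force$per_side, 1L)
})

test_that("bite force plus joint and condyle reactions balance the load", {
  sk <- test_skull(order = 1)
  mus <- skull_muscles(sk, 0.3)
  for (case in list(load_case("A", "bilateral", "anterior"),
                    load_case("D", "unilateral", "posterior"))) {
    r <- run_case(sk, mus, case, mat)
    resid <- r$applied_total + colSums(r$reactions_by_role[, c("fx", "fy", "fz")])
    expect_lt(max(abs(resid)), 1e-8 * sum(abs(r$applied_total)))
    expect_lt(r$equilibrium_residual, 1e-8)
  }
})

test_that("missing patches give a configuration error naming the patch", {
  cube <- make_patch_cube(1, 1)
  expect_error(
    run_case(cube, list(), load_case("A", "bilateral", "anterior"), mat),
    "prehension_anterior_left")
})

test_that("case results are deterministic", {
  sk <- test_skull(order = 1)
  mus <- skull_muscles(sk, 0.3)
  case <- load_case("B", "bilateral", "posterior")
  r1 <- run_case(sk, mus, case, mat)
  r2 <- run_case(sk, mus, case, mat)
  expect_identical(r1$bite_force, r2$bite_force)
  expect_identical(r1$region_mean, r2$region_mean)
  expect_identical(r1$solution$u, r2$solution$u)
})

test_that("self- and scaled comparisons behave as ratios should", {
  sk <- test_skull(order = 1)
  mus <- skull_muscles(sk, 0.3)
  case <- load_case("A", "bilateral", "anterior")
  r1 <- run_case(sk, mus, case, mat)
  self <- compare_results(r1, r1)
  expect_equal(self$bite_force_ratio, 1)
  expect_true(all(abs(self$regions$ratio - 1) < 1e-14))
  # doubled pressures double every stress and bite-force measure
  r2 <- run_case(sk, skull_muscles(sk, 0.6), case, mat)
  cmp <- compare_results(r1, r2)
  expect_equal(cmp$bite_force_ratio, 2, tolerance = 1e-10)
  expect_equal(cmp$vm_max_ratio, 2, tolerance = 1e-10)
  expect_true(all(abs(cmp$regions$ratio - 2) < 1e-8))
  expect_equal(r2$bite_force$force, 2 * r1$bite_force$force,
               tolerance = 1e-10)
  # mismatched case structures are not comparable
  rB <- run_case(sk, mus, load_case("B", "bilateral", "posterior"), mat)
  expect_error(compare_results(r1, rB), "not comparable")
})

test_that("scaled muscle pressures follow the chosen scaling law exactly", {
  ref <- test_skull(order = 1)
  tgt <- make_skull(skull_params(length = 90, width = 90, height = 27,
                                 shell_thickness = 4.5, resolution = 6,
                                 element_order = 1))
  mus <- skull_muscles(ref, 0.3)
  for (method in c("volume", "area")) {
    sc <- scale_muscles(ref, tgt, mus, method)
    for (m in mus) {
      s <- scaling_inputs(V_ref = mesh_volume(ref), V_tgt = mesh_volume(tgt),
                          S_ref = mesh_surface_area(ref),
                          S_tgt = mesh_surface_area(tgt),
                          SM_ref = patch_area(ref, m$patch),
                          SM_tgt = patch_area(tgt, m$patch))
      want <- if (method == "volume") scale_pressure_volume(m$pressure, s)
              else scale_pressure_area(m$pressure, s)
      got <- Filter(function(x) x$name == m$name, sc)[[1]]$pressure
      expect_identical(got, want)
    }
  }
})

test_that("a homothetic pair under volume-scaled loads compares at unity", {
  ref <- test_skull(order = 1)
  al <- alpha_from_volumes(144340, 24964)
  tgt <- homothety(ref, al)
  mus_ref <- skull_muscles(ref, 0.3)
  mus_tgt <- scale_muscles(ref, tgt, mus_ref, "volume")
  # volume scaling of a homothetic pair keeps pressures identical
  expect_equal(unname(attr(mus_tgt, "scaled_pressures")), rep(0.3, 4),
               tolerance = 1e-10)
  case <- load_case("A", "bilateral", "anterior")
  r_ref <- run_case(ref, mus_ref, case, mat)
  r_tgt <- run_case(tgt, mus_tgt, case, mat)
  cmp <- compare_results(r_ref, r_tgt)
  expect_equal(cmp$vm_max_ratio, 1, tolerance = 1e-6)
  expect_true(all(abs(cmp$regions$ratio - 1) < 1e-6))
  # bite force transforms with the 2/3 power of the volume ratio
  expect_equal(r_tgt$bite_force$magnitude / r_ref$bite_force$magnitude,
               (24964 / 144340)^(2 / 3), tolerance = 1e-8)
})

test_that("scenario configs round-trip through YAML", {
  sc <- list(material = material(6650, 0.35), pressure = 0.3,
             gape = gape_spec(6, 15), scaling = "volume", side = "left")
  p <- file.path(withr::local_tempdir(), "scenario.yaml")
  write_scenario(sc, p)
  back <- read_scenario(p)
  expect_equal(back$material, sc$material)
  expect_equal(back$pressure, sc$pressure)
  expect_equal(back$gape$total_deg, 21)
  expect_identical(back$scaling, "volume")
  expect_identical(back$side, "left")
})
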