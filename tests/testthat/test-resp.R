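no_restraint <- resp_config(restraint_a_stage1 = 0, restraint_a_stage2 = 0)

test_that("the Coulomb forward model matches direct summation", {
  # single +1 charge, grid point at 2 Bohr
  expect_equal(
    esp_from_point_charges(1, rbind(c(0, 0, 0)), rbind(c(2, 0, 0))),
    0.5
  )
  expect_equal(
    esp_from_point_charges(c(0, 0), rbind(c(0, 0, 0), c(1, 0, 0)),
                           rbind(c(3, 0, 0), c(0, 4, 0))),
    c(0, 0)
  )
  # dipole fixture vs independent per-point summation
  pos <- rbind(c(0, 0, 0.5), c(0, 0, -0.5))
  q <- c(0.4, -0.4)
  pts <- as.matrix(expand.grid(x = c(-2, 2), y = c(-2, 2), z = c(-1, 1)))
  direct <- apply(pts, 1, function(p) {
    sum(q / sqrt(rowSums(sweep(pos, 2, p)^2)))
  })
  expect_equal(esp_from_point_charges(q, pos, pts), direct, tolerance = 1e-12)
  expect_error(esp_from_point_charges(1, rbind(c(0, 0, 0)),
                                      rbind(c(0, 0, 0))),
               "coincides")
  expect_error(esp_grid(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)), 1), "coincides")
})

test_that("single-stage solve honours trivial and symmetric constraints", {
  # single atom with total charge -1: charge is -1 regardless of grid
  g1 <- gen_esp_fixture(-1, rbind(c(0, 0, 0)), seed = 1)
  q <- resp_solve_stage(g1, total_charge = -1)
  expect_equal(as.numeric(q), -1, tolerance = 1e-10)

  # two symmetric atoms + equivalence on an asymmetric-potential grid
  pos <- rbind(c(-1, 0, 0), c(1, 0, 0))
  g2 <- gen_esp_fixture(c(0.5, -0.5), pos, seed = 2)
  q2 <- resp_solve_stage(g2, total_charge = 0,
                         constraints = list(charge_equivalence(1:2)))
  expect_equal(q2[1], q2[2], tolerance = 1e-12, ignore_attr = TRUE)

  # fix constraints are satisfied exactly
  g3 <- gen_esp_fixture(c(0.3, -0.3, 0.0), random_positions(3, 5), seed = 3)
  q3 <- resp_solve_stage(g3, total_charge = 0,
                         constraints = list(charge_fix(2, -0.25)))
  expect_identical(q3[2], -0.25)
  expect_equal(sum(q3), 0, tolerance = 1e-10)
  expect_error(
    resp_solve_stage(g3, total_charge = 0,
                     constraints = list(charge_fix(2, -0.25),
                                        charge_fix(2, 0.1))),
    "conflicting|two different"
  )
})

test_that("noise-free unconstrained fits recover the generating charges", {
  withr::with_seed(17, {
    for (rep in 1:6) {
      n <- sample(3:25, 1)
      q_true <- rnorm(n, 0, 0.4)
      q_true[1] <- q_true[1] - (sum(q_true) - round(sum(q_true)))
      pos <- random_positions(n, seed = 1000 + rep)
      grid <- gen_esp_fixture(q_true, pos, seed = 2000 + rep)
      q_fit <- resp_solve_stage(grid, total_charge = round(sum(q_true)),
                                restraint_a = 0)
      expect_lt(max(abs(as.numeric(q_fit) - q_true)), 1e-6)
    }
  })
})

test_that("two-stage fit keeps scheme invariants and recovers constructed fixtures", {
  for (with_h in c(TRUE, FALSE)) {
    topo <- gen_capped_topology(2, with_h, seed = 40 + with_h)
    pos <- frame_coords(topo) * 1.889726
    q_true <- make_recoverable_charges(topo, total = 0, scheme = "amide",
                                       seed = 50 + with_h)
    grid <- gen_esp_fixture(q_true, pos, seed = 60 + with_h)
    for (builder in list(scheme_free_fit, scheme_cap_fix)) {
      sch <- builder(topo, total_charge = 0)
      res <- resp_fit_two_stage(grid, topo, sch, no_restraint)
      expect_lt(max(abs(res$charges - q_true)), 1e-6)
    }
    sch <- scheme_amide_fix(topo, total_charge = 0)
    res <- resp_fit_two_stage(grid, topo, sch, no_restraint)
    expect_lt(max(abs(res$charges - q_true)), 1e-6)
    expect_equal(sum(res$charges), 0, tolerance = 1e-9)
    expect_equal(res$relative_rms_fit, 0, tolerance = 1e-8)
  }
})

test_that("constraint schemes encode the published charge models", {
  topo <- gen_capped_topology(1, TRUE, seed = 7)
  fr <- scheme_free_fit(topo, total_charge = 0)
  kinds <- vapply(fr$constraints, function(c) c$kind, "")
  # two cap methyls + one sidechain methyl -> three equivalence classes
  expect_equal(sum(kinds == "equivalence"), 3L)
  expect_true(all(kinds == "equivalence"))

  # excluding cap hydrogens leaves only the sidechain class
  fr2 <- scheme_free_fit(topo, 0, cap_hydrogen_equivalence = FALSE)
  expect_equal(length(fr2$constraints), 1L)

  cf <- scheme_cap_fix(topo, total_charge = 0)
  kinds <- vapply(cf$constraints, function(c) c$kind, "")
  expect_equal(sum(kinds == "group_sum"), 2L)
  gs <- cf$constraints[kinds == "group_sum"]
  expect_true(all(vapply(gs, function(c) c$value, 0) == 0))

  # amide fix pins exactly 4 atoms: N, H, carbonyl C, carbonyl O
  af <- scheme_amide_fix(topo, total_charge = 0)
  fixes <- Filter(function(c) c$kind == "fix", af$constraints)
  expect_equal(length(fixes), 4L)
  fixed_names <- topo$atoms$name[vapply(fixes, function(c) c$atoms, 1L)]
  expect_setequal(fixed_names, c("N", "HN", "C", "O"))
  ref <- consensus_terminal_charges()
  expect_setequal(vapply(fixes, function(c) c$value, 0),
                  unname(ref[c("N", "H", "C", "O")]))

  # proline-like terminus: N left free, ACE C/O pinned instead
  topo_nh <- gen_capped_topology(1, FALSE, seed = 8)
  af2 <- scheme_amide_fix(topo_nh, total_charge = 0)
  fixes2 <- Filter(function(c) c$kind == "fix", af2$constraints)
  expect_equal(length(fixes2), 4L)
  fixed_names2 <- topo_nh$atoms$name[vapply(fixes2, function(c) c$atoms, 1L)]
  expect_setequal(fixed_names2, c("CY", "OY", "C", "O"))
  expect_false("N" %in% fixed_names2)

  # missing annotations are reported
  bare <- topo
  bare$atoms$role <- NA_character_
  bare$atoms$terminal_flag <- NA_character_
  expect_error(scheme_cap_fix(bare, 0), "cap_ACE")
})

test_that("converged fits satisfy the constraint algebra exactly", {
  topo <- gen_capped_topology(2, TRUE, seed = 70)
  pos <- frame_coords(topo) * 1.889726
  q_gen <- make_recoverable_charges(topo, total = -1, scheme = "free",
                                    seed = 71)
  grid <- gen_esp_fixture(q_gen, pos, seed = 72)
  sch <- scheme_amide_fix(topo, total_charge = -1)
  res <- resp_fit_two_stage(grid, topo, sch)  # default restraints
  expect_equal(sum(res$charges), -1, tolerance = 1e-8)
  for (con in sch$constraints) {
    if (con$kind == "fix") {
      expect_identical(res$charges[con$atoms], con$value)
    } else if (con$kind == "group_sum") {
      expect_equal(sum(res$charges[con$atoms]), con$value, tolerance = 1e-8)
    } else {
      expect_lt(diff(range(res$charges[con$atoms])), 1e-10)
    }
  }
})

test_that("relative RMS fit is 0 for generators, 1 for zero charges, and monotone in constraints", {
  pos <- random_positions(5, seed = 81)
  q <- c(0.2, -0.3, 0.4, -0.2, -0.1)
  grid <- gen_esp_fixture(q, pos, seed = 82)
  expect_lt(relative_rms_fit(grid, q), 1e-12)
  expect_equal(relative_rms_fit(grid, rep(0, 5)), 1)
  q_pert <- q + 0.01
  vm <- esp_from_point_charges(q_pert, grid$atom_positions, grid$grid_points)
  direct <- sqrt(sum((grid$potentials - vm)^2) / sum(grid$potentials^2))
  expect_equal(relative_rms_fit(grid, q_pert), direct, tolerance = 1e-12)
  zero_grid <- esp_grid(pos, grid$grid_points, rep(0, nrow(grid$grid_points)))
  expect_error(relative_rms_fit(zero_grid, q), "all zero")

  # free fit <= cap fix <= amide fix on any fixed grid
  for (seed in 1:4) {
    topo <- gen_capped_topology(2, seed %% 2 == 0, seed = 90 + seed)
    posb <- frame_coords(topo) * 1.889726
    q_gen <- withr::with_seed(95 + seed, rnorm(n_atoms(topo), 0, 0.3))
    q_gen[10] <- q_gen[10] - sum(q_gen)
    gridb <- gen_esp_fixture(q_gen, posb, seed = 100 + seed)
    rr <- vapply(
      list(scheme_free_fit(topo, 0), scheme_cap_fix(topo, 0),
           scheme_amide_fix(topo, 0)),
      function(s) resp_fit_two_stage(gridb, topo, s)$relative_rms_fit, 0
    )
    expect_true(all(diff(rr) >= -1e-12))
  }
})

test_that("stronger restraints shrink restrained charge magnitudes", {
  topo <- gen_capped_topology(1, TRUE, seed = 110)
  pos <- frame_coords(topo) * 1.889726
  q_gen <- make_recoverable_charges(topo, total = 0, scheme = "free",
                                    seed = 111)
  grid <- gen_esp_fixture(q_gen, pos, seed = 112)
  heavy <- which(topo$atoms$element != "H")
  sums <- vapply(c(0, 0.001, 0.01, 0.05), function(a) {
    cfg <- resp_config(restraint_a_stage1 = a, restraint_a_stage2 = a)
    res <- resp_fit_two_stage(grid, topo, scheme_free_fit(topo, 0), cfg)
    sum(abs(res$charges[heavy]))
  }, 0)
  expect_true(all(diff(sums) <= 1e-8))
})

test_that("stage 2 refits only methyl/methylene groups", {
  # a topology without CH2/CH3 groups: stage 2 is a no-op
  at <- data.frame(name = c("N1", "C1", "O1"), element = c("N", "C", "O"),
                   stringsAsFactors = FALSE)
  s <- xfp_structure(at, rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 1, 0)),
                     bonds = rbind(c(1L, 2L), c(2L, 3L)))
  q <- c(-0.4, 0.6, -0.2)
  grid <- gen_esp_fixture(q, frame_coords(s) * 1.889726, seed = 120)
  res <- resp_fit_two_stage(grid, s, scheme_free_fit(s, 0), no_restraint)
  expect_equal(res$charges, res$stage1_charges)
  expect_equal(res$iterations_used[["stage2"]], 0L)

  # with a methyl present, non-group atoms stay frozen at stage-1 values
  topo <- gen_capped_topology(1, TRUE, seed = 121)
  posb <- frame_coords(topo) * 1.889726
  qb <- make_recoverable_charges(topo, 0, "free", seed = 122)
  gridb <- gen_esp_fixture(qb, posb, seed = 123)
  resb <- resp_fit_two_stage(gridb, topo, scheme_free_fit(topo, 0))
  groups <- unlist(lapply(xfpchromo:::.ch_groups(topo),
                          function(g) c(g$carbon, g$hydrogens)))
  outside <- setdiff(seq_len(n_atoms(topo)), groups)
  expect_equal(resb$charges[outside], resb$stage1_charges[outside])
})

test_that("ESP grid files round trip in both layouts", {
  pos <- random_positions(4, seed = 130)
  q <- c(0.25, -0.5, 0.5, -0.25)
  grid <- gen_esp_fixture(q, pos, seed = 131)
  txt <- write_esp(grid, format = "resp")
  back <- read_esp(txt, format = "resp")
  expect_equal(back$atom_positions, grid$atom_positions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$potentials, grid$potentials, tolerance = 1e-6)
  ptxt <- write_esp(grid, format = "plain")
  pback <- read_esp(ptxt, format = "plain", atom_positions = pos)
  expect_equal(pback$potentials, grid$potentials, tolerance = 1e-9)
  expect_error(read_esp(ptxt, format = "plain"), "atom_positions")
})
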