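test_that("isolated and well-separated atoms get the analytic sphere area", {
  one <- new_atom_table("CA", "C", 0, 0, 0)
  expect_equal(shrake_rupley(one, 1.4, 960L), 4 * pi * (1.70 + 1.40)^2,
               tolerance = 1e-12)
  two <- new_atom_table(c("CA", "CA"), c("C", "C"),
                        x = c(0, 100), y = c(0, 0), z = c(0, 0))
  expect_equal(shrake_rupley(two, 1.4, 960L),
               rep(4 * pi * 3.1^2, 2), tolerance = 1e-12)
})

test_that("an atom caged by a dense shell is almost fully occluded", {
  # 26-point cubic shell at 3 A around a central C atom
  g <- expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3), z = c(-3, 0, 3))
  g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
  atoms <- new_atom_table(rep("CA", 27), rep("C", 27),
                          x = c(0, g$x), y = c(0, g$y), z = c(0, g$z))
  a <- shrake_rupley(atoms, 1.4, 960L)
  expect_lt(a[1], 1)
  # independent Monte-Carlo quadrature agrees
  mc <- oracle_sasa_mc(atoms)
  expect_lt(mc[1], 1)
  expect_equal(a, mc, tolerance = 0.05 * max(mc) + 0.5)
})

test_that("quadrature converges between 960 and 4000 points", {
  atoms <- random_cluster(5, seed = 3)
  a1 <- shrake_rupley(atoms, 1.4, 960L)
  a2 <- shrake_rupley(atoms, 1.4, 4000L)
  expect_true(all(abs(a1 - a2) / pmax(a2, 1) < 0.03))
})

test_that("residue components partition the total in both contexts", {
  toy <- make_toy_complex(toy_complex_spec(n_res_per_chain = 8,
                                           contact_patch_size = 3))
  for (ctx in c("bound", "unbound")) {
    tab <- residue_asa(toy$structure, ctx, n_points = 480L)
    expect_true(all(tab$total_asa >= 0))
    expect_equal(tab$backbone_asa + tab$sidechain_asa, tab$total_asa,
                 tolerance = 1e-9)
    expect_equal(tab$polar_asa + tab$nonpolar_asa, tab$total_asa,
                 tolerance = 1e-9)
  }
})

test_that("single-chain structures have identical bound and unbound tables", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ala_pdb(path)
  cx <- read_pdb(path)
  b <- residue_asa(cx, "bound", n_points = 480L)
  u <- residue_asa(cx, "unbound", n_points = 480L)
  expect_equal(b$total_asa, u$total_asa)
})

test_that("occlusion only reduces area: CASA <= MASA everywhere", {
  toy <- make_toy_complex(toy_complex_spec(n_res_per_chain = 10,
                                           contact_patch_size = 4))
  masa <- residue_asa(toy$structure, "unbound", n_points = 480L)
  casa <- residue_asa(toy$structure, "bound", n_points = 480L)
  expect_true(all(casa$total_asa <= masa$total_asa + 1e-9))
})

test_that("areas are invariant under rigid transforms", {
  toy <- make_toy_complex(toy_complex_spec(n_res_per_chain = 5,
                                           contact_patch_size = 2))
  a <- residue_asa(toy$structure, "bound", n_points = 480L)
  b <- residue_asa(rigid_transform_complex(toy$structure), "bound",
                   n_points = 480L)
  expect_equal(a$total_asa, b$total_asa, tolerance = 1e-6)
})

test_that("relative_asa divides by the amino-acid reference and flags X", {
  toy <- make_toy_complex(toy_complex_spec(n_res_per_chain = 4,
                                           contact_patch_size = 0,
                                           inter_chain_gap = 60))
  tab <- residue_asa(toy$structure, "unbound", n_points = 480L)
  tab$aa[1] <- "X"
  r <- relative_asa(tab)
  expect_equal(r$total_rasa[2], r$total_asa[2] / MAX_ASA[[r$aa[2]]])
  expect_equal(r$total_rasa[1], r$total_asa[1] / mean(MAX_ASA))
  expect_true(r$rasa_ref_imputed[1])
  expect_false(any(r$rasa_ref_imputed[-1]))
  # zero area -> zero RASA
  tab$total_asa[3] <- 0
  expect_equal(relative_asa(tab)$total_rasa[3], 0)
  # additivity carries over to the relative components
  expect_equal(r$backbone_rasa + r$sidechain_rasa, r$total_rasa,
               tolerance = 1e-9)
})

test_that("extended G-A-G tripeptide central residue has near-reference RASA", {
  # central residue of a fully extended isolated Gly-Ala-Gly tripeptide
  # should expose on the order of its reference maximum area (sanity band);
  # Gly flanks mirror the construction behind the reference set
  ch <- toy_chain("A", 3, 3, c(0, 0, 0), c(1, 0, 0), +1, "extended",
                  c("G", "A", "G"))
  cx <- new_complex_structure(list(ch), "TRIP")
  r <- relative_asa(residue_asa(cx, "unbound", n_points = 960L))
  expect_gt(r$total_rasa[2], 0.8)
  expect_lt(r$total_rasa[2], 1.2)
})

test_that("glycine has zero side-chain area", {
  ch <- toy_chain("A", 3, 3, c(0, 0, 0), c(1, 0, 0), +1, "extended",
                  c("A", "G", "A"))
  cx <- new_complex_structure(list(ch), "GLY")
  tab <- residue_asa(cx, "unbound", n_points = 480L)
  expect_equal(tab$sidechain_asa[2], 0)
  expect_gt(tab$sidechain_asa[1], 0)
})

test_that("read_dssp_asa reads ACC, skips chain breaks, rejects junk", {
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp_stub_lines(data.frame(num = c("1", "2"), chain = "A",
                                        aa = c("S", "L"),
                                        acc = c("100", "0"))), path)
  got <- read_dssp_asa(path)
  expect_equal(got$acc, c(100, 0))
  expect_equal(got$aa, c("S", "L"))

  writeLines(dssp_stub_lines(data.frame(num = c("1", "", "2"), chain = "A",
                                        aa = c("S", "!", "L"),
                                        acc = c("50", "", "60"))), path)
  got <- read_dssp_asa(path)
  expect_equal(got$acc, c(50, 60))  # '!' break skipped, no shift

  writeLines(dssp_stub_lines(data.frame(num = "1", chain = "A", aa = "S",
                                        acc = "abcd")), path)
  expect_error(read_dssp_asa(path), "non-numeric ACC")
  writeLines("not dssp at all", path)
  expect_error(read_dssp_asa(path), "missing residue header")
})
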