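test_that("entropy formula: one-hot, uniform, and two-state cases", {
  onehot <- c(1, rep(0, 19))
  expect_equal(unname(profile_entropy(onehot)), c(0, 0))
  unif <- rep(0.05, 20)
  e <- profile_entropy(unif)
  expect_equal(unname(e["entropy"]), log(20), tolerance = 1e-12)
  expect_equal(unname(e["relative_entropy"]), 100, tolerance = 1e-12)
  two <- c(0.5, 0.5, rep(0, 18))
  e2 <- profile_entropy(two)
  expect_equal(unname(e2["entropy"]), log(2), tolerance = 1e-12)
  expect_equal(unname(e2["relative_entropy"]), 100 * log(2) / log(20),
               tolerance = 1e-12)
  # bounds over random simplex points
  set.seed(1)
  for (i in 1:50) {
    g <- rgamma(20, 1)
    e <- profile_entropy(g / sum(g))
    expect_gte(e[["entropy"]], 0)
    expect_lte(e[["entropy"]], log(20) + 1e-12)
    expect_lte(e[["relative_entropy"]], 100 + 1e-9)
  }
})

test_that("parse_hssp reads stub profiles in HSSP column order", {
  path <- withr::local_tempfile(fileext = ".hssp")
  # row 1: 100 % A; row 2: uniform 5 %
  pc <- matrix(0L, 2, 20)
  pc[1, 9] <- 100L  # A is column 9 of the HSSP order
  pc[2, ] <- 5L
  writeLines(hssp_stub_lines(pc, nocc = 7, entropy = 0.25, relent = 12),
             path)
  prof <- parse_hssp(path)
  expect_s3_class(prof, "profile_table")
  expect_equal(nrow(prof), 2)
  expect_equal(prof$p_A[1], 1.0)
  expect_equal(sum(as.matrix(prof[1, paste0("p_", AA_CODES)])), 1.0)
  expect_equal(unlist(prof[2, paste0("p_", AA_CODES)], use.names = FALSE),
               rep(0.05, 20))
  expect_equal(prof$nocc, c(7, 7))
  expect_equal(prof$entropy, c(0.25, 0.25))
  expect_equal(prof$relative_entropy, c(12, 12))
  expect_equal(prof$sequence_variability, c(0, 0))  # no ALIGNMENTS section
})

test_that("parse_hssp picks VAR from the alignments block when present", {
  path <- withr::local_tempfile(fileext = ".hssp")
  pc <- matrix(5L, 3, 20)
  writeLines(hssp_stub_lines(pc, var = c(12L, 60L, 99L)), path)
  prof <- parse_hssp(path)
  expect_equal(prof$sequence_variability, c(12, 60, 99))
})

test_that("parse_hssp accepts integer-percent rounding within tolerance", {
  path <- withr::local_tempfile(fileext = ".hssp")
  pc <- matrix(0L, 1, 20)
  pc[1, 1:14] <- 7L  # sums to 98
  writeLines(hssp_stub_lines(pc), path)
  expect_equal(sum(as.matrix(parse_hssp(path)[paste0("p_", AA_CODES)])), 0.98)
  # missing profile section
  writeLines("HSSP stub with nothing", path)
  expect_error(parse_hssp(path), "SEQUENCE PROFILE")
})

test_that("profile TSV dialect round-trips and validates", {
  prof <- make_synthetic_profiles(6, c(1, 1, 0, 0, 1, 0), signal_spec(seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  back <- parse_profile_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(prof), tolerance = 1e-9,
               ignore_attr = TRUE)

  # negative probability rejected
  bad <- as.data.frame(prof)
  bad$p_A[1] <- -0.1
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_profile_tsv(path), "negative")

  # missing nocc defaults to 1, flagged
  noc <- as.data.frame(prof)
  noc$nocc <- NULL
  utils::write.table(noc, path, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- parse_profile_tsv(path)
  expect_true(attr(got, "nocc_defaulted"))
  expect_equal(got$nocc, rep(1, 6))

  # wrong columns rejected
  wrong <- noc[, 1:10]
  utils::write.table(wrong, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_profile_tsv(path), "missing columns")
})

test_that("physchem lookup has shape 13, X fallback, and is injective", {
  v <- physchem_lookup("W")
  expect_length(v, 13)
  expect_equal(unname(physchem_lookup("X")),
               unname(c(colMeans(HQI8_TABLE), colMeans(AA_FACTORS))))
  # vendored tables distinguish every amino-acid pair in at least one column
  allv <- t(vapply(AA_CODES, physchem_lookup, numeric(13)))
  expect_equal(nrow(unique(as.data.frame(allv))), 20)
})

test_that("assemble_residue_vector has fixed length-50 order and errors on gaps", {
  expect_length(residue_feature_names(), 50)
  prof <- make_synthetic_profiles(2, c(0, 1), signal_spec(seed = 9))
  toy <- make_toy_complex(toy_complex_spec(n_res_per_chain = 2,
                                           contact_patch_size = 0,
                                           inter_chain_gap = 50))
  sas <- relative_asa(residue_asa(toy$structure, "unbound", n_points = 480L))
  geom <- geometry_features(toy$structure, n_points = 480L)
  v <- assemble_residue_vector(prof[1, ], sas[1, ], geom[1, ],
                               physchem_lookup("A"))
  expect_length(v, 50)
  expect_equal(names(v), residue_feature_names())
  expect_equal(unname(v[1:20]),
               unlist(prof[1, paste0("p_", AA_CODES)], use.names = FALSE))
  expect_equal(v[["total_asa"]], sas$total_asa[1])
  expect_equal(v[["dpx"]], geom$dpx[1])
  expect_error(assemble_residue_vector(NULL, sas[1, ], geom[1, ],
                                       physchem_lookup("A")), "profile")
  expect_error(assemble_residue_vector(prof[1, ], sas[1, ], geom[1, ],
                                       1:3), "physchem")
  # all-zero inputs give the zero vector
  zrow <- as.list(stats::setNames(rep(0, 25), names(prof)))
  zs <- sas[1, ]
  zs[sasa_table_cols] <- 0
  zs[rasa_table_cols] <- 0
  zg <- list(dpx = 0, cx = 0)
  expect_equal(unname(assemble_residue_vector(zrow, zs, zg, rep(0, 13))),
               rep(0, 50))
})
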