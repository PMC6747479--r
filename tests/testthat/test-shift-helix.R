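mk_shifts <- function(nums, types, shifts, atom = "HN") {
  tibble::tibble(residue_number = nums, residue_type = types,
                 atom = atom, shift = shifts)
}

test_that("CSP is signed, antisymmetric and zero on identical tables", {
  a <- mk_shifts(1:5, c("A", "L", "I", "S", "N"), c(8.2, 8.1, 8.0, 8.3, 8.4))
  expect_true(all(csp(a, a)$delta == 0))
  b <- a
  b$shift[1] <- 8.05
  out <- csp(a, b)
  expect_equal(out$delta[1], -0.15, tolerance = 1e-12)
  # antisymmetry
  ab <- csp(a, b)$delta
  ba <- csp(b, a)$delta
  expect_equal(ab, -ba)
})

test_that("alternating offsets produce alternating signed differences", {
  nums <- 1:10
  base <- 8 + 0.01 * nums
  off <- rep(c(0.1, -0.1), 5)
  a <- mk_shifts(nums, rep("L", 10), base)
  b <- mk_shifts(nums, rep("L", 10), base + off)
  out <- csp(a, b)
  expect_equal(out$delta, off)
  expect_equal(sign(out$delta), rep(c(1, -1), 5))
})

test_that("residues present in only one table are reported missing, not zero", {
  a <- mk_shifts(1:5, rep("A", 5), rep(8, 5))
  b <- mk_shifts(3:7, rep("A", 5), rep(8.1, 5))
  out <- csp(a, b)
  expect_equal(nrow(out), 7)
  expect_true(all(out$missing[out$residue_number %in% c(1, 2, 6, 7)]))
  expect_true(all(!out$missing[out$residue_number %in% 3:5]))
  disjoint <- mk_shifts(10:12, rep("A", 3), rep(8, 3))
  expect_error(csp(a, disjoint), class = "micellr_empty_overlap_error")
})

test_that("combined amide CSP scales the nitrogen term by 1/5", {
  a <- dplyr::bind_rows(mk_shifts(1:3, rep("A", 3), c(8, 8, 8), "HN"),
                        mk_shifts(1:3, rep("A", 3), c(120, 120, 120), "N"))
  b <- dplyr::bind_rows(mk_shifts(1:3, rep("A", 3), c(8.1, 8, 8), "HN"),
                        mk_shifts(1:3, rep("A", 3), c(120, 121, 120), "N"))
  out <- csp_combined(a, b)
  expect_equal(out$csp_combined, c(0.1, 0.2, 0))
})

test_that("wheel angles depend only on index with 100 degree steps", {
  w <- helical_wheel(strrep("L", 19), start_residue = 1)
  expect_equal(w$angle[1], 0)
  expect_equal(w$angle[2], 100)
  # 18 residues = 5 turns exactly: residue i and i+18 coincide
  expect_equal(w$angle[19], w$angle[1])
  # angles do not depend on sequence content
  w2 <- helical_wheel(strrep("S", 19))
  expect_equal(w$angle, w2$angle)
  expect_true(all(w$face == "hydrophobic"))
  expect_true(all(w2$face == "hydrophilic"))
  expect_error(helical_wheel("LXZ"), class = "micellr_parse_error")
})

test_that("the amphipathicity statistic matches a brute-force circular resultant", {
  # helical region of the studied transmembrane fragment, Pro258-Thr271
  w <- helical_wheel("PLIACILLLSMNST", start_residue = 258)
  amph <- amphipathicity(w)
  # brute-force circular resultant of the hydrophobic angles as the oracle
  ang <- w$angle[w$residue_type %in% c("A", "C", "F", "I", "L", "M", "V", "W")] * pi / 180
  r_brute <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  expect_equal(amph$resultant_length, r_brute, tolerance = 1e-12)
  # this helix is hydrophobic nearly all around: the sequence-only wheel is
  # NOT amphipathic (face segregation in the zwitterionic micelle comes from
  # the molecular environment, not from sequence periodicity alone)
  expect_false(amph$amphipathic)
})

test_that("a designed amphipathic helix is flagged and a uniform one is not", {
  # leucines placed wherever the wheel angle falls within +/-90 deg of zero
  amph_seq <- "LSSLLSSLLSSLSSLLSS"
  res <- amphipathicity(helical_wheel(amph_seq))
  expect_true(res$amphipathic)
  expect_gt(res$resultant_length, 0.4)
  # hydrophobic face centred near zero by construction
  expect_true(res$mean_angle < 90 || res$mean_angle > 270)
  # a poly-leucine wheel is NOT amphipathic: hydrophobics everywhere
  expect_false(amphipathicity(helical_wheel(strrep("L", 18)))$amphipathic)
})
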