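test_that("the propensity matrix transforms, flags and validates cells", {
  s <- read_structure(gpc_pdb())
  specs <- enumerate_mutations(s)

  # flat table: every cell at the folding-unfolding equilibrium
  flat <- dplyr::mutate(specs, ddg = 0, source = "test")
  m <- build_propensity_matrix(flat, s)
  expect_equal(nrow(m), 60)
  expect_true(all(m$u == 0.5))

  # planted +6 kcal/mol at every substitution of residue 2
  planted <- dplyr::mutate(
    specs, ddg = ifelse(position == 2 & !is_identity, 6, 0), source = "test")
  m2 <- build_propensity_matrix(planted, s)
  row2 <- dplyr::filter(m2, position == 2)
  expect_equal(sum(row2$u > 0.9), 19)
  expect_equal(row2$u[row2$is_identity], 0.5)
  # direct transform of the planted value
  expect_equal(unique(row2$u[!row2$is_identity]),
               1 / (1 + exp(-6 / default_rt())))

  # exactly one identity cell per row, 20 columns per row
  per_row <- dplyr::summarise(tibble::as_tibble(m2),
                              n = dplyr::n(), n_id = sum(is_identity),
                              .by = position)
  expect_true(all(per_row$n == 20))
  expect_true(all(per_row$n_id == 1))
})

test_that("wild-type mismatches and missing-cell policies are enforced", {
  s <- read_structure(make_toy_structure(6, seed = 1))
  ddg <- make_synthetic_ddg(s, seed = 1)$ddg

  bad <- ddg
  bad$wt[bad$position == 5] <- ifelse(bad$wt[bad$position == 5] == "A", "G", "A")
  expect_error(build_propensity_matrix(bad, s), "position.*A:5|A:5")

  # a dropped record leaves a missing (never imputed) cell
  drop1 <- ddg[-5, ]
  m <- build_propensity_matrix(drop1, s)
  expect_equal(sum(is.na(m$u)), 1)
  expect_error(build_propensity_matrix(drop1, s, on_missing = "error"),
               "no ddG record")
})

test_that("foldability is the threshold-gated sum over substitutions", {
  # all 19 substitutions fully unfolded -> the printed maximum 19
  m_max <- matrix_from_u(list(row_u("A", 1.0)))
  expect_equal(foldability_profile(m_max)$foldability, 19)

  # nothing exceeds the saturation threshold
  m_mid <- matrix_from_u(list(row_u("A", 0.5)))
  expect_equal(foldability_profile(m_mid)$foldability, 0)

  # three substitutions at 0.95, the rest at 0.2: brute-force sum 3 x 0.95
  u <- rep(0.2, 20)
  u[amino_acids() == "A"] <- 0.5 # identity
  u[which(amino_acids() != "A")[1:3]] <- 0.95
  m3 <- matrix_from_u(list(u))
  expect_equal(foldability_profile(m3)$foldability, 2.85)

  # the identity cell is excluded even when extreme
  u_id <- row_u("A", 0.2, u0 = 0.99)
  expect_equal(foldability_profile(matrix_from_u(list(u_id)))$foldability, 0)

  expect_error(foldability_profile(m_max, threshold = 1.2), "\\(0, 1\\)")
})

test_that("foldability is monotone in the threshold and maxes iff all-ones", {
  s <- read_structure(make_toy_structure(12, seed = 5))
  m <- build_propensity_matrix(estimate_ddg_toy(s), s)
  thresholds <- c(0.5, 0.7, 0.9, 0.95)
  profs <- lapply(thresholds, function(t) foldability_profile(m, t)$foldability)
  for (i in seq_len(length(profs) - 1)) {
    expect_true(all(profs[[i + 1]] <= profs[[i]]))
  }
  # 19 exactly iff every substitution cell is exactly 1
  almost <- matrix_from_u(list(row_u("A", 1 - 1e-9)))
  expect_lt(foldability_profile(almost)$foldability, 19)
  expect_equal(foldability_profile(matrix_from_u(list(row_u("C", 1)), wt = "C"))$foldability, 19)
})

test_that("critical residues come from strict cutoff comparison", {
  m <- matrix_from_u(list(row_u("A", 1.0 - 0.02 / 19),  # foldability 18.98
                          row_u("C", 0.5),
                          row_u("D", 0.52)))
  prof <- foldability_profile(m)
  expect_equal(prof$foldability[1], 18.98, tolerance = 1e-12)
  crit <- critical_residues(prof)
  expect_equal(crit$position, 1)

  # all-zero profile: empty set
  m0 <- matrix_from_u(list(row_u("A", 0.1), row_u("C", 0.2)))
  expect_equal(nrow(critical_residues(foldability_profile(m0))), 0)

  # monotone in the cutoff: stricter cutoffs give subsets
  s <- read_structure(make_toy_structure(15, seed = 3))
  prof2 <- foldability_profile(build_propensity_matrix(estimate_ddg_toy(s), s))
  strict <- critical_residues(prof2, cutoff = 17.1)
  loose <- critical_residues(prof2, cutoff = 10)
  expect_true(all(strict$position %in% loose$position))

  # rows with >2 missing substitution cells are excluded with a warning
  m_na <- matrix_from_u(list(replace(row_u("A", 1.0), 2:4, NA),
                             row_u("C", 1.0)))
  prof_na <- foldability_profile(m_na)
  expect_false(prof_na$comparable[1])
  expect_warning(crit_na <- critical_residues(prof_na), "excluded")
  expect_equal(crit_na$position, 2)
})

test_that("internal control reports identity statistics and a CI verdict", {
  # ideal stereochemistry: all identity cells exactly 0.5
  s <- read_structure(make_toy_structure(8, seed = 1))
  m <- build_propensity_matrix(estimate_ddg_toy(s), s)
  ctrl <- internal_control(m)
  expect_equal(ctrl$mean, 0.5)
  expect_equal(ctrl$sd, 0)
  expect_equal(ctrl$verdict, "pass")

  # hand-computed sample statistics
  m3 <- matrix_from_u(list(row_u("A", 0.3, u0 = 0.48),
                           row_u("C", 0.3, u0 = 0.50),
                           row_u("D", 0.3, u0 = 0.52)),
                      wt = c("A", "C", "D"))
  ctrl3 <- internal_control(m3)
  expect_equal(ctrl3$n, 3)
  expect_equal(ctrl3$mean, 0.5)
  expect_equal(ctrl3$sd, 0.02)
  expect_true(ctrl3$conf_low <= 0.5 && 0.5 <= ctrl3$conf_high)
  td <- tidy(ctrl3)
  expect_equal(td$mean, 0.5)
  expect_equal(td$verdict, ctrl3$verdict)

  # the CI half-width matches the t-based oracle and drives the verdict
  set.seed(11)
  noisy_u <- pmin(pmax(0.5 + rnorm(100, 0, 0.2), 0), 1)
  rows <- lapply(noisy_u, function(v) row_u("A", 0.3, u0 = v))
  ctrl_noisy <- internal_control(matrix_from_u(rows))
  half_width <- qt(0.975, 99) * sd(noisy_u) / 10
  expect_equal((ctrl_noisy$conf_high - ctrl_noisy$conf_low) / 2, half_width,
               tolerance = 1e-9)
  in_ci <- ctrl_noisy$conf_low <= 0.5 && 0.5 <= ctrl_noisy$conf_high
  expect_equal(ctrl_noisy$verdict,
               if (half_width <= 0.05 && in_ci) "pass" else "fail")

  # few, scattered identities: half-width ~ t * 0.2 / 5 > 0.05 -> fail
  set.seed(12)
  few_u <- pmin(pmax(0.5 + rnorm(25, 0, 0.2), 0), 1)
  ctrl_few <- internal_control(
    matrix_from_u(lapply(few_u, function(v) row_u("A", 0.3, u0 = v))))
  expect_gt((ctrl_few$conf_high - ctrl_few$conf_low) / 2, 0.05)
  expect_equal(ctrl_few$verdict, "fail")

  expect_error(internal_control(matrix_from_u(list(row_u("A", 0.5)))),
               "at least 2")
})

test_that("the matrix serialises to TSV and round-trips", {
  s <- read_structure(make_toy_structure(7, seed = 4))
  m <- build_propensity_matrix(estimate_ddg_toy(s), s)
  text <- write_propensity_matrix(m)
  back <- read_propensity_matrix(text)
  expect_equal(back$u, m$u)
  expect_equal(back$position, m$position)
  expect_equal(back$wt, m$wt)
  expect_equal(back$mut, m$mut)
  header <- strsplit(strsplit(text, "\n")[[1]][1], "\t")[[1]]
  expect_equal(header, c("residue", amino_acids()))
})
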