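fx <- fertscreen_fixtures()

test_that("study-inclusion rule needs >= 4 MII and FR <= 1/3 in one ICSI record", {
  p2 <- fx$cycles[fx$cycles$patient_id == "P2", ]
  expect_true(eligibility(p2))
  # MII floor: 1/3 fertilization but only 3 oocytes
  tiny <- data.frame(arm = "ICSI", mii = 3L, two_pn = 1L)
  expect_false(eligibility(tiny))
  # boundary: 33.34% is over the line, 33.33...% (exactly 1/3) is not
  over <- data.frame(arm = "ICSI", mii = 10000L, two_pn = 3334L)
  expect_false(eligibility(over))
  at <- data.frame(arm = "ICSI", mii = 9L, two_pn = 3L)
  expect_true(eligibility(at))
  expect_false(eligibility(data.frame(arm = "ICSI_AOA", mii = 10L, two_pn = 0L)))
})

test_that("MOAT groups partition the activation-rate axis", {
  expect_identical(moat_group(5, 26)$group, 1L)    # 19.23%
  expect_identical(moat_group(20, 24)$group, 2L)   # 83.33%
  expect_identical(moat_group(17, 19)$group, 3L)   # 89.47%
  expect_identical(moat_group(1, 5)$group, 1L)     # 20% exactly -> group 1
  expect_identical(moat_group(17, 20)$group, 3L)   # 85% exactly -> group 3
  # monotone step function of the rate
  groups <- vapply(0:100, function(k) moat_group(k, 100)$group, integer(1))
  expect_true(all(diff(groups) >= 0))
  expect_error(moat_group(3, 0), "mii >= 1")
  expect_error(moat_group(5, 4), "exceeds")
})

test_that("pooled rates reproduce the printed per-arm totals", {
  icsi <- fx$cycles[fx$cycles$arm == "ICSI", ]
  aoa <- fx$cycles[fx$cycles$arm == "ICSI_AOA", ]
  fr_icsi <- aggregate_rate(icsi, "fertilization")
  expect_identical(c(fr_icsi$numerator, fr_icsi$denominator), c(56L, 498L))
  fr_aoa <- aggregate_rate(aoa, "fertilization")
  expect_identical(c(fr_aoa$numerator, fr_aoa$denominator), c(199L, 322L))
  bl <- aggregate_rate(aoa, "blastocyst")
  expect_identical(c(bl$numerator, bl$denominator), c(94L, 143L))
  hcg <- aggregate_rate(aoa, "hcg_per_cycle")
  expect_identical(c(hcg$numerator, hcg$denominator), c(21L, 35L))
  lbr <- aggregate_rate(icsi, "lb_per_cycle")
  expect_identical(c(lbr$numerator, lbr$denominator), c(3L, 47L))
  expect_error(aggregate_rate(icsi, "blastocyst"), "blastocyst culture")
})

test_that("pooling is invariant to partitioning the cycles", {
  aoa <- fx$cycles[fx$cycles$arm == "ICSI_AOA", ]
  set.seed(11)
  half <- sample(nrow(aoa), nrow(aoa) %/% 2)
  for (kind in c("fertilization", "hcg_per_cycle", "lb_per_cycle")) {
    whole <- aggregate_rate(aoa, kind)
    a <- aggregate_rate(aoa[half, ], kind)
    b <- aggregate_rate(aoa[-half, ], kind)
    expect_identical(a$numerator + b$numerator, whole$numerator)
    expect_identical(a$denominator + b$denominator, whole$denominator)
  }
})

test_that("the exact Fisher test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  # independent binomial-coefficient oracle on all tables with margins <= 8
  for (a in 0:8) for (b in 0:(8 - a)) for (c in 0:8) for (d in 0:(8 - c)) {
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d), fisher_oracle(a, b, c, d),
                 tolerance = 1e-12)
  }
  # spot-check against the reference implementation on larger random tables
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # invariant under row and column swaps
  expect_equal(fisher_exact_2x2(5, 42, 21, 14), fisher_exact_2x2(21, 14, 5, 42))
  expect_equal(fisher_exact_2x2(5, 42, 21, 14), fisher_exact_2x2(42, 5, 14, 21))
  # degenerate column margins are certain tables, not errors
  expect_equal(fisher_exact_2x2(0, 5, 0, 3), 1)
  expect_equal(fisher_exact_2x2(5, 0, 3, 0), 1)
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins")
  expect_error(fisher_exact_2x2(2, -1, 3, 4), "non-negative")
})

test_that("arm comparison reports all endpoints with exact p-values", {
  cmp <- compare_arms(fx$cycles)
  expect_lt(cmp$fertilization$p_value, 1e-4)
  expect_lt(cmp$hcg$p_value, 1e-4)
  expect_lt(cmp$live_birth$p_value, 0.005)
  expect_true(cmp$live_birth$significant)
  # identical arms: p = 1 throughout
  same <- data.frame(
    patient_id = "X", arm = rep(c("ICSI", "ICSI_AOA"), each = 2),
    n_cycles = 1L, mii = 10L, two_pn = 4L, blastocysts = 2L,
    embryos_transferred = 1L, transfer_day = NA, hcg_positive = 1L,
    outcomes = "LB"
  )
  cmp0 <- compare_arms(same)
  for (e in c("fertilization", "blastocyst", "hcg", "live_birth")) {
    expect_equal(cmp0[[e]]$p_value, 1)
  }
  expect_error(compare_arms(fx$cycles[fx$cycles$arm == "ICSI", ]), "both arms")
})

test_that("acrosome detachment calls use the 50% rule", {
  expect_true(detachment_call(0.50))
  expect_false(detachment_call(0.49))
  expect_true(detachment_call(0.6, folded_curved = TRUE))
  expect_false(detachment_call(0.3, folded_curved = TRUE))
  expect_error(detachment_call(1.2), "\\[0, 1\\]")
})

test_that("detachment rates compare against the control by Fisher", {
  p29 <- sperm_cells(25, 28)
  control <- sperm_cells(10, 30)
  res <- detachment_rate(p29, control)
  expect_identical(c(res$rate$numerator, res$rate$denominator), c(25L, 28L))
  expect_equal(round(100 * res$rate$rate, 2), 89.29)
  expect_equal(round(100 * detachment_rate(control)$rate$rate, 2), 33.33)
  expect_lt(res$fisher_p, 0.0001)
  expect_false(res$low_n)
  expect_warning(detachment_rate(sperm_cells(3, 10)), "low_n")
  expect_error(detachment_rate(sperm_cells(0, 5)[0, ]), "intact")
})

test_that("immunofluorescence classes split on background-corrected intensity", {
  thr <- list(invisible_max = 5, obvious_min = 30)
  expect_identical(if_expression_class(10, 10, thr), "invisible")
  expect_identical(if_expression_class(27.5, 10, thr), "weak")  # midway
  expect_identical(if_expression_class(45, 10, thr), "obvious")
  expect_error(if_expression_class(10, 5, list(invisible_max = 10, obvious_min = 5)),
               "exceed")
  expect_error(if_expression_class(NA, 5, thr), "present")
})

test_that("expression proportions count weak-or-obvious cells", {
  cells <- function(n_expr, n_total) {
    data.frame(acrosome_intact = TRUE,
               if_intensity = c(rep(40, n_expr), rep(2, n_total - n_expr)),
               if_background = 1)
  }
  all_inv <- expression_proportion(cells(0, 60))
  expect_identical(all_inv$rate$numerator, 0L)
  all_obv <- expression_proportion(cells(60, 60))
  expect_identical(all_obv$rate$rate, 1)
  two_thirds <- expression_proportion(cells(40, 60))
  expect_equal(round(100 * two_thirds$rate$rate, 2), 66.67)
  p29_like <- expression_proportion(cells(14, 57))
  expect_equal(round(100 * p29_like$rate$rate, 2), 24.56)
  expect_true(expression_proportion(cells(2, 10))$low_n)
})
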