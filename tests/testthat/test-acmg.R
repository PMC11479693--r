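test_that("evidence items validate code/direction/strength agreement", {
  expect_s3_class(evidence_item("PS3", "pathogenic", "strong"), "evidence_item")
  expect_s3_class(evidence_item("BA1", "benign", "stand_alone"), "evidence_item")
  expect_error(evidence_item("PS3", "benign", "strong"), "disagrees")
  expect_error(evidence_item("BS3", "pathogenic", "strong"), "disagrees")
  expect_error(evidence_item("PM2", "pathogenic", "stand_alone"), "stand_alone")
})

test_that("points follow the exponent scheme with benign symmetry", {
  expect_identical(points_of(evidence_item("PS3", "pathogenic", "strong")), 4L)
  expect_identical(points_of(evidence_item("PP3", "pathogenic", "supporting")), 1L)
  expect_identical(points_of(evidence_item("BS3", "benign", "strong")), -4L)
  # symmetry across every finite strength
  codes <- list(supporting = c("PP1", "BP1"), moderate = c("PM1", "BP2"),
                strong = c("PS1", "BS2"), very_strong = c("PVS1", "BS1"))
  for (s in names(codes)) {
    expect_identical(
      points_of(evidence_item(codes[[s]][1], "pathogenic", s)),
      -points_of(evidence_item(codes[[s]][2], "benign", s))
    )
  }
  expect_true(is.na(points_of(evidence_item("BA1", "benign", "stand_alone"))))
})

test_that("net points sum signed items and tolerate the empty set", {
  expect_identical(net_points(list()), 0L)
  expect_identical(net_points(path_items(c("strong", "supporting"))), 5L)
  ev <- c(path_items(c("very_strong", "supporting")),
          list(evidence_item("BP4", "benign", "moderate")))
  expect_identical(net_points(ev), 7L)
})

test_that("posterior returns the prior at zero and increases strictly", {
  expect_identical(posterior_probability(0), 0.1)
  n <- -15:15
  post <- posterior_probability(n)
  expect_true(all(diff(post) > 0))
  expect_true(all(post > 0 & post < 1))
  # direct evaluation at -8: odds 1/350
  expect_equal(posterior_probability(-8),
               (0.1 / 350) / ((1 / 350 - 1) * 0.1 + 1), tolerance = 1e-12)
  # custom prior respected exactly at zero points
  expect_identical(posterior_probability(0, bayes_params(prior = 0.3)), 0.3)
})

test_that("categories follow the point bounds and BA1 overrides", {
  expect_identical(categorize(9), "LP")
  expect_identical(categorize(10), "P")
  expect_identical(categorize(5), "VUS")
  expect_identical(categorize(0), "VUS")
  expect_identical(categorize(-1), "LB")
  expect_identical(categorize(-6), "LB")
  expect_identical(categorize(-7), "B")
  ba1 <- list(evidence_item("BA1", "benign", "stand_alone"))
  expect_identical(categorize(5, ba1), "B")
  # monotone toward pathogenic: increasing points never moves toward benign
  order_of <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  cats <- vapply(-12:14, categorize, character(1))
  expect_true(all(diff(order_of[cats]) >= 0))
})

test_that("VUS temperature tiers map points 5..0 to hot..ice_cold", {
  expect_identical(vus_tier(5), "hot")
  expect_identical(vus_tier(4), "warm")
  expect_identical(vus_tier(3), "tepid")
  expect_identical(vus_tier(2), "cool")
  expect_identical(vus_tier(1), "cold")
  expect_identical(vus_tier(0), "ice_cold")
  expect_error(vus_tier(6), "VUS band")
  expect_error(vus_tier(-1), "VUS band")
})

test_that("classify composes points, posterior, category and tier", {
  cl0 <- classify()
  expect_identical(cl0$net_points, 0L)
  expect_identical(cl0$posterior, 0.1)
  expect_identical(cl0$category, "VUS")
  expect_identical(cl0$vus_tier, "ice_cold")

  cl6 <- classify(path_items(c("strong", "moderate")))
  expect_identical(cl6$net_points, 6L)
  expect_equal(round(cl6$posterior, 3), 0.900)
  expect_identical(cl6$category, "LP")
  expect_true(is.na(cl6$vus_tier))

  cl7 <- classify(path_items(c("strong", "moderate", "supporting")))
  expect_equal(round(cl7$posterior, 3), 0.949)
  expect_identical(cl7$category, "LP")
})

test_that("functional evidence updates move the classification both ways", {
  hot <- classify(path_items(rep("supporting", 5)))
  up <- update_with_functional(hot, path_items("supporting"))
  expect_identical(up$category, "LP")
  expect_equal(round(up$posterior, 3), 0.900)

  lp7 <- classify(path_items(c("strong", "moderate", "supporting")))
  up4 <- update_with_functional(lp7, path_items("strong"))
  expect_identical(up4$category, "P")
  expect_equal(round(up4$posterior, 3), 0.997)

  down <- update_with_functional(hot, list(evidence_item("BP4", "benign", "supporting")))
  expect_identical(down$category, "VUS")
  expect_identical(down$vus_tier, "warm")
  expect_equal(round(down$posterior, 3), 0.675)
})

test_that("posterior inversion round-trips all integer point totals", {
  for (n in -15:15) {
    expect_identical(invert_posterior(posterior_probability(n)), as.integer(n))
  }
  expect_identical(invert_posterior(0.1), 0L)
  expect_identical(invert_posterior(0.949), 7L)
  expect_identical(invert_posterior(0.988), 9L)
  expect_error(invert_posterior(1), "strictly")
})

test_that("evidence JSON round-trips through the classification report", {
  sets <- list(
    v1 = list(list(criterion = "PS3", direction = "pathogenic", strength = "strong"),
              list(criterion = "PM2", direction = "pathogenic", strength = "moderate")),
    v2 = list()
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(sets, path, auto_unbox = TRUE)
  ev <- read_evidence_json(path)
  expect_length(ev$v1, 2)
  out <- classification_report(ev)
  expect_identical(out$net_points, c(6L, 0L))
  expect_identical(out$posterior, c(0.9, 0.1))
  expect_identical(out$category, c("LP", "VUS"))
  expect_identical(out$vus_tier, c(NA_character_, "ice_cold"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  classification_report(ev, path = tsv)
  back <- read.delim(tsv)
  expect_identical(back$variant_id, c("v1", "v2"))
})
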