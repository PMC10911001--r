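demo_units <- function(n = 8) {
  u <- toy_units(ceiling(sqrt(n)), 10)[seq_len(n), ]
  u$pct_minority <- seq(10, 80, length.out = n)
  u$pct_black <- seq(5, 60, length.out = n)
  u$pct_native_american <- c(55, rep(5, n - 1))
  u$pct_asian <- rep(4, n)
  u$pct_hispanic <- seq(60, 4, length.out = n)
  u$pct_poverty <- seq(5, 40, length.out = n)
  u$svi <- (seq_len(n) - 0.5) / n
  u$urbanicity <- rep(c("rural", "urban cluster", "urban"), length.out = n)
  u$pop_density <- seq(0.1, 2, length.out = n)
  u$prominence_km <- seq(0, 1.4, length.out = n)
  u
}

test_that("categorize_units applies the documented boundary conventions", {
  u <- demo_units(8)
  u$pct_native_american[2] <- 50.0 # exactly 50 is NOT majority
  u$pct_poverty[2] <- 20.0 # exactly 20 is NOT low income (strict >)
  u$svi[1] <- 0.25 # right-closed: very low
  u$svi[2] <- 0.250001 # just above: low
  cats <- categorize_units(u)
  expect_false(cats$majority_native_american[2])
  expect_true(cats$majority_native_american[1])
  expect_equal(cats$income_class[2], "not low income")
  expect_equal(cats$svi_bin[1], "very low")
  expect_equal(cats$svi_bin[2], "low")

  # configurable >= operator flips the exactly-20 case
  cats_ge <- categorize_units(u, poverty_op = `>=`)
  expect_equal(cats_ge$income_class[2], "low income")

  # missing attribute flags the unit unclassifiable for that scheme only
  u$pct_black[3] <- NA
  cats_na <- categorize_units(u)
  expect_true(is.na(cats_na$majority_black[3]))
  expect_false(is.na(cats_na$majority_hispanic[3]))
})

test_that("stratification schemes are total and mutually exclusive", {
  u <- demo_units(8)
  cats <- categorize_units(u)
  expect_false(anyNA(cats$svi_bin))
  expect_false(anyNA(cats$income_class))
  expect_true(all(table(cats$svi_bin) == 2)) # uniform SVI -> 2 per quartile
})

test_that("prominence is the max-min over intersecting aggregated cells", {
  spec <- grid_spec(0, 0, 1, 1, 4, 4)
  flat <- list(spec = spec, values = matrix(0.3, 4, 4))
  ring <- epeagree:::rect_ring(0.5, 3.5, 0.5, 3.5)
  expect_equal(prominence_from_elevation(ring, flat), 0)

  three <- list(spec = grid_spec(0, 0, 1, 1, 3, 1), values = matrix(c(0.1, 0.5, 0.9), 1))
  expect_equal(
    prominence_from_elevation(epeagree:::rect_ring(0, 3, 0, 1), three),
    0.8
  )

  # checkerboard: 2x2 block means halve the extremes
  cb <- matrix(rep(c(0, 1), 8), 4, 4)
  cb[, c(2, 4)] <- 1 - cb[, c(2, 4)]
  el <- list(spec = spec, values = cb)
  full <- epeagree:::rect_ring(0, 4, 0, 4)
  expect_equal(prominence_from_elevation(full, el), 1)
  # block means of a perfect checkerboard are constant 0.5 -> prominence 0
  expect_equal(prominence_from_elevation(full, el, agg_factor = 2), 0)

  blocky <- list(spec = spec, values = matrix(rep(c(0, 0, 1, 1), 4), 4, byrow = TRUE))
  expect_equal(prominence_from_elevation(full, blocky, agg_factor = 2), 1)

  expect_error(
    prominence_from_elevation(epeagree:::rect_ring(10, 12, 10, 12), flat),
    "does not intersect"
  )
})

test_that("matching uses closed one-SD bands around the referent", {
  u <- demo_units(8)
  flag <- u$pct_native_american > 50
  u$pct_native_american[2] <- 60 # two referent units
  flag <- u$pct_native_american > 50

  mu_d <- mean(u$pop_density[flag])
  sd_d <- sd(u$pop_density[flag])
  mu_p <- mean(u$prominence_km[flag])
  sd_p <- sd(u$prominence_km[flag])
  # plant a candidate exactly at mu + sd on both covariates: matched (closed)
  u$pop_density[5] <- mu_d + sd_d
  u$prominence_km[5] <- mu_p + sd_p
  res <- match_units(u, flag)
  expect_equal(res$match_group[5], "matched")
  expect_equal(sum(res$match_group == "referent"), 2)
  expect_equal(nrow(res), length(res$match_group))
  expect_setequal(unique(res$match_group), c("referent", "matched", "unmatched"))

  # partition property
  expect_equal(
    sum(res$match_group == "referent") + sum(res$match_group == "matched") +
      sum(res$match_group == "unmatched"),
    nrow(u)
  )

  # identical covariates: every non-referent unit is matched
  u2 <- u
  u2$pop_density <- 1
  u2$prominence_km <- 0.5
  res2 <- match_units(u2, flag)
  expect_true(all(res2$match_group[!flag] == "matched"))

  # ordering invariance
  perm <- sample(nrow(u))
  res3 <- match_units(u[perm, ], flag[perm])
  expect_equal(
    res3$match_group[match(res$unit_id, res3$unit_id)],
    res$match_group
  )

  expect_error(match_units(u, u$pct_asian > 50), "at least 2")
})

test_that("distance regression recovers planted coefficients", {
  # two points: exact line, zero residual
  prof <- tibble::tibble(unit_id = c("A", "B"), mean_daily_distance_km = c(5, 25))
  un <- tibble::tibble(
    unit_id = c("A", "B"), pct_native_american = c(10, 50),
    prominence_km = c(0, 0.5), pop_density = c(1, 2)
  )
  fit <- distance_regression(prof, un, models = 1)
  expect_equal(fit$estimate[fit$term == "native_share"], 20 / 0.4)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 5 - (20 / 0.4) * 0.1)

  # slope recovery with vanishing noise
  set.seed(71)
  n <- 120
  share <- runif(n, 0, 0.8)
  un2 <- tibble::tibble(
    unit_id = sprintf("U%03d", 1:n),
    pct_native_american = 100 * share,
    prominence_km = runif(n), pop_density = runif(n, 0, 3)
  )
  prof2 <- tibble::tibble(
    unit_id = un2$unit_id,
    mean_daily_distance_km = 7 + 20 * share + rnorm(n, 0, 1e-8)
  )
  fit2 <- distance_regression(prof2, un2, models = 1)
  expect_equal(fit2$estimate[fit2$term == "native_share"], 20, tolerance = 1e-6)

  # an orthogonalized covariate leaves the share coefficient unchanged
  un3 <- un2
  un3$prominence_km <- resid(lm(runif(n) ~ share))
  m1 <- distance_regression(prof2, un3, models = 1)
  m2 <- distance_regression(prof2, un3, models = 2)
  expect_equal(
    m2$estimate[m2$term == "native_share"],
    m1$estimate[m1$term == "native_share"],
    tolerance = 1e-6
  )

  # collinear design is rejected with the offending term named
  un4 <- un2
  un4$prominence_km <- un4$pct_native_american / 100
  expect_error(distance_regression(prof2, un4, models = 2), "collinear")

  expect_error(distance_regression(prof[1, ], un[1, ], models = 1), "too few")
})

test_that("one-way ANOVA matches t^2 for two groups and is label-invariant", {
  set.seed(73)
  x <- rnorm(20, 0)
  y <- rnorm(15, 1)
  res <- one_way_anova(c(x, y), rep(c("a", "b"), c(20, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  r1 <- one_way_anova(v, g)
  relab <- c(a = "c", b = "a", c = "b")[g]
  r2 <- one_way_anova(v, relab)
  expect_equal(r1$f_statistic, r2$f_statistic)

  # degenerate zero within-group variance
  dg <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(dg$f_statistic, Inf)
  expect_equal(dg$p_value, 0)
  expect_equal(dg$note, "zero within-group variance")

  expect_error(one_way_anova(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("confusion counts match an exhaustive unit-day comparison", {
  def <- epe_definition("percentile_99")
  dates <- as.Date("2015-01-01") + 0:2
  r <- epe_matrix(matrix(c(1, 0, 1), 1), "U1", dates, "ref", def)
  c1 <- epe_matrix(matrix(c(0, 0, 1), 1), "U1", dates, "cmp", def)
  out <- confusion_counts(r, c1, "U1")
  expect_equal(out$false_negatives, 1)
  expect_equal(out$false_positives, 0)
  expect_equal(out$reference_epes, 2)

  same <- confusion_counts(r, r, "U1")
  expect_equal(same$false_positives + same$false_negatives, 0)

  set.seed(79)
  nu <- 12
  nd <- 50
  ids <- sprintf("U%02d", 1:nu)
  a <- matrix(rbinom(nu * nd, 1, 0.1), nu)
  b <- matrix(rbinom(nu * nd, 1, 0.1), nu)
  a[sample(length(a), 20)] <- NA
  dts <- as.Date("2015-01-01") + seq_len(nd) - 1
  ra <- epe_matrix(a, ids, dts, "ref", def)
  rb <- epe_matrix(b, ids, dts, "cmp", def)
  sub <- ids[1:5]
  out2 <- confusion_counts(ra, rb, sub)
  fp <- fn <- 0
  for (u in 1:5) {
    for (d in 1:nd) {
      if (is.na(a[u, d]) || is.na(b[u, d])) next
      if (b[u, d] == 1 && a[u, d] == 0) fp <- fp + 1
      if (b[u, d] == 0 && a[u, d] == 1) fn <- fn + 1
    }
  }
  expect_equal(out2$false_positives, fp)
  expect_equal(out2$false_negatives, fn)
  expect_equal(out2$fp_per_tract, fp / 5)
  expect_match(attr(out2, "disclaimer"), "no claim")

  expect_error(confusion_counts(ra, rb, character()), "non-empty")
})
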