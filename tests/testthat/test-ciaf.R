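# CIAF classification and zone aggregation

test_that("the eight failure combinations map to their categories", {
  # (wasting, stunting, underweight) -> code; flag = any failure
  cases <- list(
    list(z = c(haz = -1.0, waz = -1.0, whz = -1.0), code = "A", flag = 0),
    list(z = c(haz = -1.0, waz = -1.0, whz = -2.5), code = "B", flag = 1),
    list(z = c(haz = -1.0, waz = -2.5, whz = -2.5), code = "C", flag = 1),
    list(z = c(haz = -2.1, waz = -2.2, whz = -2.5), code = "D", flag = 1),
    list(z = c(haz = -2.5, waz = -2.5, whz = -1.0), code = "E", flag = 1),
    list(z = c(haz = -2.5, waz = -1.0, whz = -1.0), code = "F", flag = 1),
    list(z = c(haz = -1.0, waz = -2.5, whz = -1.0), code = "Y", flag = 1),
    list(z = c(haz = -2.5, waz = -1.0, whz = -2.5), code = "X", flag = 1)
  )
  for (cs in cases) {
    got <- classify_child(cs$z[["haz"]], cs$z[["waz"]], cs$z[["whz"]])
    expect_identical(got$code, cs$code)
    expect_identical(got$ciaf_flag, as.integer(cs$flag))
  }
})

test_that("the boundary is strict: z exactly at the cutoff is not a failure", {
  got <- classify_child(-2, -2, -2)
  expect_identical(got$code, "A")
  expect_identical(got$ciaf_flag, 0L)
})

test_that("classification rejects non-finite input and warns on implausible z", {
  expect_error(classify_child(NA, -1, -1), "haz")
  expect_error(classify_child(-1, Inf, -1), "waz")
  expect_warning(classify_child(-7, -1, -1), "implausible")
  expect_error(classify_child(-1, -1, -1, cutoff = 2), "cutoff")
})

test_that("lowering any single z-score never clears the failure flag", {
  grid <- seq(-4, 2, length.out = 10)
  deltas <- c(0.5, 1.5)
  for (h in grid) for (wz in grid) for (wh in grid) {
    base <- classify_child(h, wz, wh)$ciaf_flag
    for (d in deltas) {
      expect_gte(classify_child(h - d, wz, wh)$ciaf_flag, base)
      expect_gte(classify_child(h, wz - d, wh)$ciaf_flag, base)
      expect_gte(classify_child(h, wz, wh - d)$ciaf_flag, base)
    }
  }
})

test_that("classify_children performs listwise deletion and hard exclusion", {
  df <- data.frame(
    child_id = sprintf("c%d", 1:5), zone_id = "Z1",
    haz = c(-1, NA, -1, -11, -3),
    waz = c(-1, -1, -1, -1, -2.5),
    whz = c(-1, -1, NaN, -1, -1)
  )
  cls <- classify_children(df)
  expect_equal(nrow(cls), 2)
  expect_equal(unname(attr(cls, "exclusions")), c(2, 1))
  expect_identical(cls$code, c("A", "E"))
})

test_that("zone aggregation counts, conserves and orders deterministically", {
  df <- data.frame(
    child_id = sprintf("c%d", 1:6),
    zone_id = c("Z2", "Z1", "Z1", "Z1", "Z1", "Z2"),
    haz = c(-1, -2.5, -1, -2.6, -2.2, -1),
    waz = c(-1, -2.5, -1, -2.4, -2.1, -1),
    whz = c(-1, -2.5, -1, -1.0, -2.3, -1)
  )
  cls <- classify_children(df)
  zt <- suppressWarnings(aggregate_zones(cls))
  expect_identical(zt$zone_id, c("Z1", "Z2"))
  expect_equal(zt$n, c(4L, 2L))
  expect_equal(zt$y, c(3L, 0L))
  expect_equal(zt$prevalence, c(0.75, 0))
  expect_warning(aggregate_zones(cls), "fewer than")
  expect_error(aggregate_zones(cls[0, ]), "no analyzable")
})

test_that("prevalence from classify-aggregate matches an independent count", {
  set.seed(31)
  n <- 600
  df <- data.frame(
    child_id = sprintf("c%d", 1:n),
    zone_id = sample(sprintf("Z%d", 1:6), n, replace = TRUE),
    haz = rnorm(n, -1), waz = rnorm(n, -1), whz = rnorm(n, -1)
  )
  cls <- classify_children(df)
  zt <- aggregate_zones(cls)
  flag <- with(cls, (haz < -2) | (waz < -2) | (whz < -2))
  ind <- tapply(flag, cls$zone_id, mean)
  expect_equal(zt$prevalence, as.numeric(ind[zt$zone_id]))
  expect_equal(sum(zt$n), n)
})

test_that("expected counts follow the common-rate rule and conserve totals", {
  zt <- data.frame(zone_id = c("a", "b"), n = c(100L, 200L), y = c(10L, 20L))
  zt <- expected_counts(zt)
  expect_equal(zt$E, c(10, 20))
  zt2 <- data.frame(zone_id = c("a", "b"), n = c(100L, 500L), y = c(250L, 50L))
  zt2 <- expected_counts(zt2)
  expect_equal(zt2$E[1], 100 * 300 / 600)
  expect_equal(sum(zt2$E), sum(zt2$y), tolerance = 1e-12)
})

test_that("crude relative risk has E-weighted mean one and guards zero E", {
  zt <- data.frame(zone_id = c("a", "b"), n = c(100L, 100L), y = c(30L, 10L))
  zt <- crude_relative_risk(expected_counts(zt))
  expect_equal(zt$rr, c(1.5, 0.5))
  expect_equal(sum(zt$rr * zt$E) / sum(zt$E), 1, tolerance = 1e-12)
  z0 <- data.frame(zone_id = c("a", "b"), n = c(10L, 10L), y = c(0L, 0L))
  expect_error(crude_relative_risk(expected_counts(z0)), "zone")
})

test_that("child files round-trip through the delimited-text interface", {
  df <- data.frame(child_id = c("c1", "c2"), zone_id = c("Z1", "Z2"),
                   haz = c(-1.5, -2.5), waz = c(-0.5, -2.1),
                   whz = c(0.25, -2.25))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  back <- read_children(path)
  expect_equal(back$haz, df$haz)
  expect_identical(back$zone_id, df$zone_id)
})
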