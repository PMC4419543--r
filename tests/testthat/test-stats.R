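# Brute-force balanced two-way ANOVA decomposition via cell/marginal means.
twoway_oracle <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  al <- unique(A); bl <- unique(B)
  n <- sum(A == al[1] & B == bl[1])
  g <- mean(y)
  mA <- sapply(al, function(a) mean(y[A == a]))
  mB <- sapply(bl, function(b) mean(y[B == b]))
  mAB <- outer(al, bl, Vectorize(function(a, b) mean(y[A == a & B == b])))
  ss_a <- length(bl) * n * sum((mA - g)^2)
  ss_b <- length(al) * n * sum((mB - g)^2)
  ss_ab <- n * sum((mAB - outer(mA - g, mB - g, `+`) - g)^2)
  ss_e <- 0
  for (i in seq_along(al)) for (j in seq_along(bl)) {
    yy <- y[A == al[i] & B == bl[j]]
    ss_e <- ss_e + sum((yy - mAB[i, j])^2)
  }
  df_e <- length(y) - length(al) * length(bl)
  list(ss = c(ss_a, ss_b, ss_ab, ss_e),
       f = c(ss_a / (length(al) - 1), ss_b / (length(bl) - 1),
             ss_ab / ((length(al) - 1) * (length(bl) - 1))) / (ss_e / df_e))
}

test_that("per-condition summaries compute the thickness-error formula", {
  ref <- data.frame(tissue = c("a", "a", "b"),
                    step_size = c(200, 400, 300),
                    speed = c(0.1, 0.2, 0.2),
                    mean_um = c(460.4, 533.5, 300),
                    sd_um = 1)
  recs <- records_with_exact_means(ref)
  combos <- summarize_combos(recs)
  expect_equal(combos$error_pct[combos$step_size == 200], 130.2)
  expect_equal(combos$error_pct[combos$step_size == 400], 33.375)
  expect_equal(combos$error_pct[combos$step_size == 300], 0)
  expect_equal(combos$n, rep(2L, 3))
  expect_equal(combos$mean_um[combos$step_size == 200], 460.4)

  expect_error(summarize_combos(data.frame()), "non-empty")
})

test_that("the error percentage is invariant to a consistent unit change", {
  recs <- data.frame(tissue = "t", step_size = 200, speed = 0.1,
                     thickness = c(420, 480))
  recs_mm <- transform(recs, step_size = step_size / 1000,
                       thickness = thickness / 1000)
  expect_equal(summarize_combos(recs)$error_pct,
               summarize_combos(recs_mm)$error_pct)
})

test_that("overall errors average condition errors at full precision", {
  one <- data.frame(tissue = "t", error_pct = 42)
  expect_equal(overall_error(one)$overall_error_pct, 42)

  ref <- reference_measurements()
  liver <- ref[ref$tissue == "liver" & !is.na(ref$printed_error_pct), ]
  # brute-force sum / 6 of the printed per-condition errors
  s <- 0
  for (v in liver$printed_error_pct) s <- s + v
  expect_equal(s / 6, 100.8875)
  ov <- overall_error(data.frame(tissue = "liver",
                                 error_pct = liver$printed_error_pct))
  expect_equal(ov$overall_error_pct, 100.8875, tolerance = 1e-12)
  # full precision disagrees with the printed rounded overall
  expect_true(flag_rounding_mismatch(ov$overall_error_pct, 100.8, digits = 1))
  # the PFA overall rounds cleanly to its printed value
  pfa <- ref[ref$tissue == "pfa_brain", ]
  ov_pfa <- mean(pfa$printed_error_pct)
  expect_false(flag_rounding_mismatch(ov_pfa, 38.8, digits = 1))

  expect_error(overall_error(data.frame(tissue = "t", error_pct = NA_real_)),
               "no conditions")
})

test_that("balanced two-way ANOVA matches the closed-form oracle", {
  set.seed(61)
  recs <- data.frame(
    tissue = "t",
    step_size = rep(c(100, 200), each = 6),
    speed = rep(rep(c(0.1, 0.2), each = 3), 2),
    thickness = rnorm(12, mean = 300, sd = 40)
  )
  out <- thickness_anova(recs)
  orc <- twoway_oracle(recs$thickness, recs$step_size, recs$speed)
  expect_equal(out$sumsq, c(orc$ss), tolerance = 1e-10)
  expect_equal(out$statistic[1:3], orc$f, tolerance = 1e-10)
  expect_equal(out$term, c("step_size", "speed", "step_size:speed",
                           "Residuals"))
  expect_equal(out$df, c(1, 1, 1, 8))
  expect_true(all(out$p_value[1:3] >= 0 & out$p_value[1:3] <= 1))
})

test_that("balanced sums of squares decompose the total exactly", {
  set.seed(62)
  recs <- data.frame(
    tissue = "t",
    step_size = rep(c(100, 200, 400), each = 8),
    speed = rep(rep(c(0.05, 0.2), each = 4), 3),
    thickness = rnorm(24, 400, 60)
  )
  out <- thickness_anova(recs)
  ss_total <- sum((recs$thickness - mean(recs$thickness))^2)
  expect_equal(sum(out$sumsq), ss_total, tolerance = 1e-10)
})

test_that("a shifted cell produces an overwhelming effect", {
  set.seed(63)
  recs <- data.frame(
    tissue = "t",
    step_size = rep(c(100, 200), each = 8),
    speed = rep(rep(c(0.1, 0.2), each = 4), 2),
    thickness = rnorm(16, 300, 10)
  )
  shift <- recs$step_size == 200 & recs$speed == 0.2
  recs$thickness[shift] <- recs$thickness[shift] + 100   # +10 SD
  out <- thickness_anova(recs)
  expect_lt(min(out$p_value, na.rm = TRUE), 1e-6)
})

test_that("one-way ANOVA agrees with the pooled t test and handles flat data", {
  set.seed(64)
  recs <- data.frame(tissue = "t", step_size = rep(c(100, 200), each = 6),
                     speed = 0.2, thickness = rnorm(12, 300, 30))
  out <- thickness_anova(recs, factors = "step_size")
  tt <- t.test(thickness ~ step_size, data = recs, var.equal = TRUE)
  expect_equal(out$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p_value[1], tt$p.value, tolerance = 1e-10)

  flat <- data.frame(tissue = "t", step_size = rep(c(100, 200, 400), each = 3),
                     speed = 0.2, thickness = rep(c(1, 2, 3), 3))
  outf <- thickness_anova(flat, factors = "step_size")
  expect_equal(outf$sumsq[1], 0)
  expect_equal(outf$statistic[1], 0)
})

test_that("one-way SS decomposition matches brute force at k = 3, n = 6", {
  set.seed(65)
  recs <- data.frame(tissue = "t", step_size = rep(c(100, 200, 400), each = 6),
                     speed = 0.2, thickness = rnorm(18, 350, 50))
  out <- thickness_anova(recs, factors = "step_size")
  g <- mean(recs$thickness)
  ss_b <- 0; ss_w <- 0
  for (lev in unique(recs$step_size)) {
    yy <- recs$thickness[recs$step_size == lev]
    ss_b <- ss_b + length(yy) * (mean(yy) - g)^2
    ss_w <- ss_w + sum((yy - mean(yy))^2)
  }
  expect_equal(out$sumsq, c(ss_b, ss_w), tolerance = 1e-10)
})

test_that("ANOVA input contracts are enforced", {
  recs <- data.frame(tissue = "t", step_size = c(100, 100, 200, 200),
                     speed = c(0.1, 0.2, 0.1, 0.2),
                     thickness = c(100, 110, 200, 210))
  expect_error(thickness_anova(recs, c("step_size", "speed")),
               "single record")
  expect_s3_class(thickness_anova(recs, c("step_size", "speed"),
                                  interaction = FALSE), "data.frame")
  one_level <- data.frame(tissue = "t", step_size = 100, speed = c(0.1, 0.2),
                          thickness = c(100, 110))
  expect_error(thickness_anova(one_level, "step_size"), "fewer than 2 levels")
})

test_that("unbalanced designs go through Type-II sums of squares", {
  set.seed(66)
  recs <- data.frame(
    tissue = "t",
    step_size = rep(c(100, 200), each = 8),
    speed = rep(rep(c(0.1, 0.2), each = 4), 2),
    thickness = rnorm(16, 300, 30)
  )
  recs <- recs[-1, ]                        # unbalance one cell
  out <- thickness_anova(recs)
  expect_equal(out$term[1:3], c("step_size", "speed", "step_size:speed"))
  expect_true(all(out$sumsq >= 0))
  expect_true(all(out$df[1:3] == 1))
})

test_that("Tukey groupings separate distant groups and merge identical ones", {
  set.seed(67)
  recs <- data.frame(tissue = "t", step_size = rep(c(100, 200, 400), each = 6),
                     speed = 0.2,
                     thickness = rnorm(18, sd = 5) +
                       rep(c(100, 200, 300), each = 6))  # gaps 20x SD
  tg <- tukey_grouping(recs, "step_size")
  expect_equal(sort(tg$groups$letters), c("a", "b", "c"))

  same <- data.frame(tissue = "t", step_size = rep(c(100, 200, 400), each = 6),
                     speed = 0.2, thickness = rep(c(300, 310, 320, 290,
                                                    305, 315), 3))
  tg2 <- tukey_grouping(same, "step_size")
  expect_equal(tg2$groups$letters, c("a", "a", "a"))

  expect_error(tukey_grouping(data.frame(tissue = "t", step_size = 100,
                                         speed = 0.2,
                                         thickness = c(1, 2, 3)),
                              "step_size"), "2 groups")
})

test_that("letters encode exactly the thresholded significance relation", {
  # constructed matrix: only pair (1,2) non-significant
  p <- matrix(0.01, 3, 3); p[1, 2] <- p[2, 1] <- 0.6; diag(p) <- 1
  dimnames(p) <- list(c("x", "y", "z"), c("x", "y", "z"))
  lets <- letter_display(p, alpha = 0.05)
  sh <- share_from_letters(lets)
  expect_true(sh[1, 2])
  expect_false(sh[1, 3])
  expect_false(sh[2, 3])

  set.seed(68)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    pm <- random_pmat(k)
    alpha <- runif(1, 0.02, 0.5)
    lets <- letter_display(pm, alpha = alpha)
    expect_identical(share_from_letters(lets),
                     unname(pm >= alpha | diag(k) == 1))
  }
})
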