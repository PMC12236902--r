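make_events <- function(t_align, animal = "m1", kind = "void") {
  n <- length(t_align)
  data.frame(event_id = if (n) sprintf("%s_e%02d", animal, seq_len(n))
                         else character(0),
             animal_id = rep(animal, n), kind = rep(kind, n),
             t_align_s = t_align,
             t_start_s = t_align - 5, t_end_s = t_align + 5,
             included = rep(TRUE, n), exclusion_reason = rep("", n),
             stringsAsFactors = FALSE)
}

test_that("peri-event rows equal direct per-event recomputation", {
  set.seed(7)
  d <- flat_dff(rnorm(3000, mean = 0.05, sd = 0.01))  # 300 s at 10 Hz
  ev <- make_events(c(80, 150, 220))
  pem <- build_matrix(d, ev, "percent")
  expect_identical(nrow(pem$values), 3L)
  expect_identical(ncol(pem$values), 1201L)
  for (i in 1:3) {
    oracle <- normalize_per_event(d, ev$t_align_s[i])
    expect_equal(pem$values[i, ], oracle$values, tolerance = 1e-12)
  }
  # single event on a flat trace -> all-zero row
  dz <- flat_dff(rep(0.5, 3000))
  expect_true(all(build_matrix(dz, make_events(150), "percent")$values == 0))
  # event too close to the trace edge is dropped with a reason
  pem2 <- build_matrix(d, make_events(c(30, 150)), "percent")
  expect_identical(nrow(pem2$values), 1L)
  expect_identical(pem2$dropped$reason, "window_out_of_bounds")
  # no usable events -> empty matrix, not an exception
  pem3 <- build_matrix(d, make_events(numeric(0)), "percent")
  expect_identical(nrow(pem3$values), 0L)
  # row order: by animal then time
  ev_mix <- rbind(make_events(c(220, 80), "m2"), make_events(150, "m1"))
  pm <- build_matrix(d, ev_mix, "raw")
  expect_identical(pm$rows$animal_id, c("m1", "m2", "m2"))
  expect_identical(pm$rows$t_align_s, c(150, 80, 220))
})

test_that("shuffle null is deterministic, in-bounds and zone-respecting", {
  set.seed(8)
  d <- flat_dff(rnorm(6000, 0, 0.01))
  expect_identical(nrow(shuffle_null(d, 0, seed = 1)$values), 0L)
  s1 <- shuffle_null(d, 12, seed = 5)
  s2 <- shuffle_null(d, 12, seed = 5)
  expect_identical(s1$rows$t_align_s, s2$rows$t_align_s)
  expect_identical(s1$values, s2$values)
  expect_true(all(s1$rows$t_align_s >= 60 & s1$rows$t_align_s <= 540))
  # exclusion zones respected
  zones <- rbind(c(100, 300), c(350, 500))
  s3 <- shuffle_null(d, 15, seed = 6, exclusion_zones = zones)
  expect_false(any(s3$rows$t_align_s >= 100 & s3$rows$t_align_s <= 300))
  expect_false(any(s3$rows$t_align_s >= 350 & s3$rows$t_align_s <= 500))
  # infeasible placement errors
  expect_error(shuffle_null(d, 5, seed = 7,
                            exclusion_zones = rbind(c(0, 600))),
               "infeasible")
})

test_that("average_trace matches column loops and SEM scaling", {
  set.seed(9)
  d <- flat_dff(rnorm(3000, 0.05, 0.01))
  ev <- make_events(c(70, 110, 150, 190, 230))
  pem <- build_matrix(d, ev, "raw")
  av <- average_trace(pem)
  for (j in c(1, 600, 1201)) {
    expect_equal(av$mean[j], mean(pem$values[, j]), tolerance = 1e-12)
    expect_equal(av$sem[j], sd(pem$values[, j]) / sqrt(5), tolerance = 1e-12)
  }
  # duplicating every row leaves the mean unchanged and scales the SEM by
  # ~1/sqrt(2); with the sample-sd convention the exact factor at n rows is
  # sqrt((n-1)/(2n-1))
  pem2 <- pem
  pem2$values <- rbind(pem$values, pem$values)
  pem2$rows <- rbind(pem$rows, pem$rows)
  av2 <- average_trace(pem2)
  expect_equal(av2$mean, av$mean, tolerance = 1e-12)
  expect_equal(av2$sem, av$sem * sqrt((5 - 1) / (2 * 5 - 1)),
               tolerance = 1e-9)
  # one-row matrix: mean equals the row, SEM flagged as NA
  av1 <- average_trace(build_matrix(d, make_events(100), "raw"))
  expect_true(all(is.na(av1$sem)))
  expect_identical(av1$n, 1L)
})

test_that("per-animal subsampling is equally weighted and seeded", {
  set.seed(10)
  d <- flat_dff(rnorm(20000, 0.05, 0.01))  # 2000 s at 10 Hz
  evs <- do.call(rbind, lapply(1:4, function(a)
    make_events(seq(100, 1900, length.out = 12), sprintf("m%d", a))))
  pem <- build_matrix(d, evs, "raw")
  s <- per_animal_summary(pem, n_per_animal = 10, seed = 3)
  expect_identical(nrow(s), 40L)  # 4 animals x 10 events, equally weighted
  expect_true(all(table(s$animal_id) == 10))
  # deterministic given seed
  expect_identical(per_animal_summary(pem, 10, seed = 3), s)
  # n_per_animal = all rows -> no subsampling
  sall <- per_animal_summary(pem, 12, seed = 99)
  expect_identical(nrow(sall), 48L)
  # the statistic is the mean over the stat window
  sel <- pem$lag_s >= 0 & pem$lag_s <= 10
  i <- match(sall$event_id[1], pem$rows$event_id)
  expect_equal(sall$value[1], mean(pem$values[i, sel]), tolerance = 1e-12)
  # an animal with too few rows is named in the error
  expect_error(per_animal_summary(pem, 13, seed = 1), "m1")
})

test_that("group comparison behaves at the null and under separation", {
  set.seed(11)
  x <- rnorm(32)
  # identical groups: omnibus and pairwise p near 1-ish, no rejections
  res <- compare_groups(x, x, x)
  expect_gt(res$omnibus$p, 0.9)
  expect_true(all(res$pairwise$p_adj > 0.9))
  expect_identical(res$omnibus$method, "Kruskal-Wallis")
  expect_identical(nrow(res$pairwise), 3L)
  # clearly separated void group is detected
  res2 <- compare_groups(x + 5, x, x - 1)
  expect_lt(res2$omnibus$p, 1e-6)
  vd <- res2$pairwise[res2$pairwise$group1 == "void" &
                        res2$pairwise$group2 == "shuffle", ]
  expect_lt(vd$p_adj, 1e-4)
  # two-group fallback is a Mann-Whitney test
  res3 <- compare_groups(x + 5, NULL, x)
  expect_identical(res3$omnibus$method, "Mann-Whitney")
  expect_lt(res3$omnibus$p, 1e-6)
  expect_error(compare_groups(numeric(0), x, x), "empty")
})
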