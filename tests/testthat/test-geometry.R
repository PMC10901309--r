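test_that("midpoint is the componentwise mean", {
  expect_equal(midpoint(c(0, 0), c(1, 1)), c(x = 0.5, y = 0.5))
  expect_equal(midpoint(c(0.4, 0.4), c(0.4, 0.4)), c(x = 0.4, y = 0.4))
  set.seed(21)
  for (i in 1:20) {
    p <- rnorm(2); q <- rnorm(2)
    expect_equal(unname(midpoint(p, q)), colMeans(rbind(p, q)))
  }
  expect_error(midpoint(c(NA, 0), c(1, 1)),
               class = "mtmpose_invalid_coordinate_error")
})

make_frame_with_trunk <- function(lm11, lm12, lm23, lm24) {
  f <- template_pose()
  f[11 + 1, ] <- lm11; f[12 + 1, ] <- lm12
  f[23 + 1, ] <- lm23; f[24 + 1, ] <- lm24
  f
}

test_that("midbody line passes through both midpoints in x = a*y + b form", {
  # vertical midline through x = 0.5
  f <- make_frame_with_trunk(c(0.6, 0.2), c(0.4, 0.2), c(0.6, 0.8), c(0.4, 0.8))
  ln <- midbody_line(f)
  expect_equal(ln$a, 0)
  expect_equal(ln$b, 0.5)
  # oblique: midpoints (0.4, 0.2) and (0.6, 0.8) -> a = 1/3, b = 1/3
  f <- make_frame_with_trunk(c(0.5, 0.2), c(0.3, 0.2), c(0.7, 0.8), c(0.5, 0.8))
  ln <- midbody_line(f)
  expect_equal(ln$a, 1 / 3)
  expect_equal(ln$b, 0.4 - (1 / 3) * 0.2)
  # both midpoints satisfy x = a*y + b
  set.seed(22)
  for (i in 1:50) {
    f <- random_frame()
    ln <- midbody_line(f)
    expect_lt(abs(ln$a * ln$shoulder_mid[["y"]] + ln$b - ln$shoulder_mid[["x"]]),
              1e-9)
    expect_lt(abs(ln$a * ln$hip_mid[["y"]] + ln$b - ln$hip_mid[["x"]]), 1e-9)
  }
  # horizontal body axis is degenerate
  f <- make_frame_with_trunk(c(0.4, 0.5), c(0.4, 0.5), c(0.6, 0.5), c(0.6, 0.5))
  expect_error(midbody_line(f), class = "mtmpose_degeneracy_error")
})

test_that("signed distance is the horizontal offset at the landmark's y", {
  f <- make_frame_with_trunk(c(0.6, 0.2), c(0.4, 0.2), c(0.6, 0.8), c(0.4, 0.8))
  ln <- midbody_line(f)  # x = 0.5
  expect_equal(signed_distance(c(0.3, 0.6), ln), 0.2)
  expect_equal(signed_distance(c(0.5, 0.9), ln), 0)
  # reflecting in x at fixed y flips the sign with equal magnitude
  set.seed(23)
  for (i in 1:50) {
    f <- random_frame()
    ln <- midbody_line(f)
    p <- rnorm(2, 0.5, 0.2)
    d <- signed_distance(p, ln)
    x_line <- ln$a * p[2] + ln$b
    p_ref <- c(2 * x_line - p[1], p[2])
    expect_equal(signed_distance(p_ref, ln), -d, tolerance = 1e-12)
  }
})

test_that("body length averages the two shoulder-hip distances", {
  f <- make_frame_with_trunk(c(0.4, 0.3), c(0.6, 0.3), c(0.4, 0.7), c(0.6, 0.7))
  expect_equal(body_length(f), 0.4)
  set.seed(24)
  for (i in 1:20) {
    f <- random_frame()
    oracle <- (sqrt(sum((f[12, ] - f[24, ])^2)) +
                 sqrt(sum((f[13, ] - f[25, ])^2))) / 2
    expect_equal(body_length(f), oracle)
  }
  f <- make_frame_with_trunk(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  expect_error(body_length(f), class = "mtmpose_degenerate_body_error")
})

test_that("body centre is the mean of all 33 landmarks", {
  f <- matrix(0.5, 33, 2)
  expect_equal(body_center(f), c(x = 0.5, y = 0.5))
  # symmetric cloud about (0.5, 0.5): 32 mirrored points + the centre itself
  set.seed(25)
  pts <- matrix(rnorm(32, 0.5, 0.1), 16, 2)
  f <- rbind(pts, 1 - pts, c(0.5, 0.5))
  expect_equal(body_center(f), c(x = 0.5, y = 0.5))
  f <- random_frame()
  expect_equal(unname(body_center(f)), unname(colMeans(f)))
  f[5, 1] <- NA
  expect_error(body_center(f), class = "mtmpose_invalid_frame_error")
})

test_that("shoelace quadrilateral area matches the triangulation oracle", {
  expect_equal(quad_area(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), 1)
  expect_equal(quad_area(c(0, 0), c(1, 1), c(2, 2), c(3, 3)), 0)
  set.seed(26)
  for (i in 1:1000) {
    P <- random_convex_quad()
    a <- quad_area(P[1, ], P[2, ], P[3, ], P[4, ])
    oracle <- tri_area(P[1, ], P[2, ], P[3, ]) +
      tri_area(P[1, ], P[3, ], P[4, ])
    expect_equal(a, oracle, tolerance = 1e-12)
  }
})

test_that("triangle area matches the rotate-to-axis-aligned-base oracle", {
  expect_equal(tri_area(c(0, 0), c(1, 0), c(0, 1)), 0.5)
  expect_equal(tri_area(c(0, 0), c(1, 1), c(2, 2)), 0)
  set.seed(27)
  for (i in 1:1000) {
    p <- rnorm(2); q <- rnorm(2); r <- rnorm(2)
    base <- sqrt(sum((q - p)^2))
    th <- atan2(q[2] - p[2], q[1] - p[1])
    rot <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
    rp <- rot %*% (r - p)
    oracle <- 0.5 * base * abs(rp[2])
    expect_equal(tri_area(p, q, r), oracle, tolerance = 1e-9)
  }
})

test_that("frame features normalize distances by body length", {
  # vertical midline x = 0.5, body length 0.4, left wrist at x = 0.3
  f <- make_frame_with_trunk(c(0.6, 0.3), c(0.4, 0.3), c(0.6, 0.7), c(0.4, 0.7))
  f[15 + 1, ] <- c(0.3, 0.6)
  ff <- features_of_frame(f)
  expect_equal(ff$dlm15, (0.5 - 0.3) / 0.4)
  expect_true(ff$valid)
})

test_that("uniform scaling leaves normalized distances unchanged and scales areas by exponent", {
  set.seed(28)
  for (i in 1:25) {
    f <- random_frame()
    f2 <- f * 2  # uniform scaling about the origin
    a1 <- features_of_frame(f, feature_config(area_norm_exponent = 1))
    a2 <- features_of_frame(f2, feature_config(area_norm_exponent = 1))
    b1 <- features_of_frame(f, feature_config(area_norm_exponent = 2))
    b2 <- features_of_frame(f2, feature_config(area_norm_exponent = 2))
    for (d in c("dlm15", "dlm16", "dlm27", "dlm28")) {
      expect_equal(a2[[d]], a1[[d]], tolerance = 1e-9)
    }
    for (ar in c("area_whole", "area_upper", "area_lower")) {
      expect_equal(a2[[ar]], 2 * a1[[ar]], tolerance = 1e-9)
      expect_equal(b2[[ar]], b1[[ar]], tolerance = 1e-9)
    }
  }
})

test_that("degenerate frames are flagged invalid instead of raising", {
  f <- template_pose(orientation = pi / 2)  # body axis horizontal
  ff <- features_of_frame(f)
  expect_false(ff$valid)
  expect_false(ff$valid_distance)
  expect_true(is.na(ff$dlm15))
})

test_that("video summaries are brute-force means of per-frame features", {
  set.seed(29)
  frames <- replicate(100, random_frame(), simplify = FALSE)
  s <- series_from_frames(frames, video_id = "avg")
  sm <- summarize_video(s)
  per_frame <- do.call(rbind, lapply(frames, features_of_frame))
  expect_equal(sm$mean_dlm15, mean(per_frame$dlm15))
  expect_equal(sm$mean_dlm28, mean(per_frame$dlm28))
  expect_equal(sm$mean_area_whole, mean(per_frame$area_whole))
  expect_equal(sm$mean_area_lower, mean(per_frame$area_lower))
  expect_equal(sm$n_valid_frames, 100L)
  # identical frames: means equal the single frame's features
  f <- random_frame()
  sm1 <- summarize_video(series_from_frames(list(f, f, f)))
  expect_equal(sm1$mean_dlm16, features_of_frame(f)$dlm16)
  # two known distances average
  expect_equal(mean(c(0.2, 0.4)), 0.3)
})

test_that("unusable videos are flagged when too many frames are invalid", {
  set.seed(30)
  good <- replicate(8, random_frame(), simplify = FALSE)
  bad <- lapply(1:2, function(i) {
    f <- random_frame(); f[15 + 1, 1] <- NA; f
  })
  s <- series_from_frames(c(good, bad))
  sm_lenient <- summarize_video(s, feature_config(max_invalid_fraction = 0.25))
  expect_true(sm_lenient$usable)
  sm_strict <- summarize_video(s, feature_config(max_invalid_fraction = 0.10))
  expect_false(sm_strict$usable)
  expect_equal(sm_strict$n_valid_frames, 8L)
  # all-invalid series refuses to summarize
  allbad <- lapply(1:3, function(i) {
    f <- random_frame(); f[11 + 1, 1] <- NA; f[1, 1] <- NA; f
  })
  expect_error(summarize_video(series_from_frames(allbad)),
               class = "mtmpose_no_data_error")
})
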