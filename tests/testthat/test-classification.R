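test_that("implausible stride lengths are rejected", {
  expect_true(reject_implausible(0.20))
  expect_false(reject_implausible(1.2))
  expect_true(reject_implausible(2.5))
  expect_true(reject_implausible(1.2, temporal_valid = FALSE))
})

test_that("stride-type thresholds require both height and inclination", {
  expect_equal(classify_stride(0.35, 33.4), "ascending")
  expect_equal(classify_stride(0.12, 4), "level")     # inclination fails
  expect_equal(classify_stride(-0.29, -22.5), "descending")
  expect_equal(classify_stride(0.08, 20), "level")    # height fails
  # thresholds are inclusive
  expect_equal(classify_stride(0.10, 6), "ascending")
  expect_equal(classify_stride(-0.10, -6), "descending")
})

test_that("ascending and descending are disjoint by construction", {
  set.seed(30)
  h <- stats::runif(500, -0.6, 0.6)
  inc <- stats::runif(500, -45, 45)
  cls <- classify_stride(h, inc)
  expect_false(any(cls == "ascending" & h < 0))
  expect_false(any(cls == "descending" & h > 0))
})

mk_strides <- function(types, t0 = 0, gap = 0.6, start_foot = "left") {
  n <- length(types)
  feet <- rep(c(start_foot, setdiff(c("left", "right"), start_foot)),
              length.out = n)
  data.frame(time_s = t0 + gap * (seq_len(n) - 1), foot = feet,
             stride_type = types, stride_time_s = rep(1.1, n),
             swing_time_s = rep(0.45, n), stance_time_s = rep(0.65, n))
}

test_that("bout assembly follows the stair-count and gap rules", {
  # five contiguous alternating ascending strides form one stair bout
  b <- assemble_bouts(mk_strides(rep("ascending", 5)))
  expect_equal(length(b), 1L)
  expect_equal(b[[1]]$activity, "ascending")
  expect_equal(nrow(b[[1]]$strides), 5L)

  # two descending strides in a level sequence are re-labelled level
  b2 <- assemble_bouts(mk_strides(c("level", "level", "descending",
                                    "descending", "level", "level"),
                                  start_foot = "right"))
  expect_equal(length(b2), 1L)
  expect_equal(b2[[1]]$activity, "level")
  expect_equal(nrow(b2[[1]]$strides), 6L)

  # empty input
  expect_equal(assemble_bouts(mk_strides(character(0))), list())

  # a brief level interruption does not split a stair run when merging
  s <- mk_strides(c("ascending", "ascending", "ascending", "level", "level",
                    "ascending", "ascending"))
  b3 <- assemble_bouts(s, merge_interrupted = TRUE)
  acts <- vapply(b3, function(b) b$activity, character(1))
  expect_true("ascending" %in% acts)
  asc <- b3[[which(acts == "ascending")]]
  expect_equal(nrow(asc$strides), 5L)
  # without merging, the split runs fall below the 5-stride minimum
  b4 <- assemble_bouts(s, merge_interrupted = FALSE)
  expect_false("ascending" %in% vapply(b4, function(b) b$activity,
                                       character(1)))

  # gaps beyond 2.5 s split candidate bouts
  s5 <- rbind(mk_strides(rep("ascending", 3)),
              mk_strides(rep("ascending", 3), t0 = 10, start_foot = "right"))
  b5 <- assemble_bouts(s5)
  expect_false("ascending" %in% vapply(b5, function(b) b$activity,
                                       character(1)))

  # overlapping strides from one foot violate the input contract
  bad <- mk_strides(rep("level", 4))
  bad$time_s[3] <- bad$time_s[1]
  expect_error(assemble_bouts(bad), "overlapping")
})

test_that("rejected strides never enter a bout", {
  s <- mk_strides(rep("level", 6))
  s$stride_type[3] <- "rejected"
  b <- assemble_bouts(s)
  members <- unlist(lapply(b, function(bout) bout$strides$stride_type))
  expect_false("rejected" %in% members)
  # removing a stride breaks the alternating-feet pattern here, so no
  # valid level bout remains either
  expect_equal(length(b), 0L)
})

test_that("DMO summaries pool member strides per activity", {
  s <- mk_strides(rep("level", 4))
  s$stride_time_s <- c(1.0, 1.2, 1.0, 1.2)
  b <- assemble_bouts(s)
  d <- compute_dmos(b)
  expect_equal(d$stride_time_mean_s, 1.1)
  expect_equal(d$n_strides, 4L)
  # population SD: single value twice -> sd of {1.0,1.2} with divisor n
  expect_equal(d$stride_time_sd_s, 0.1)
  # an activity with no strides is omitted with a notice
  expect_message(compute_dmos(b), "ascending")
})

test_that("noise-free staircase geometries classify 100% correctly", {
  geo <- staircase_geometries()
  for (i in seq_len(nrow(geo))) {
    for (steps in c(1, 2)) {
      h <- steps * geo$rise_m[i]
      l <- steps * geo$run_m[i]
      inc <- stride_inclination(h, l)
      expect_equal(classify_stride(h, inc), "ascending")
      expect_equal(classify_stride(-h, -inc), "descending")
    }
  }
  expect_equal(classify_stride(0, 0), "level")
})
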