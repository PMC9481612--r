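particle <- function(x, y, ox = 0, oy = 0, psi = 0, class = 1L) {
  list(coordinate_x = x, coordinate_y = y, origin_x = ox, origin_y = oy,
       angle_psi = psi, class_id = class)
}

test_that("zero offset reduces to origin subtraction for any psi", {
  p <- particle(1000, 2000, ox = 10, oy = -5, psi = 37)
  expect_equal(recenter_particle(p, class_offset(1, 0, 0)),
               c(x_new = 990, y_new = 2005))
  for (psi in c(-180, -90, 0, 33.3, 90, 179.9)) {
    p$angle_psi <- psi
    expect_equal(unname(recenter_particle(p, class_offset(1, 0, 0))),
                 c(990, 2005))
  }
})

test_that("psi = 0 gives a pure translation and psi = 90 a quarter turn", {
  p <- particle(1000, 2000)
  expect_equal(recenter_particle(p, class_offset(1, 50, 20)),
               c(x_new = 1050, y_new = 2020))
  p$angle_psi <- 90
  expect_equal(recenter_particle(p, class_offset(1, 50, 20)),
               c(x_new = 1020, y_new = 1950))
})

test_that("the transform matches an independent rotation-matrix oracle", {
  set.seed(11)
  for (i in 1:200) {
    psi <- runif(1, -180, 180)
    dx <- runif(1, -60, 60); dy <- runif(1, -60, 60)
    ox <- rnorm(1, 0, 5); oy <- rnorm(1, 0, 5)
    p <- particle(runif(1, 200, 3000), runif(1, 200, 3000), ox, oy, psi)
    got <- recenter_particle(p, class_offset(1, dx, dy))
    # oracle: rotate (dx, dy) by -psi about the origin (image raster frame,
    # y down), add to origin-subtracted coordinate
    a <- psi * pi / 180
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    off <- R %*% c(dx, dy)
    expect_equal(unname(got),
                 c(p$coordinate_x - ox + off[1], p$coordinate_y - oy + off[2]),
                 tolerance = 1e-12)
  }
})

test_that("rotation preserves offset distances (isometry)", {
  set.seed(12)
  for (i in 1:100) {
    p <- particle(runif(1, 100, 4000), runif(1, 100, 4000),
                  rnorm(1), rnorm(1), runif(1, -180, 180))
    o1 <- class_offset(1, runif(1, -50, 50), runif(1, -50, 50))
    o2 <- class_offset(1, runif(1, -50, 50), runif(1, -50, 50))
    r1 <- recenter_particle(p, o1)
    r2 <- recenter_particle(p, o2)
    expect_equal(sqrt(sum((r1 - r2)^2)),
                 sqrt((o1$dx - o2$dx)^2 + (o1$dy - o2$dy)^2),
                 tolerance = 1e-9)
  }
})

test_that("psi and psi + 360 agree to 1e-9 pixels", {
  set.seed(13)
  for (i in 1:50) {
    psi <- runif(1, -180, 180)
    p1 <- particle(1000, 1500, 2, -3, psi)
    p2 <- particle(1000, 1500, 2, -3, psi + 360)
    o <- class_offset(1, 40, -25)
    expect_equal(recenter_particle(p1, o), recenter_particle(p2, o),
                 tolerance = 1e-9)
  }
})

test_that("class mismatch is a contract error", {
  p <- particle(100, 100, class = 2L)
  expect_error(recenter_particle(p, class_offset(1, 5, 5)), "class")
})

test_that("the forward simulator's planted centers are recovered to 1e-6 px", {
  classes <- data.frame(class_id = 1:3, dx = c(30, -25, 12),
                        dy = c(-40, 15, 33))
  g <- gen_star(1000, classes, seed = 99)
  offs <- lapply(1:3, function(i)
    class_offset(classes$class_id[i], classes$dx[i], classes$dy[i]))
  r <- recenter_set(g$particles, offs)
  expect_equal(r$report$n_written, 1000L)
  err <- pmax(abs(r$particles$particles$coordinate_x - g$truth$center_x),
              abs(r$particles$particles$coordinate_y - g$truth$center_y))
  expect_lt(max(err), 1e-6)
  # alignment is consumed in the output
  expect_true(all(r$particles$particles$origin_x == 0))
  expect_true(all(r$particles$particles$angle_psi == 0))
})

test_that("classes without an offset are skipped and counted", {
  classes <- data.frame(class_id = 1:2, dx = c(30, -25), dy = c(-40, 15))
  g <- gen_star(300, classes, seed = 5)
  r <- recenter_set(g$particles, list(class_offset(1, 30, -40)))
  n_class2 <- sum(g$particles$particles$class_id == 2L)
  expect_equal(r$report$n_skipped_no_offset, n_class2)
  expect_equal(r$report$n_written, 300L - n_class2)
})

test_that("out-of-bounds new boxes are dropped, not clamped", {
  p <- data.frame(coordinate_x = c(37, 2000), coordinate_y = c(500, 500),
                  origin_x = c(0, 0), origin_y = c(0, 0),
                  angle_psi = c(0, 0), class_id = c(1L, 1L))
  ps <- particle_set(p)
  r <- recenter_set(ps, list(class_offset(1, -32, 0)),
                    micrograph_extent = c(4096, 4096), new_box = 64)
  # first particle recenters to x = 5; 5 - 32 < 0 so it is dropped
  expect_equal(r$report$n_dropped_out_of_bounds, 1L)
  expect_equal(r$report$n_written, 1L)
  expect_equal(r$particles$particles$coordinate_x, 1968)
})

test_that("report counts reconcile against a brute-force bound check", {
  classes <- data.frame(class_id = 1L, dx = 30, dy = -40)
  g <- gen_star(500, classes, micrograph_extent = c(1200, 1200),
                margin = 20, seed = 21)
  r <- recenter_set(g$particles, list(class_offset(1, 30, -40)),
                    micrograph_extent = c(1200, 1200), new_box = 128)
  # oracle: the new center is the planted center; check its box per particle
  inb <- g$truth$center_x - 64 >= 0 & g$truth$center_x + 64 <= 1200 &
         g$truth$center_y - 64 >= 0 & g$truth$center_y + 64 <= 1200
  expect_equal(r$report$n_written, sum(inb))
  expect_equal(r$report$n_dropped_out_of_bounds, sum(!inb))
  expect_equal(r$report$n_input,
               r$report$n_written + r$report$n_dropped_out_of_bounds +
                 r$report$n_skipped_no_offset)
})

test_that("duplicate class offsets are a config error", {
  classes <- data.frame(class_id = 1L, dx = 0, dy = 0)
  g <- gen_star(10, classes, seed = 1)
  expect_error(recenter_set(g$particles,
                            list(class_offset(1, 1, 1),
                                 class_offset(1, 2, 2))),
               "duplicate")
})

test_that("offsets files parse with comma or whitespace and optional label", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("class_id,dx,dy,label", "1, 30, -40, head", "2 -25 15"), f)
  offs <- read_offsets(f)
  expect_length(offs, 2L)
  expect_equal(offs[[1]]$dx, 30)
  expect_equal(offs[[1]]$label, "head")
  expect_equal(offs[[2]]$class_id, 2L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), empty)
  expect_equal(read_offsets(empty), list())

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1, 30, -40", "2, x, 15"), bad)
  expect_error(read_offsets(bad), "row 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1, 30, -40", "1, 2, 2"), dup)
  expect_error(read_offsets(dup), "duplicate")
})

test_that("an empty offsets list skips every particle", {
  classes <- data.frame(class_id = 1L, dx = 5, dy = 5)
  g <- gen_star(20, classes, seed = 2)
  r <- recenter_set(g$particles, list())
  expect_equal(r$report$n_skipped_no_offset, 20L)
  expect_equal(r$report$n_written, 0L)
})
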