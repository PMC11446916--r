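test_that("nuclear shape recovers area of simple geometries", {
  img <- matrix(0, 60, 60); img[21:40, 21:40] <- 200  # 20x20 px square
  p <- nuclear_shape(img, pixel_size_um = 0.5)
  expect_equal(p$area_um2, 100)

  # ellipse semi-axes 10 and 5 um at 0.25 um/px
  n <- 200
  img <- matrix(0, n, n)
  img[ellipse_mask_fx(n, 10 / 0.25, 5 / 0.25)] <- 200
  p <- nuclear_shape(img, pixel_size_um = 0.25)
  expect_equal(p$area_um2, pi * 10 * 5, tolerance = 0.02)

  img <- matrix(0, 100, 100); img[disk_mask(100, 30)] <- 200
  p <- nuclear_shape(img, pixel_size_um = 0.25)
  expect_gte(p$circularity, 0.9)
})

test_that("focal adhesion sizes average planted rectangles", {
  img <- matrix(10, 100, 100)
  # four 2x4 px rectangles at 0.5 um/px -> 2 um^2 each
  org <- list(c(10, 10), c(10, 60), c(60, 10), c(60, 60))
  for (o in org) img[o[1]:(o[1] + 1), o[2]:(o[2] + 3)] <- 200
  fa <- focal_adhesion_sizes(img, pixel_size_um = 0.5)
  expect_identical(fa$count, 4L)
  expect_equal(fa$mean_area_um2, 2)
})

test_that("a signal-free channel yields zero adhesions, not zero area", {
  fa <- focal_adhesion_sizes(matrix(0, 50, 50), pixel_size_um = 0.5)
  expect_identical(fa$count, 0L)
  expect_true(is.na(fa$mean_area_um2))
})

test_that("a focal adhesion size ladder is recovered in rank order", {
  mk <- function(w) {  # rectangles of w px^2 at 0.5 um/px -> w/4 um^2
    img <- matrix(10, 80, 80)
    for (o in list(c(10, 10), c(10, 50), c(50, 10))) {
      img[o[1]:(o[1] + 1), o[2]:(o[2] + w / 2 - 1)] <- 200
    }
    img
  }
  means <- vapply(c(4, 8, 16), function(w)
    focal_adhesion_sizes(mk(w), pixel_size_um = 0.5)$mean_area_um2, numeric(1))
  expect_equal(means, c(1, 2, 4))
  expect_true(all(diff(means) > 0))
})

test_that("MTOC distance is signed by the nucleus footprint", {
  px <- 0.5
  dapi <- matrix(0, 120, 120); dapi[disk_mask(120, 30, 60, 60)] <- 200
  # centrosome 10 px (5 um) beyond the border, to the right
  peri <- matrix(0, 120, 120); peri[disk_mask(120, 2, 60, 100)] <- 250
  res <- mtoc_nucleus_distance(peri, dapi, px)
  expect_equal(res$distance_um, 5, tolerance = px / 2 + 1e-9)

  # centrosome inside, ~2 um from the border
  peri2 <- matrix(0, 120, 120); peri2[disk_mask(120, 2, 60, 86)] <- 250
  res2 <- mtoc_nucleus_distance(peri2, dapi, px)
  expect_lt(res2$distance_um, 0)
  expect_equal(res2$distance_um, -2, tolerance = px / 2 + 1e-9)

  expect_null(mtoc_nucleus_distance(matrix(0, 120, 120) +
                                      matrix(rnorm(14400, 1, 0.01), 120, 120) * 0,
                                    dapi, px))
})

test_that("MTOC distance matches a brute-force border scan", {
  set.seed(19)
  for (i in 1:10) {
    n <- 80
    dapi <- matrix(0, n, n)
    r <- sample(12:20, 1)
    dapi[disk_mask(n, r, n / 2, n / 2)] <- 200
    cy <- runif(1, 10, n - 10); cx <- runif(1, 10, n - 10)
    peri <- matrix(0, n, n); peri[disk_mask(n, 1.5, cy, cx)] <- 250
    res <- mtoc_nucleus_distance(peri, dapi, 0.4)
    idx <- which(peri > 0)
    ccy <- mean(((idx - 1) %% n) + 1); ccx <- mean(((idx - 1) %/% n) + 1)
    expect_equal(res$distance_um, mtoc_brute(dapi > 0, ccy, ccx, 0.4),
                 tolerance = 1e-9)
  }
})

test_that("coherency hits its oriented, flat and isotropic limits", {
  n <- 96
  stripes <- matrix(sin(2 * pi * (1:n) / 8), n, n, byrow = TRUE)
  expect_gte(factin_coherency(stripes, pixel_size_um = 0.5), 0.99)
  expect_equal(factin_coherency(matrix(3, n, n), pixel_size_um = 0.5), 0)
  coh <- vapply(1:20, function(s) {
    set.seed(600 + s)
    factin_coherency(matrix(rnorm(64 * 64), 64, 64), pixel_size_um = 0.5)
  }, numeric(1))
  expect_lt(mean(coh), 0.2)
})

test_that("coherency is invariant to rotation and affine intensity maps", {
  set.seed(23)
  img <- EBImage::gblur(matrix(rnorm(64 * 64), 64, 64), 2)
  rot90 <- function(m) t(m)[, seq_len(nrow(m)), drop = FALSE][, nrow(m):1]
  c0 <- factin_coherency(img, pixel_size_um = 0.5)
  expect_equal(factin_coherency(rot90(img), pixel_size_um = 0.5), c0,
               tolerance = 1e-6)
  expect_equal(factin_coherency(3 * img + 7, pixel_size_um = 0.5), c0,
               tolerance = 1e-9)
})

test_that("spheroid metrics count invading nuclei and rank solidity", {
  body <- disk_mask(120, 40)
  inside <- data.frame(x = c(60, 70), y = c(60, 50))
  m <- spheroid_metrics(body, inside, 1)
  expect_identical(m$n_invading, 0L)
  expect_gte(m$solidity, 0.98)
  one_out <- rbind(inside, data.frame(x = 115, y = 115))
  expect_identical(spheroid_metrics(body, one_out, 1)$n_invading, 1L)

  star <- matrix(FALSE, 120, 120)
  star[55:65, 10:110] <- TRUE; star[10:110, 55:65] <- TRUE  # plus shape
  ms <- spheroid_metrics(star, inside[0, ], 1)
  expect_lt(ms$solidity, m$solidity)
  expect_error(spheroid_metrics(matrix(FALSE, 10, 10), inside, 1),
               class = "emdmn_input_error")
})

test_that("path statistics compute distance and velocity", {
  still <- data.frame(t_min = c(0, 5, 10), x_um = 1, y_um = 2)
  st <- path_statistics(still)
  expect_equal(st$total_distance_um, 0)
  expect_equal(st$mean_velocity_um_per_min, 0)

  p <- data.frame(t_min = c(0, 7), x_um = c(0, 3), y_um = c(0, 4))
  st <- path_statistics(p)
  expect_equal(st$total_distance_um, 5)
  expect_equal(st$mean_velocity_um_per_min, 5 / 7)

  sq <- data.frame(t_min = 0:4, x_um = c(0, 10, 10, 0, 0), y_um = c(0, 0, 10, 10, 0))
  expect_equal(path_statistics(sq)$total_distance_um, 40)

  expect_error(path_statistics(p[1, ]), class = "emdmn_input_error")
  expect_error(path_statistics(data.frame(t_min = c(1, 1), x_um = 0:1, y_um = 0:1)),
               class = "emdmn_input_error")
})

test_that("path distance is invariant under rigid motion", {
  set.seed(31)
  p <- data.frame(t_min = 0:9, x_um = cumsum(rnorm(10)), y_um = cumsum(rnorm(10)))
  th <- 0.7
  q <- data.frame(t_min = p$t_min,
                  x_um = cos(th) * p$x_um - sin(th) * p$y_um + 12,
                  y_um = sin(th) * p$x_um + cos(th) * p$y_um - 5)
  expect_equal(path_statistics(q)$total_distance_um,
               path_statistics(p)$total_distance_um)
})

test_that("track CSVs round-trip and summarize per track", {
  f <- file.path(tempdir(), "tracks.csv")
  tr <- data.frame(track_id = rep(1:2, each = 3), t_min = rep(c(0, 5, 10), 2),
                   x_um = c(0, 3, 3, 0, 0, 6), y_um = c(0, 4, 4, 0, 8, 8))
  write.csv(tr, f, row.names = FALSE)
  got <- read_tracks(f)
  st <- track_statistics(got)
  expect_equal(st$total_distance_um, c(5, 14))
  expect_equal(st$mean_velocity_um_per_min, c(0.5, 1.4))
  unlink(f)
  write.csv(tr[, 1:3], f, row.names = FALSE)
  expect_error(read_tracks(f), class = "emdmn_input_error")
  unlink(f)
})
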