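test_that("connected components honour connectivity and calibration", {
  m <- matrix(0L, 40, 40)
  m[5:14, 5:14] <- 1L            # 10x10 square
  m[25:34, 25:34] <- 1L          # disjoint 10x10 square
  tab <- label_clusters(binary_mask(m, 1), min_area = 0)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$area), c(100, 100))
  expect_equal(sort(tab$centroid_x), c(mean(5:14) - 1, mean(25:34) - 1))

  # pixel size enters areas quadratically
  tab2 <- label_clusters(binary_mask(m, 2.5), min_area = 0)
  expect_equal(sort(tab2$area), c(100, 100) * 2.5^2)

  # corner-touching squares: one cluster under 8-connectivity, two under 4
  cm <- matrix(0L, 20, 20); cm[2:5, 2:5] <- 1L; cm[6:9, 6:9] <- 1L
  expect_equal(nrow(label_clusters(binary_mask(cm, 1), 8, min_area = 0)), 1)
  expect_equal(nrow(label_clusters(binary_mask(cm, 1), 4, min_area = 0)), 2)

  # empty mask: empty table, not an error
  empty <- label_clusters(binary_mask(matrix(0L, 10, 10), 1))
  expect_equal(nrow(empty), 0)
})

test_that("generator scenes are recovered with exact counts and areas", {
  areas <- c(100, 250, 480, 900, 1600, 2500)
  sc <- make_culture_scene(areas, shape = "rect", frame_shape = c(256, 256),
                           seed = 5)
  tab <- label_clusters(sc$truth_mask, min_area = 0)
  expect_equal(nrow(tab), length(areas))
  expect_equal(sort(tab$area), sort(areas))
})

test_that("area bookkeeping is conserved under min_area filtering", {
  set.seed(3)
  sc <- make_culture_scene(c(20, 30, 400, 900), shape = "rect",
                           frame_shape = c(128, 128), seed = 9)
  tab <- label_clusters(sc$truth_mask, min_area = 50)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$area) + attr(tab, "discarded_area"),
               attr(tab, "total_mask_area"))
})

test_that("cluster statistics are invariant under whole-pixel translation", {
  sc <- make_culture_scene(c(150, 700, 3000), shape = "rect",
                           frame_shape = c(128, 128), seed = 13)
  m <- sc$truth_mask$pixels
  shifted <- matrix(0L, 128, 128)
  shifted[6:128, 4:128] <- m[1:123, 1:125]   # shift by (5, 3); objects clear the edge
  t1 <- label_clusters(binary_mask(m, 1), min_area = 0)
  t2 <- label_clusters(binary_mask(shifted, 1), min_area = 0)
  expect_equal(sort(t1$area), sort(t2$area))
})

test_that("size histograms bin half-open and report overflow", {
  tab <- data.frame(area = c(100, 500, 5000))
  h <- size_histogram(tab, c(0, 300, 3000, 10000))
  expect_equal(h$counts, c(1, 1, 1))
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$overflow, 0)

  # boundary values land in the right-hand bin (half-open [lo, hi))
  hb <- size_histogram(data.frame(area = c(300, 3000)), c(0, 300, 3000, 10000))
  expect_equal(hb$counts, c(0, 1, 1))

  # empty table: all-zero counts
  h0 <- size_histogram(data.frame(area = numeric(0)), c(0, 10, 20))
  expect_equal(h0$counts, c(0, 0))

  # overflow counted outside the edges
  ho <- size_histogram(data.frame(area = c(5, 15, 150)), c(10, 20))
  expect_equal(ho$counts, 1)
  expect_equal(ho$overflow, 2)

  expect_error(size_histogram(tab, c(0, 300, 300)), "increasing")
})

test_that("histogram counts equal brute-force binning on many clusters", {
  set.seed(17)
  areas <- exp(runif(1000, log(30), log(20000)))
  edges <- c(0, 100, 300, 1000, 3000, 10000)
  h <- size_histogram(data.frame(area = areas), edges)
  expect_equal(h$counts, brute_bin_counts(areas, edges))
  expect_equal(h$overflow, sum(areas >= 10000))
})

test_that("band frequency agrees with its histogram identity", {
  expect_equal(band_frequency(data.frame(area = c(500, 5000))), 0.5)
  expect_equal(band_frequency(data.frame(area = c(400, 1000, 2999))), 1)
  expect_warning(bf <- band_frequency(data.frame(area = numeric(0))),
                 "undefined")
  expect_true(is.na(bf))

  set.seed(23)
  areas <- exp(runif(400, log(30), log(20000)))
  tab <- data.frame(area = areas)
  h <- size_histogram(tab, c(300, 3000))
  expect_equal(band_frequency(tab, 300, 3000),
               h$counts[1] / length(areas))
})

test_that("pooled distributions are additive and mix frequencies by counts", {
  set.seed(31)
  t1 <- data.frame(area = exp(runif(80, log(50), log(9000))))
  t2 <- data.frame(area = exp(runif(50, log(50), log(9000))))
  edges <- c(0, 300, 3000, 10000)
  # pooling a table with itself doubles every count
  h1 <- size_histogram(t1, edges)
  hp <- pooled_distribution(list(t1, t1), edges)
  expect_equal(hp$counts, 2 * h1$counts)
  # pooled frequency = count-weighted mix of per-table frequencies
  h2 <- size_histogram(t2, edges)
  hm <- pooled_distribution(list(t1, t2), edges)
  w <- c(sum(h1$counts), sum(h2$counts))
  expect_equal(hm$frequency,
               (h1$frequency * w[1] + h2$frequency * w[2]) / sum(w))
})

test_that("clusters at the frame border are flagged", {
  m <- matrix(0L, 20, 20)
  m[1:4, 3:6] <- 1L       # touches row 1
  m[10:13, 10:13] <- 1L   # interior
  tab <- label_clusters(binary_mask(m, 1), min_area = 0)
  expect_equal(sort(tab$touches_border), c(FALSE, TRUE))
})
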