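test_that("confusion counts match a brute-force per-node comparison", {
  set.seed(12)
  n <- 10
  for (rep in 1:20) {
    pred <- which(rbinom(n, 1, 0.4) == 1)
    truth <- which(rbinom(n, 1, 0.3) == 1)
    cm <- confusion(pred, truth, n)
    tp <- sum(seq_len(n) %in% pred & seq_len(n) %in% truth)
    fp <- sum(seq_len(n) %in% pred & !seq_len(n) %in% truth)
    fn <- sum(!seq_len(n) %in% pred & seq_len(n) %in% truth)
    expect_equal(cm$TP, tp); expect_equal(cm$FP, fp); expect_equal(cm$FN, fn)
    expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, n)
  }
  cm0 <- confusion(integer(0), 1:5, 20)
  expect_equal(cm0$FN, 5); expect_equal(cm0$TP, 0)
  cm1 <- confusion(1:5, 1:5, 20)
  expect_equal(cm1$FP, 0); expect_equal(cm1$FN, 0)
  expect_equal(cm1$sensitivity, 1)
  # invariant to node labeling order
  cm2 <- confusion(c(5, 3, 1), c(3, 5, 1), 20)
  expect_equal(cm2$TP, 3)
})

test_that("false-positive distances use nearest-truth Euclidean metric", {
  m <- std_mesh()
  expect_equal(fp_mean_distance(integer(0), 1:3, m), 0)
  # single FP: direct definition
  truth <- which.min(rowSums(m$node_coords^2))
  d <- sqrt(rowSums((m$node_coords -
                       matrix(m$node_coords[truth, ], m$n_nodes, 2,
                              byrow = TRUE))^2))
  fp <- order(d)[5]
  expect_equal(fp_mean_distance(fp, truth, m), d[fp], tolerance = 1e-12)
  # 5-node case vs exhaustive pairwise-min oracle
  set.seed(3)
  fp5 <- sample(m$n_nodes, 5)
  truth5 <- sample(m$n_nodes, 7)
  oracle <- mean(vapply(fp5, function(i) {
    min(sqrt(rowSums((m$node_coords[truth5, , drop = FALSE] -
                        matrix(m$node_coords[i, ], 7, 2, byrow = TRUE))^2)))
  }, numeric(1)))
  expect_equal(fp_mean_distance(fp5, truth5, m), oracle, tolerance = 1e-12)
  expect_error(fp_mean_distance(1:2, integer(0), m), "empty")
})

test_that("region statistics match brute-force mean/sd and define errors correctly", {
  set.seed(5)
  n <- 60
  recon <- runif(n, 0.005, 0.03)
  truth <- rep(0.01, n); truth[1:10] <- 0.023
  regions <- list(inc = 1:10, bg = 31:60)
  rs <- region_stats(recon, truth, regions)
  expect_equal(rs$mean[1], mean(recon[1:10]))
  expect_equal(rs$sd[2], sd(recon[31:60]))
  expect_equal(rs$percent_error[1],
               100 * abs(mean(recon[1:10]) - 0.023) / 0.023)
  # recon == truth: zero error
  rs0 <- region_stats(truth, truth, regions)
  expect_equal(rs0$percent_error, c(0, 0))
  # two-node arithmetic example
  rs2 <- region_stats(c(0.020, 0.026), c(0.023, 0.023), list(r = 1:2))
  expect_equal(rs2$mean[1], 0.023)
  expect_equal(rs2$percent_error[1], 0)
  expect_error(region_stats(recon, truth, list()), "nonempty")
})

test_that("artifact level measures spurious background contrast", {
  n <- 50
  truth <- rep(0.01, n); truth[1:5] <- 0.023
  recon <- truth                      # perfect recovery
  rs <- region_stats(recon, truth, list(inc = 1:5), background_nodes = 11:50,
                     inclusion_nodes = 1:5, reference_mua = 0.01)
  expect_equal(attr(rs, "artifact_level"), 0)   # no spurious contrast
  recon2 <- recon; recon2[20] <- 0.0165         # half-contrast artifact
  rs2 <- region_stats(recon2, truth, list(inc = 1:5),
                      background_nodes = 11:50, inclusion_nodes = 1:5,
                      reference_mua = 0.01)
  expect_equal(attr(rs2, "artifact_level"), 50)
})

test_that("FWHM of a Gaussian ridge equals 2.355 sigma and scales invariantly", {
  m <- std_mesh()
  sigma <- 2
  v <- exp(-(rowSums(m$node_coords^2)) / (2 * sigma^2))
  map <- rasterize(v, m, 256)
  line <- rbind(c(-10, 0), c(10, 0))
  pr <- line_profile_fwhm(map, line)
  expect_equal(nrow(pr$peaks), 1)
  expect_lt(abs(pr$peaks$fwhm[1] - 2.355 * sigma) / (2.355 * sigma), 0.02)
  # scale invariance of the half-max crossing
  map5 <- pmir:::new_temperature_map(map$pixels * 5, map$extent, map$mask)
  pr5 <- line_profile_fwhm(map5, line)
  expect_equal(pr5$peaks$fwhm, pr$peaks$fwhm, tolerance = 1e-9)
  # flat map: no peaks
  flat <- rasterize(rep(1, m$n_nodes), m, 128)
  prf <- line_profile_fwhm(flat, line)
  expect_equal(nrow(prf$peaks), 0)
})

test_that("closely spaced inclusions are flagged resolvable on the case-3 profile", {
  m <- std_mesh()
  ph <- representative_cases(m)$case3
  dm <- simulate_difference_map(ph, source_spec(), thermal_params(), 8)
  pr <- line_profile_fwhm(dm, rbind(c(0, -4), c(0, 9)))
  expect_gte(nrow(pr$peaks), 2)
  expect_true(isTRUE(pr$resolvable))
  # the valley at the inter-inclusion node sits below the lower peak's
  # half maximum
  o <- order(pr$peaks$height, decreasing = TRUE)
  lower_peak <- min(pr$peaks$height[o[1:2]])
  valley_xy <- matrix(c(0, 2.3), 1)
  v_between <- pmir:::sample_map_xy(dm, valley_xy)
  expect_lt(v_between, lower_peak / 2)
})
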