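test_that("duplicate-run consensus averages matched peaks and drops singletons", {
  c1 <- merge_duplicates(rp(100.2, 500), rp(100.5, 700), tol = 0.5)
  expect_equal(c1$peaks$size_bp, 100.35)
  expect_equal(c1$peaks$area, 600)
  expect_equal(c1$total_fluorescence, 600)

  c2 <- merge_duplicates(rp(100.0, 500), rp(101.0, 500), tol = 0.5)
  expect_equal(nrow(c2$peaks), 0L)
  expect_equal(c2$total_fluorescence, 0)

  r <- rp(c(90, 150.3, 400), c(10, 20, 30))
  c3 <- merge_duplicates(r, r)
  expect_equal(c3$peaks$size_bp, r$peaks$size_bp)
  expect_equal(c3$peaks$area, r$peaks$area)

  expect_error(merge_duplicates(rp(100, 1), rp(100, 1, id = "other")),
               "share sample_id")
})

test_that("greedy matching pairs by smallest size difference, each peak once", {
  # run1 peak 100.0 could pair with 100.3 or 99.9; nearest is 99.9
  cons <- merge_duplicates(rp(c(100.0, 100.4), c(10, 20)),
                           rp(c(99.9, 100.3), c(30, 40)), tol = 0.5)
  expect_equal(cons$peaks$size_bp, c(99.95, 100.35))
  expect_equal(cons$peaks$area, c(20, 30))
})

test_that("consensus is symmetric and idempotent on random inputs", {
  withr::local_seed(11)
  for (trial in 1:50) {
    n1 <- sample(0:8, 1)
    n2 <- sample(0:8, 1)
    r1 <- if (n1 > 0) rp(runif(n1, 80, 600), runif(n1, 1, 100)) else
      rp(numeric(0), numeric(0))
    r2 <- if (n2 > 0) rp(runif(n2, 80, 600), runif(n2, 1, 100)) else
      rp(numeric(0), numeric(0))
    a <- merge_duplicates(r1, r2)
    b <- merge_duplicates(r2, r1)
    expect_equal(a$peaks, b$peaks)
    i <- merge_duplicates(r1, r1)
    expect_equal(i$peaks, r1$peaks)
  }
})

test_that("size gate keeps strictly interior peaks and recomputes the total", {
  p <- cp(c(80.0, 80.1, 599.9, 600.0), c(1, 2, 3, 4))
  g <- size_gate(p)
  expect_equal(g$peaks$size_bp, c(80.1, 599.9))
  expect_equal(g$total_fluorescence, 5)

  inside <- cp(c(100, 200), c(5, 5))
  expect_equal(size_gate(inside)$peaks, inside$peaks)

  outside <- cp(c(10, 700), c(5, 5))
  expect_equal(nrow(size_gate(outside)$peaks), 0L)
  expect_equal(size_gate(outside)$total_fluorescence, 0)
})

test_that("percent threshold is strict and computed once from the input total", {
  p <- cp(c(100, 200, 300), c(980, 10, 10))
  f <- apply_percent_threshold(p, 1.2)  # cutoff 12.0; 10 < 12 < 980
  expect_equal(f$peaks$area, 980)

  one <- cp(150, 42)
  expect_equal(nrow(apply_percent_threshold(one, 99)$peaks), 1L)
  expect_equal(nrow(apply_percent_threshold(p, 0)$peaks), 3L)
  # exactly at the cutoff -> excluded (strictly "more than")
  q <- cp(c(100, 200), c(12, 988))
  expect_equal(apply_percent_threshold(q, 1.2)$peaks$area, 988)
})

test_that("variable percentage threshold removes the count-total dependence", {
  # counts independent of totals at every pct -> smallest grid value
  flat <- lapply(1:6, function(i) cp(c(100, 200, 300), c(500, 300, 200) * i))
  expect_equal(as.numeric(variable_percentage_threshold(flat,
                                                        grid = c(0.5, 1, 2))),
               0.5)
  # singleton grid is forced
  expect_equal(as.numeric(variable_percentage_threshold(flat, grid = 1.2)),
               1.2)
  expect_error(variable_percentage_threshold(flat[1:2]), ">= 3 profiles")

  # background peaks detected only in high-fluorescence profiles: the raw
  # count correlates with the total until the cutoff clears the background
  withr::local_seed(5)
  profs <- lapply(1:12, function(i) {
    total <- 1000 * i
    main <- c(0.5, 0.3, 0.15) * total
    n_bg <- floor(total / 2000)  # more detected background when more loaded
    bg <- rep(8, n_bg)           # absolute-scale background areas
    cp(seq(100, by = 10, length.out = 3 + n_bg), c(main, bg))
  })
  grid <- seq(0.1, 5, by = 0.1)
  chosen <- variable_percentage_threshold(profs, grid = grid)
  # brute-force oracle: smallest pct whose one-sided correlation test is
  # not significant
  totals <- vapply(profs, function(p) p$total_fluorescence, numeric(1))
  ps <- vapply(grid, function(g) {
    counts <- vapply(profs, function(p) sum(p$peaks$area > g / 100 *
                                              p$total_fluorescence),
                     numeric(1))
    if (sd(counts) == 0) return(1)
    cor.test(counts, totals, alternative = "greater")$p.value
  }, numeric(1))
  expect_equal(as.numeric(chosen), grid[which(ps >= 0.05)[1]])
  counts_at <- vapply(profs, function(p) {
    sum(p$peaks$area > chosen / 100 * p$total_fluorescence)
  }, numeric(1))
  expect_true(sd(counts_at) == 0 ||
                cor(counts_at, totals) < cor(vapply(profs, function(p)
                  nrow(p$peaks), numeric(1)), totals))
})

test_that("bin_frames produces round(WS/Sh) frames with half-open bins", {
  params <- binning_params(window_ws = 1, shift_sh = 0.1)
  profs <- list(cp(100.0, 10), cp(100.0, 20, id = "s2"))
  frames <- bin_frames(profs, params)
  expect_length(frames, 10L)
  for (fr in frames) {
    expect_equal(length(fr$bin_centers), 1L)
    expect_equal(unname(fr$values), matrix(1, 2, 1))
  }

  # peaks at 100.45 / 100.55: joined when both fall in one bin, split when
  # an edge passes between them; verify against interval arithmetic
  profs2 <- list(cp(100.45, 10), cp(100.55, 10, id = "s2"))
  frames2 <- bin_frames(profs2, params)
  for (fr in frames2) {
    k1 <- floor((100.45 - 80 - fr$frame_offset) / 1)
    k2 <- floor((100.55 - 80 - fr$frame_offset) / 1)
    expect_equal(length(fr$bin_centers), length(unique(c(k1, k2))))
  }
  split_frames <- sum(vapply(frames2, function(fr)
    length(fr$bin_centers) == 2L, logical(1)))
  expect_true(split_frames >= 1 && split_frames < 10)
})

test_that("bin labels are fluorescence-weighted mean sizes", {
  profs <- list(cp(c(100.2), c(30)), cp(c(100.4), c(10), id = "s2"))
  fr <- bin_frames(profs, binning_params())[[1]]  # offset 0: one bin
  expect_equal(fr$bin_centers, (100.2 * 30 + 100.4 * 10) / 40)
})

test_that("rows of a binned matrix sum to 1 for samples retaining peaks", {
  withr::local_seed(3)
  profs <- lapply(1:5, function(i) {
    n <- sample(3:8, 1)
    cp(runif(n, 81, 599), runif(n, 5, 100), id = sprintf("s%d", i))
  })
  best <- select_best_frame(bin_frames(profs, binning_params()))
  expect_equal(unname(rowSums(best$values)), rep(1, 5), tolerance = 1e-9)
})

test_that("best-frame choice is invariant to candidate and sample order", {
  withr::local_seed(9)
  profs <- lapply(1:4, function(i) {
    cp(runif(6, 81, 599), runif(6, 5, 100), id = sprintf("s%d", i))
  })
  params <- binning_params()
  cands <- bin_frames(profs, params)
  best1 <- select_best_frame(cands)
  best2 <- select_best_frame(rev(cands))
  expect_equal(best1$frame_offset, best2$frame_offset)
  best3 <- select_best_frame(bin_frames(rev(profs), params))
  expect_equal(best1$frame_offset, best3$frame_offset)

  one <- select_best_frame(cands[3])
  expect_equal(one$frame_offset, cands[[3]]$frame_offset)
})

test_that("presence/absence transform is exact", {
  m <- binned_matrix("CfoI", c("a", "b"), c(100, 200),
                     rbind(c(0.371, 0), c(0, 0)))
  pa <- to_presence_absence(m)
  expect_identical(unname(pa), rbind(c(1L, 0L), c(0L, 0L)))
})

test_that("noise-free pipeline recovers the planted TRF set exactly", {
  # integer planted TRFs >= 2 bp apart, no jitter, no background: the best
  # frame must reproduce one bin per planted TRF, identical across samples
  planted <- c(105, 171, 193, 240, 388, 504)
  peaks <- do.call(rbind, lapply(1:4, function(s) {
    do.call(rbind, lapply(1:2, function(run) {
      data.frame(sample_id = sprintf("s%d", s), site = "x", season = "y",
                 replicate_run = run, enzyme = "CfoI",
                 size_bp = planted, area = c(5000, 500, 400, 300, 200, 100))
    }))
  }))
  fp <- trflp_fingerprint(peaks, "CfoI", pct = 1.2)
  expect_equal(fp$matrix$bin_centers, as.numeric(planted))
  expect_true(all(to_presence_absence(fp$matrix) == 1L))
})

test_that("jittered planted TRFs land in a single bin under the best frame", {
  withr::local_seed(21)
  planted <- c(105, 171, 240, 388)
  ok <- 0L
  for (rep in 1:20) {
    peaks <- do.call(rbind, lapply(1:6, function(s) {
      do.call(rbind, lapply(1:2, function(run) {
        data.frame(sample_id = sprintf("s%d", s), site = "x", season = "y",
                   replicate_run = run, enzyme = "CfoI",
                   size_bp = planted + rnorm(length(planted), 0, 0.15),
                   area = c(5000, 900, 700, 600))
      }))
    }))
    fp <- trflp_fingerprint(peaks, "CfoI", pct = 1.2)
    ok <- ok + (length(fp$matrix$bin_centers) == length(planted))
  }
  expect_gte(ok, 19L)
})
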