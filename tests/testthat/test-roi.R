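test_that("an all-subthreshold map is an explicit 'ROI not identified' outcome", {
  z <- array(0, dim = c(5, 5, 5))
  roi <- extract_roi(z, seed = c(3, 3, 3), threshold = 2.3)
  expect_false(roi$identified)
  expect_equal(roi$size, 0L)
  expect_error(overall_selectivity(rnorm(125), roi), "empty")
})

test_that("the seed's connected component is returned, matching a graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:5) {
    z <- array(rnorm(7^3, mean = 1.2), dim = c(7, 7, 7))
    for (nb in c(6, 18, 26)) {
      seedv <- sample(2:6, 3, replace = TRUE)
      roi <- extract_roi(z, seedv, threshold = 2.3, neighborhood = nb,
                         search_radius = 6)
      # oracle: connected components of the supra-threshold adjacency graph
      idx <- which(z > 2.3, arr.ind = TRUE)
      if (nrow(idx) == 0) {
        expect_false(roi$identified)
        next
      }
      edges <- integer(0)
      for (i in seq_len(nrow(idx) - 1)) {
        for (j in (i + 1):nrow(idx)) {
          d <- abs(idx[i, ] - idx[j, ])
          connected <- switch(as.character(nb),
                              "6" = sum(d) == 1,
                              "18" = max(d) == 1 && sum(d) <= 2,
                              "26" = max(d) == 1)
          if (connected) edges <- c(edges, i, j)
        }
      }
      g <- igraph::make_graph(edges, n = nrow(idx), directed = FALSE)
      comp <- igraph::components(g)$membership
      lin <- idx[, 1] + 7 * (idx[, 2] - 1) + 49 * (idx[, 3] - 1)
      if (roi$identified) {
        memb <- comp[match(roi$indices, lin)]
        expect_true(all(!is.na(memb)) && length(unique(memb)) == 1)
        oracle_set <- sort(lin[comp == memb[1]])
        expect_equal(sort(roi$indices), oracle_set)
      }
    }
  }
})

test_that("two disjoint blobs: the seed selects exactly its own blob", {
  z <- array(0, dim = c(5, 5, 5))
  blob_a <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1))
  blob_b <- rbind(c(5, 5, 5), c(4, 5, 5))
  for (v in seq_len(nrow(blob_a))) z[blob_a[v, 1], blob_a[v, 2], blob_a[v, 3]] <- 3
  for (v in seq_len(nrow(blob_b))) z[blob_b[v, 1], blob_b[v, 2], blob_b[v, 3]] <- 3
  roi <- extract_roi(z, seed = c(1, 1, 1), threshold = 2.3, neighborhood = 6)
  expect_true(roi$identified)
  expect_equal(roi$size, 3L)
  lin_a <- sort(blob_a[, 1] + 5 * (blob_a[, 2] - 1) + 25 * (blob_a[, 3] - 1))
  expect_equal(roi$indices, lin_a)
  roi_b <- extract_roi(z, seed = c(5, 5, 5), threshold = 2.3, neighborhood = 6)
  expect_equal(roi_b$size, 2L)
})

test_that("degenerate threshold returns the whole connected volume", {
  z <- array(rnorm(4^3), dim = c(4, 4, 4))
  roi <- extract_roi(z, seed = c(2, 2, 2), threshold = -Inf, neighborhood = 26)
  expect_true(roi$identified)
  expect_equal(roi$size, 64L)
})

test_that("min_size and search radius govern identification", {
  z <- array(0, dim = c(5, 5, 5))
  z[2, 2, 2] <- 3
  expect_true(extract_roi(z, c(4, 4, 4), search_radius = 2)$identified)
  expect_false(extract_roi(z, c(5, 5, 5), search_radius = 1)$identified)
  expect_false(extract_roi(z, c(2, 2, 2), min_size = 2)$identified)
  expect_error(extract_roi(z, c(9, 9, 9)), "bounds")
})

test_that("overall selectivity is the arithmetic mean of contrast Z", {
  pm <- make_pm_const_runs(list(faces = rnorm(10), objects = rnorm(10),
                                scenes = rnorm(10)),
                           contrast_z = rep(1.7, 10))
  expect_equal(overall_selectivity(pm), 1.7)
  expect_equal(overall_selectivity(c(1, 2, 3, 6)), 3)
  set.seed(2)
  z <- rnorm(100)
  expect_equal(overall_selectivity(z), sum(z) / 100)  # brute-force oracle
})

test_that("identical patterns give zero dissimilarity; degenerate centering forces two", {
  v <- c(1, 5, 2, 8, 3)
  pm <- make_pm_const_runs(list(faces = v, objects = v, scenes = rnorm(5),
                                scrambled = rnorm(5)))
  expect_equal(between_category_dissimilarity(pm, centering_categories = NULL), 0)

  pm2 <- make_pm_const_runs(list(faces = c(1, 2, 3, 7), objects = c(4, 1, 0, 2),
                                 scenes = c(0, 0, 1, 0)))
  expect_error(
    between_category_dissimilarity(pm2, centering_categories = c("faces", "objects")),
    "degenerate")
  # forced degeneracy: centered vectors are exact negatives -> dissimilarity 2
  expect_equal(
    between_category_dissimilarity(pm2, centering_categories = c("faces", "objects"),
                                   allow_degenerate = TRUE), 2)
})

test_that("four-category mean-removed dissimilarity matches a covariance oracle", {
  pm <- make_pm_const_runs(list(faces = c(1, 2, 3, 4), objects = c(4, 3, 2, 1),
                                scenes = c(0, 0, 0, 0), scrambled = c(0, 0, 0, 0)))
  d <- between_category_dissimilarity(pm)
  # hand-rolled covariance oracle on the centered vectors
  m <- (c(1, 2, 3, 4) + c(4, 3, 2, 1) + 0 + 0) / 4
  a <- c(1, 2, 3, 4) - m
  b <- c(4, 3, 2, 1) - m
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(d, 1 - r_oracle, tolerance = 1e-12)
})

test_that("within-category dissimilarity hits its algebraic anchors", {
  v <- c(2, 4, 1, 7, 3)
  pm <- make_pm(list(faces = rbind(v, v),
                     objects = rbind(rnorm(5), rnorm(5)),
                     scenes = rbind(rnorm(5), rnorm(5))))
  expect_equal(within_category_dissimilarity(pm, "faces", 1, 2), 0)

  anti <- mean(v) - (v - mean(v))
  pm2 <- make_pm(list(faces = rbind(v, anti),
                      objects = rbind(rnorm(5), rnorm(5)),
                      scenes = rbind(rnorm(5), rnorm(5))))
  expect_equal(within_category_dissimilarity(pm2, "faces", 1, 2), 2)

  expect_error(within_category_dissimilarity(pm, "faces", 1, 1), "differ")
  expect_error(within_category_dissimilarity(pm, "faces", 1, 5), "out of range")
  pm3 <- make_pm(list(faces = rbind(rep(1, 5), v),
                      objects = rbind(v, v), scenes = rbind(v, v)))
  expect_error(within_category_dissimilarity(pm3, "faces", 1, 2), "zero-variance")
})

test_that("within-category dissimilarity grows monotonically with noise", {
  base <- rnorm(60)
  mean_d <- vapply(c(0.1, 0.5, 1, 2), function(ns) {
    set.seed(17)
    mean(replicate(200, {
      pm <- make_pm(list(faces = rbind(base + rnorm(60, 0, ns),
                                       base + rnorm(60, 0, ns)),
                         objects = rbind(base, base),
                         scenes = rbind(base, base)))
      within_category_dissimilarity(pm, "faces", 1, 2)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
})

test_that("dissimilarities respect bounds, symmetry, and invariances", {
  set.seed(31)
  for (rep in 1:20) {
    pm <- make_pm_const_runs(list(faces = rnorm(15), objects = rnorm(15),
                                  scenes = rnorm(15), scrambled = rnorm(15)),
                             n_runs = 2)
    d_ab <- between_category_dissimilarity(pm, "faces", "objects")
    d_ba <- between_category_dissimilarity(pm, "objects", "faces")
    expect_gte(d_ab, 0); expect_lte(d_ab, 2)
    expect_equal(d_ab, d_ba)  # symmetry

    # common voxel permutation leaves all measures unchanged
    perm <- sample(15)
    pm_p <- make_pm(list(faces = pm$betas["faces", , perm],
                         objects = pm$betas["objects", , perm],
                         scenes = pm$betas["scenes", , perm],
                         scrambled = pm$betas["scrambled", , perm]),
                    contrast_z = pm$contrast_z[perm])
    expect_equal(between_category_dissimilarity(pm_p), d_ab, tolerance = 1e-12)
    expect_equal(overall_selectivity(pm_p), overall_selectivity(pm))

    # adding a common constant to both compared categories changes nothing
    pm_c <- make_pm(list(faces = pm$betas["faces", , ] + 7,
                         objects = pm$betas["objects", , ] + 7,
                         scenes = pm$betas["scenes", , ],
                         scrambled = pm$betas["scrambled", , ]))
    expect_equal(between_category_dissimilarity(pm_c), d_ab, tolerance = 1e-12)
  }
})

test_that("pattern matrices validate their shape", {
  expect_error(pattern_matrix(array(0, c(3, 2, 5)), rep(0, 5)), "dimnames")
  b <- array(0, c(3, 2, 5), dimnames = list(c("a", "b", "c"), NULL, NULL))
  expect_error(pattern_matrix(b, rep(0, 4)), "voxel count")
  b1 <- array(0, c(3, 2, 1), dimnames = list(c("a", "b", "c"), NULL, NULL))
  expect_error(pattern_matrix(b1, 0), "2 voxels")
})
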