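test_that("overlap colocalization applies the 1-pixel rule", {
  la <- matrix(0L, 10, 10); la[2:4, 2:4] <- 1L; la[7:9, 7:9] <- 2L
  labs <- label_image(la, 102.4)

  # identical masks: every object flagged
  full <- binary_mask(la > 0L, 102.4)
  expect_true(all(overlap_colocalize(labs, full)$colocalized))

  # disjoint mask: none flagged
  none <- binary_mask(matrix(FALSE, 10, 10), 102.4)
  expect_true(all(!overlap_colocalize(labs, none)$colocalized))

  # single-pixel overlap is enough
  one <- matrix(FALSE, 10, 10); one[4, 4] <- TRUE
  fl <- overlap_colocalize(labs, binary_mask(one, 102.4))
  expect_equal(fl$colocalized, c(TRUE, FALSE))
  expect_equal(fl$overlap_px, c(1L, 0L))
  # but a 2-pixel requirement rejects it
  expect_false(overlap_colocalize(labs, binary_mask(one, 102.4),
                                  min_overlap_px = 2)$colocalized[1])

  expect_error(overlap_colocalize(labs, binary_mask(matrix(FALSE, 5, 5), 102.4)),
               "physical frame")
})

test_that("mixed-resolution overlap is evaluated through physical frames", {
  # fine labels (20 nm), coarse mask (100 nm), same 1 um frame
  la <- matrix(0L, 50, 50); la[10:14, 10:14] <- 1L; la[40:44, 40:44] <- 2L
  labs <- label_image(la, 20)
  coarse <- matrix(FALSE, 10, 10); coarse[2:3, 2:3] <- TRUE
  fl <- overlap_colocalize(labs, binary_mask(coarse, 100))
  expect_equal(fl$colocalized, c(TRUE, FALSE))
})

test_that("the four categories follow the truth table and partition PSDs", {
  expect_equal(as.character(classify_category(FALSE, FALSE)), "psd_only")
  expect_equal(as.character(classify_category(TRUE, FALSE)), "synapse")
  expect_equal(as.character(classify_category(FALSE, TRUE)), "psd_astro")
  expect_equal(as.character(classify_category(TRUE, TRUE)), "tripartite")
  set.seed(1)
  v <- runif(200) < 0.5; a <- runif(200) < 0.5
  cat <- classify_category(v, a)
  expect_equal(sum(table(cat)), 200)
  expect_equal(as.integer(table(cat)["tripartite"]), sum(v & a))
})

test_that("nearest_neighbors matches the brute-force oracle exactly", {
  set.seed(10)
  for (rep in 1:10) {
    n_p <- sample(5:30, 1); n_a <- sample(1:200, 1)
    psd <- tibble::tibble(id = seq_len(n_p), x_um = runif(n_p, 0, 30),
                          y_um = runif(n_p, 0, 30))
    ast <- tibble::tibble(x_um = runif(n_a, 0, 30), y_um = runif(n_a, 0, 30))
    nn <- nearest_neighbors(psd, ast)
    ref <- ref_nearest_neighbors(psd, ast)
    for (i in seq_len(n_p)) {
      expect_identical(nn$nn_distances_um[[i]], ref[[i]]$nn)
      expect_identical(nn$count_within_radius[i], as.integer(ref[[i]]$count))
    }
    expect_equal(nn$padded, rep(n_a < 10, n_p))
  }
})

test_that("radius counting uses a closed boundary and empty sets give zeros", {
  psd <- tibble::tibble(id = 1L, x_um = 0, y_um = 0)
  ast <- tibble::tibble(x_um = c(2, 3), y_um = 0)
  nn <- nearest_neighbors(psd, ast, k = 10, radius_um = 3)
  expect_equal(nn$count_within_radius, 2L) # the punctum at exactly 3.0 counts
  expect_equal(nn$nn_distances_um[[1]][1:2], c(2, 3))
  expect_true(nn$padded)

  nn0 <- nearest_neighbors(psd, ast[0, ], k = 10)
  expect_equal(nn0$count_within_radius, 0L)
  expect_true(all(is.na(nn0$nn_distances_um[[1]])))
})

test_that("edge-edge distances use boundary pixels with overlap as zero", {
  # overlapping objects -> distance 0, counted
  pl <- matrix(0L, 20, 20); pl[5:10, 5:10] <- 1L
  al <- matrix(0L, 20, 20); al[9:12, 9:12] <- 1L
  ee <- edge_edge_count(label_image(pl, 19.97), label_image(al, 19.97))
  expect_equal(ee$pairs$distance_nm, 0)
  expect_equal(ee$per_psd$n_astro_within_max, 1L)

  # two 1-px objects 5 px apart at 19.97 nm/px -> 99.85 nm, counted at 200
  p1 <- matrix(0L, 20, 20); p1[10, 5] <- 1L
  a1 <- matrix(0L, 20, 20); a1[10, 10] <- 1L
  ee1 <- edge_edge_count(label_image(p1, 19.97), label_image(a1, 19.97))
  expect_equal(ee1$pairs$distance_nm, 5 * 19.97, tolerance = 1e-9)
  expect_equal(ee1$per_psd$n_astro_within_max, 1L)

  # an object at ~250 nm is not counted at the 200 nm limit
  a2 <- matrix(0L, 20, 20); a2[10, 18] <- 1L # 13 px ~ 260 nm
  ee2 <- edge_edge_count(label_image(p1, 19.97), label_image(a2, 19.97),
                         max_nm = 200)
  expect_equal(ee2$per_psd$n_astro_within_max, 0L)
  # and the boundary is closed: exactly 200 nm counts
  ee3 <- edge_edge_count(label_image(p1, 19.97), label_image(a2, 19.97),
                         max_nm = 13 * 19.97)
  expect_equal(ee3$per_psd$n_astro_within_max, 1L)
})

test_that("the 180-degree rotation is an involution preserving statistics", {
  set.seed(11)
  m <- matrix(runif(35 * 28), 35)
  img <- channel_image(m, 102.4, "highres", "astro")
  rot <- rotated_control(img)
  expect_identical(rotated_control(rot)$pixels, img$pixels)
  expect_identical(sort(as.vector(rot$pixels)), sort(as.vector(img$pixels)))

  lab <- label_image(matrix(c(0L, 1L, 0L, 2L), 2), 100)
  rl <- rotated_control(lab)
  expect_equal(rl$n, 2L)
  expect_identical(table(rl$pixels), table(lab$pixels))

  # a point at the frame centre is a fixed point
  pts <- tibble::tibble(x_um = c(5, 1), y_um = c(5, 2))
  rp <- rotated_control(pts, field_um = c(10, 10))
  expect_equal(rp$x_um, c(5, 9))
  expect_equal(rp$y_um, c(5, 8))
  expect_equal(rotated_control(rp, field_um = c(10, 10)), pts)
  expect_error(rotated_control(pts), "field_um")
})

test_that("point and pixel rotation agree through physical coordinates", {
  # a mask with one pixel set, rotated, matches the rotated pixel-centre point
  m <- matrix(FALSE, 9, 11); m[3, 4] <- TRUE
  bm <- binary_mask(m, 100)
  rot <- rotated_control(bm)
  idx <- which(rot$pixels, arr.ind = TRUE)
  centre_rot <- unname(c(idx[1, 2], idx[1, 1]) - 0.5) * 0.1 # (x, y) um
  pt <- rotated_control(tibble::tibble(x_um = (4 - 0.5) * 0.1,
                                       y_um = (3 - 0.5) * 0.1),
                        field_um = c(1.1, 0.9))
  expect_equal(centre_rot, c(pt$x_um, pt$y_um))
})

test_that("the rotated null is centred under CSR and detects clustering", {
  csr_diff <- vapply(1:10, function(sd) {
    p <- scene_params(field_um = c(30, 30), psd_density_um2 = 0.06,
                      bouton_frac = 0, tripartite_frac = 0,
                      astro_nonsyn_frac = 0, decoy_astro_density_um2 = 0.3)
    s <- generate_scene(p, sd)
    nt <- nearest_neighbors(s$psds, s$astros)
    nr <- nearest_neighbors(s$psds, rotated_control(s$astros, s$field_um))
    null_comparison(nt, nr)$count_diff
  }, numeric(1))
  expect_lt(abs(mean(csr_diff)), 2 * stats::sd(csr_diff) / sqrt(length(csr_diff)))

  clus_diff <- vapply(1:10, function(sd) {
    p <- scene_params(field_um = c(40, 40), psd_density_um2 = 0.08,
                      bouton_frac = 1, tripartite_frac = 0.5,
                      astro_nonsyn_frac = 0.5, decoy_astro_density_um2 = 0.05)
    s <- generate_scene(p, sd)
    nt <- nearest_neighbors(s$psds, s$astros)
    nr <- nearest_neighbors(s$psds, rotated_control(s$astros, s$field_um))
    null_comparison(nt, nr)$count_diff
  }, numeric(1))
  expect_gte(sum(clus_diff > 0), 9)

  # identical inputs give exactly zero difference
  psd <- tibble::tibble(id = 1:5, x_um = 1:5, y_um = 1)
  ast <- tibble::tibble(x_um = c(2, 4), y_um = 1.5)
  nn <- nearest_neighbors(psd, ast)
  z <- null_comparison(nn, nn)
  expect_equal(z$count_diff, 0)
  expect_equal(z$nn_diff, 0)
  expect_error(null_comparison(nn, nn[1:3, ]), "different PSD sets")
})
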