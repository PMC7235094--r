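test_that("NC assignment follows the majority-overlap rule", {
  psd <- matrix(0L, 10, 10)
  psd[1:5, 1:10] <- 1L   # PSD 1: rows 1-5
  psd[6:10, 1:10] <- 2L  # PSD 2: rows 6-10
  psd_lab <- label_image(psd, 100)

  nc <- matrix(0L, 10, 10)
  nc[2:3, 2:3] <- 1L            # wholly inside PSD 1
  nc[4:6, 5] <- 2L              # 2 px in PSD 1, 1 px in PSD 2 -> PSD 1
  nc_lab <- label_image(nc, 100)
  a <- assign_ncs_to_psds(psd_lab, nc_lab)
  expect_equal(a$psd_id, c(1L, 1L))
  expect_equal(a$overlap_px, c(4L, 2L))

  # exact tie -> lower PSD id
  nc2 <- matrix(0L, 10, 10); nc2[5:6, 8] <- 1L
  a2 <- assign_ncs_to_psds(psd_lab, label_image(nc2, 100))
  expect_equal(a2$psd_id, 1L)

  # orphan NC outside all PSDs
  psd3 <- matrix(0L, 10, 10); psd3[1:3, 1:3] <- 1L
  nc3 <- matrix(0L, 10, 10); nc3[8:9, 8:9] <- 1L
  a3 <- assign_ncs_to_psds(label_image(psd3, 100), label_image(nc3, 100))
  expect_true(is.na(a3$psd_id))

  # mismatched physical frames are rejected
  expect_error(assign_ncs_to_psds(label_image(psd, 100),
                                  label_image(nc[1:5, ], 100)),
               "physical frame")
})

test_that("assignment works across resolutions through physical coordinates", {
  # coarse grid 10x10 at 100 nm; fine grid 50x50 at 20 nm (same 1 um frame)
  psd <- matrix(0L, 10, 10); psd[1:10, 1:5] <- 1L; psd[1:10, 6:10] <- 2L
  nc <- matrix(0L, 50, 50)
  nc[10:12, 10:12] <- 1L  # physical x ~ 0.19-0.25 um -> PSD 1
  nc[20:22, 40:42] <- 2L  # physical x ~ 0.79-0.85 um -> PSD 2
  a <- assign_ncs_to_psds(label_image(psd, 100), label_image(nc, 20))
  expect_equal(a$psd_id, c(1L, 2L))
})

test_that("NC-count classes partition and never decrease with extra NCs", {
  expect_equal(as.character(classify_psd(c(0, 1, 2, 5))),
               c("0NC", "1NC", "2NC", "3plusNC"))
  expect_error(classify_psd(-1), "negative")
  cls <- classify_psd(0:10)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("per-PSD counts plus orphans account for every NC", {
  s <- generate_scene(scene_params(field_um = c(20, 20)), 13)
  cfg <- pipeline_config()
  icf <- render_channel(s, "psd95", render_spec("confocal"), seed = 14)
  ist <- render_channel(s, "psd95", render_spec("sted"), seed = 15)
  scf <- segment_channel(icf, cfg, "punctate")
  sst <- segment_channel(ist, cfg, "punctate", min_px = cfg$min_particle_px)
  a <- assign_ncs_to_psds(scf$labels, sst$labels)
  nt <- psd_nc_table(a, scf$objects)
  expect_equal(sum(nt$nc_count) + sum(is.na(a$psd_id)), sst$labels$n)
  expect_identical(nt$nc_class, classify_psd(nt$nc_count))
})

test_that("fwhm_profile matches closed forms and flags unmeasurable profiles", {
  s <- single_nc_scene(2, 2, fwhm_long = 40 * SIGMA_TO_FWHM)
  img <- render_channel(s, "psd95", noiseless("sted", psf_fwhm_nm = 0))
  f <- fwhm_profile(img, c(0.8, 2), c(3.2, 2))
  expect_equal(f, 40 * SIGMA_TO_FWHM, tolerance = 0.02)

  # top-hat profile: FWHM = width within one sample spacing
  px <- matrix(0, 40, 40); px[, 15:26] <- 100
  th <- channel_image(px, 19.97, "sted", "tophat")
  f_th <- fwhm_profile(th, c(0.05, 0.4), c(0.75, 0.4))
  expect_lt(abs(f_th - 12 * 19.97), 19.97)

  # monotone ramp has no peak
  ramp <- channel_image(matrix(rep(1:40, each = 40), 40), 19.97, "sted", "r")
  expect_true(is.na(fwhm_profile(ramp, c(0.05, 0.4), c(0.75, 0.4))))
  expect_error(fwhm_profile(img, c(-1, 2), c(3, 2)), "outside")
})

test_that("FWHM is unbiased across sub-pixel offsets (noiseless Gaussians)", {
  offsets <- seq(0, 0.9, by = 0.3) * 0.01997
  for (sig in c(30, 60, 100)) {
    for (ox in offsets) for (oy in offsets) {
      s <- single_nc_scene(1.5 + ox, 1.5 + oy, fwhm_long = sig * SIGMA_TO_FWHM,
                           field = c(3, 3))
      img <- render_channel(s, "psd95", noiseless("sted", psf_fwhm_nm = 0))
      f <- fwhm_profile(img, c(0.5, 1.5 + oy), c(2.5, 1.5 + oy))
      expect_lt(abs(f - sig * SIGMA_TO_FWHM) / (sig * SIGMA_TO_FWHM), 0.03)
    }
  }
})

test_that("nc_axes recovers anisotropic axis lengths and enforces isolation", {
  # a single elliptical NC, sigmas (40, 80) nm, delta PSF
  s <- single_nc_scene(2, 2, fwhm_long = 80 * SIGMA_TO_FWHM,
                       fwhm_short = 40 * SIGMA_TO_FWHM, theta = pi / 5)
  img <- render_channel(s, "psd95", noiseless("sted", psf_fwhm_nm = 0))
  mask <- binary_mask(img$pixels > max(img$pixels) / 20, 19.97)
  labs <- detect_particles(mask, 8)
  ax <- nc_axes(img, labs)
  expect_true(ax$measured)
  expect_equal(ax$fwhm_short_nm, 40 * SIGMA_TO_FWHM, tolerance = 0.05)
  expect_equal(ax$fwhm_long_nm, 80 * SIGMA_TO_FWHM, tolerance = 0.05)
  expect_lt(ax$aspect_ratio, 0.6)

  # circular NC -> aspect ratio near 1
  sc <- single_nc_scene(2, 2, fwhm_long = 60 * SIGMA_TO_FWHM)
  imgc <- render_channel(sc, "psd95", noiseless("sted", psf_fwhm_nm = 0))
  labc <- detect_particles(binary_mask(imgc$pixels > max(imgc$pixels) / 20,
                                       19.97), 8)
  axc <- nc_axes(imgc, labc)
  expect_gte(axc$aspect_ratio, 0.9)

  # two NCs 300 nm apart violate the 400 nm isolation radius
  s2 <- ground_truth_scene(
    psds = s$psds,
    ncs = tibble::tibble(id = 1:2, psd_id = 1L, x_um = c(1.85, 2.15),
                         y_um = 2, fwhm_long_nm = 120, fwhm_short_nm = 120,
                         theta = 0, amplitude = 1e4),
    field_um = c(4, 4))
  img2 <- render_channel(s2, "psd95", noiseless("sted", psf_fwhm_nm = 0))
  lab2 <- detect_particles(binary_mask(img2$pixels > max(img2$pixels) / 10,
                                       19.97), 8)
  ax2 <- nc_axes(img2, lab2)
  expect_true(all(!ax2$measured))
  expect_true(all(ax2$reason == "not isolated"))
})

test_that("population axis medians are recovered at the generator defaults", {
  p <- scene_params(field_um = c(30, 30), psd_density_um2 = 0.08,
                    nc_count_probs = 1, bouton_frac = 0, tripartite_frac = 0,
                    astro_nonsyn_frac = 0, decoy_astro_density_um2 = 0,
                    psd_diffuse_frac = 0)
  s <- generate_scene(p, 9)
  img <- render_channel(s, "psd95", render_spec("sted"), seed = 10)
  seg <- segment_channel(img, pipeline_config(), "punctate", min_px = 8)
  ax <- nc_axes(img, seg$labels)
  ok <- ax[ax$measured, ]
  expect_gt(nrow(ok), 40)
  # measured sizes are PSF-composed: apparent = sqrt(intrinsic^2 + 80^2)
  exp_short <- sqrt(stats::median(s$ncs$fwhm_short_nm)^2 + 80^2)
  exp_long <- sqrt(stats::median(s$ncs$fwhm_long_nm)^2 + 80^2)
  expect_lt(abs(stats::median(ok$fwhm_short_nm) - exp_short) / exp_short, 0.10)
  expect_lt(abs(stats::median(ok$fwhm_long_nm) - exp_long) / exp_long, 0.10)
})
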