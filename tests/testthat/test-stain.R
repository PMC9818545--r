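angle_deg <- function(a, b) acos(pmin(1, sum(a * b))) * 180 / pi

test_that("optical density conversion is the Beer-Lambert inverse pair", {
  px <- array(c(0.1, 0.5, 1.0), dim = c(1, 1, 3))
  od <- rgb_to_od(px, 1.0, eps = 0)
  expect_equal(od[1, 1, 1], 1.0)              # background/10 -> OD 1
  expect_equal(od[1, 1, 3], 0.0)              # background -> OD 0
  expect_equal(od_to_rgb(od), px, tolerance = 1e-12)
  expect_equal(od_to_rgb(array(0, dim = c(2, 2, 3)), 0.9)[1, 1, 1], 0.9)
  expect_equal(od_to_rgb(array(1, dim = c(1, 1, 3)), 1.0)[1, 1, 1], 0.1)
  set.seed(8)
  x <- array(runif(48, 0.01, 1), dim = c(4, 4, 3))
  expect_equal(od_to_rgb(rgb_to_od(x)), x, tolerance = 1e-4)
})

test_that("Macenko recovers the generative stain vectors within 5 degrees", {
  truth <- fixture_truth_matrix()
  for (rec in class_fixture_images()) {
    sm <- estimate_stains(rec$pixels)
    expect_s3_class(sm, "stain_model")
    expect_equal(sqrt(colSums(sm$stain_matrix^2)), c(1, 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(sm$stain_matrix >= 0))
    expect_true(all(sm$max_concentrations > 0))
    expect_lt(angle_deg(sm$stain_matrix[, 1], truth[, 1]), 5)
    expect_lt(angle_deg(sm$stain_matrix[, 2], truth[, 2]), 5)
  }
})

test_that("stain recovery degrades gracefully with noise", {
  truth <- fixture_truth_matrix()
  errs <- vapply(c(0, 0.01, 0.05), function(ns) {
    spec <- fixture_spec(n_per_class = 1, height = 256, width = 256,
                         seed = 13, noise_sd = ns)
    rec <- render_fixture_image("benign", spec, 1)
    sm <- estimate_stains(rec$pixels)
    max(angle_deg(sm$stain_matrix[, 1], truth[, 1]),
        angle_deg(sm$stain_matrix[, 2], truth[, 2]))
  }, numeric(1))
  expect_lt(errs[1], 5)
  expect_true(all(diff(errs) > -1)) # monotone up to 1 degree of slack
})

test_that("degenerate inputs raise informative errors", {
  white <- array(1, dim = c(16, 16, 3))
  expect_error(estimate_stains(white), "degenerate")
  # rank-1 cloud: a single stain at varying concentration
  v <- c(0.4, 0.6, 0.69); v <- v / sqrt(sum(v^2))
  conc <- seq(0.3, 2, length.out = 64)
  od <- outer(conc, v)
  single <- od_to_rgb(array(od, dim = c(8, 8, 3)))
  expect_error(estimate_stains(single), "rank 1|single stain")
})

test_that("stain estimation is invariant to pixel order", {
  rec <- class_fixture_images()[[3]]
  sm1 <- estimate_stains(rec$pixels)
  set.seed(4)
  perm <- rec$pixels[sample(dim(rec$pixels)[1]), sample(dim(rec$pixels)[2]), ]
  sm2 <- estimate_stains(perm)
  expect_equal(sm1$stain_matrix, sm2$stain_matrix, tolerance = 1e-8)
  expect_equal(sm1$max_concentrations, sm2$max_concentrations,
               tolerance = 1e-8)
})

test_that("self-normalization is the identity within 2/255", {
  rec <- class_fixture_images()[[2]]
  template <- estimate_stains(rec$pixels)
  out <- normalize_to_template(rec, template)
  expect_lt(max(abs(out$pixels - rec$pixels)), 2 / 255)
  expect_equal(out$label, rec$label)
})

test_that("normalization maps images with shared concentrations together", {
  # two images built from the same concentration fields under different
  # stain matrices must coincide after normalization to one template
  base <- class_fixture_images()[[4]]
  truth <- attr(base, "truth")
  C <- cbind(as.vector(truth$hematoxylin), as.vector(truth$eosin))
  m2 <- cbind(c(0.3, 0.55, 0.78), c(0.62, 0.7, 0.35))
  m2 <- sweep(m2, 2, sqrt(colSums(m2^2)), "/")
  d <- dim(base$pixels)
  img_a <- base$pixels
  img_b <- od_to_rgb(array(C %*% t(m2), dim = d))
  template <- estimate_stains(class_fixture_images()[[2]]$pixels)
  rec_a <- structure(list(image_id = "a", pixels = img_a, label = "invasive",
                          split = "train"), class = "image_record")
  rec_b <- structure(list(image_id = "b", pixels = img_b, label = "invasive",
                          split = "train"), class = "image_record")
  na <- normalize_to_template(rec_a, template)$pixels
  nb <- normalize_to_template(rec_b, template)$pixels
  expect_lt(mean(abs(na - nb)), 0.02)
  # rescaling contract: re-estimated max concentrations match the template's
  re <- estimate_stains(na)
  expect_equal(re$max_concentrations, template$max_concentrations,
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("stain separation reconstructs one stain at a time", {
  rec <- class_fixture_images()[[1]]
  sm <- estimate_stains(rec$pixels)
  sep <- stain_separation(rec$pixels, sm)
  expect_named(sep, c("hematoxylin", "eosin"))
  expect_equal(dim(sep$hematoxylin), dim(rec$pixels))
  # single-stain reconstructions are no darker than the full image
  expect_true(mean(sep$eosin) >= mean(rec$pixels) - 1e-6)
})

test_that("stain model JSON round trip preserves the model", {
  sm <- estimate_stains(class_fixture_images()[[1]]$pixels)
  path <- tempfile(fileext = ".json")
  write_stain_model(sm, path)
  back <- read_stain_model(path)
  expect_equal(back$stain_matrix, sm$stain_matrix, tolerance = 1e-12)
  expect_equal(back$max_concentrations, sm$max_concentrations,
               tolerance = 1e-12, ignore_attr = TRUE)
})
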