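make_patch <- function(seed = 17, n = 32) {
  set.seed(seed)
  structure(list(patch_id = "p", parent_id = "img", row = 0L, col = 0L,
                 y = 0L, x = 0L,
                 pixels = array(runif(n * n * 3), dim = c(n, n, 3)),
                 label = "benign"),
            class = "patch_record")
}

test_that("identity configuration returns the input unchanged", {
  p <- make_patch()
  spec <- augment_spec(p_hflip = 0, p_vflip = 0, max_rotation_degrees = 0,
                       max_translation_fraction = 0)
  out <- augment_patch(p, spec, seed = 1)
  expect_equal(out$pixels, p$pixels)
  expect_equal(out$label, p$label)
})

test_that("horizontal flip is an involution and flips conserve the mean", {
  p <- make_patch()
  spec <- augment_spec(p_hflip = 1, p_vflip = 0, max_rotation_degrees = 0,
                       max_translation_fraction = 0)
  once <- augment_patch(p, spec, seed = 1)
  expect_false(identical(once$pixels, p$pixels))
  expect_equal(mean(once$pixels), mean(p$pixels))
  twice <- augment_patch(once, spec, seed = 2)
  expect_equal(twice$pixels, p$pixels)
  both <- augment_spec(p_hflip = 1, p_vflip = 1, max_rotation_degrees = 0,
                       max_translation_fraction = 0)
  expect_equal(mean(augment_patch(p, both, seed = 3)$pixels),
               mean(p$pixels))
})

test_that("random draws are deterministic given a seed and preserve shape", {
  p <- make_patch()
  spec <- augment_spec(seed = 5)
  a <- augment_patch(p, spec, seed = 11)
  b <- augment_patch(p, spec, seed = 11)
  c <- augment_patch(p, spec, seed = 12)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
  expect_equal(dim(a$pixels), dim(p$pixels))
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
})

test_that("rotation/translation with reflect fill roughly conserves the mean", {
  p <- make_patch(n = 64)
  spec <- augment_spec(p_hflip = 0, p_vflip = 0, max_rotation_degrees = 15,
                       max_translation_fraction = 0.1,
                       fill_mode = "reflect")
  out <- augment_patch(p, spec, seed = 7)
  expect_lt(abs(mean(out$pixels) - mean(p$pixels)), 0.02)
  # constant fill injects the fill value at the borders instead
  specc <- augment_spec(p_hflip = 0, p_vflip = 0, max_rotation_degrees = 15,
                        max_translation_fraction = 0.1,
                        fill_mode = "constant", fill_value = 1)
  outc <- augment_patch(p, specc, seed = 7)
  expect_gt(mean(outc$pixels), mean(p$pixels))
})

test_that("offline expansion produces k labelled copies per patch", {
  p <- make_patch()
  spec <- augment_spec(seed = 2)
  out <- augment_expand(list(p, p), spec, k = 2)
  expect_length(out, 6)
  expect_true(all(grepl("_aug", vapply(out[3:6], `[[`, character(1),
                                       "patch_id"))))
  expect_true(all(vapply(out, `[[`, character(1), "label") == "benign"))
})
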