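test_that("span-0 integration is the bare target as an H x W x 1 cuboid", {
  g <- render_glyph("A")
  cfg <- integration_config(0, 0)
  out <- integrate_stimuli(g, list(), list(), cfg)
  expect_identical(dim(out$cuboid), c(32L, 32L, 1L))
  expect_identical(out$cuboid[, , 1], g$pixels)
})

test_that("depth is conserved for symmetric and asymmetric spans", {
  g <- render_glyph("A")
  ctx <- function(n) lapply(rep("B", n), function(x) render_glyph(x))
  for (sp in list(c(1, 1), c(2, 2), c(0, 3), c(2, 0))) {
    cfg <- integration_config(sp[1], sp[2])
    out <- integrate_stimuli(g, ctx(sp[1]), ctx(sp[2]), cfg)
    expect_identical(dim(out$cuboid)[3], as.integer(sp[1] + 1 + sp[2]))
    expect_identical(out$slot_labels$position, seq.int(-sp[1], sp[2]))
  }
})

test_that("zero-weight context slots are annihilated, target slice unchanged", {
  cfg <- integration_config(1, 1, weights = c(0, 1, 0))
  out <- integrate_stimuli(render_glyph("A"),
                           list(render_glyph("B")), list(render_glyph("G")), cfg)
  expect_true(all(out$cuboid[, , 1] == 0))
  expect_true(all(out$cuboid[, , 3] == 0))
  expect_identical(out$cuboid[, , 2], render_glyph("A")$pixels)
})

test_that("slices are weighted copies of their stimuli with no cross-slice mixing", {
  cfg <- integration_config(1, 1, weights = c(0.4, 1, 0.7))
  A <- render_glyph("A"); B <- render_glyph("B"); G <- render_glyph("G")
  out <- integrate_stimuli(A, list(B), list(G), cfg)
  expect_equal(out$cuboid[, , 1], 0.4 * B$pixels)
  expect_equal(out$cuboid[, , 2], A$pixels)
  expect_equal(out$cuboid[, , 3], 0.7 * G$pixels)
})

test_that("at zero noise the integration is linear in the weights", {
  cfg1 <- integration_config(1, 1, weights = c(0.8, 0.6, 0.4))
  cfg2 <- integration_config(1, 1, weights = 0.5 * c(0.8, 0.6, 0.4))
  A <- render_glyph("A")
  args <- list(list(render_glyph("B")), list(render_glyph("G")))
  o1 <- integrate_stimuli(A, args[[1]], args[[2]], cfg1)
  o2 <- integrate_stimuli(A, args[[1]], args[[2]], cfg2)
  expect_equal(o2$cuboid, 0.5 * o1$cuboid)
})

test_that("reversing distinct context letters changes the cuboid", {
  cfg <- integration_config(1, 1)
  A <- render_glyph("A")
  o1 <- integrate_stimuli(A, list(render_glyph("B")), list(render_glyph("G")), cfg)
  o2 <- integrate_stimuli(A, list(render_glyph("G")), list(render_glyph("B")), cfg)
  expect_false(identical(o1$cuboid, o2$cuboid))
})

test_that("per-slot noise is reproducible from the seed and respects variances", {
  cfg <- integration_config(1, 1, noise_variances = c(0.5, 0, 0.5))
  A <- render_glyph("A")
  args <- list(list(render_glyph("B")), list(render_glyph("G")))
  o1 <- integrate_stimuli(A, args[[1]], args[[2]], cfg, seed = 11)
  o2 <- integrate_stimuli(A, args[[1]], args[[2]], cfg, seed = 11)
  expect_identical(o1$cuboid, o2$cuboid)
  # noise-free target slice, noisy context slices
  expect_identical(o1$cuboid[, , 2], A$pixels)
  expect_false(identical(o1$cuboid[, , 1], render_glyph("B")$pixels))
  # the two context slots use independent streams
  expect_false(identical(o1$cuboid[, , 1] - render_glyph("B")$pixels,
                         o1$cuboid[, , 3] - render_glyph("G")$pixels))
})

test_that("shape and span mismatches are rejected", {
  cfg <- integration_config(1, 1)
  A <- render_glyph("A")
  expect_error(integrate_stimuli(A, list(), list(render_glyph("G")), cfg),
               "left context")
  expect_error(integrate_stimuli(A, list(render_glyph("B")),
                                 list(matrix(0, 16, 16)), cfg),
               "height, width")
  expect_error(integration_config(-1, 0), "non-negative")
  expect_error(integration_config(1, 1, weights = c(1, 2, 1)), "\\[0, 1\\]")
  expect_error(integration_config(1, 1, noise_variances = c(0, -1, 0)), ">= 0")
  expect_error(integration_config(1, 1, weights = c(1, 1)), "length")
})

test_that("word inputs order slices left context, centre, right context", {
  cfg <- integration_config(1, 1)
  x <- word_input("BAG", config = cfg)
  expect_identical(x$slot_labels$label, c("B", "A", "G"))
  expect_identical(x$cuboid[, , 1], render_glyph("B")$pixels)
  expect_identical(x$cuboid[, , 2], render_glyph("A")$pixels)
  expect_identical(x$cuboid[, , 3], render_glyph("G")$pixels)
  # centre substitution
  h <- make_ambiguous("A", "H")
  xh <- word_input("BAG", center_stimulus = h, config = cfg)
  expect_identical(xh$cuboid[, , 2], h$pixels)
  expect_identical(xh$cuboid[, , 1], render_glyph("B")$pixels)
  # flipped word reorders slots
  xf <- word_input(flip_word("BAG"), center_stimulus = h, config = cfg)
  expect_identical(xf$slot_labels$label, c("G", "A/H", "B"))
  expect_false(identical(x$cuboid, xf$cuboid))
})

test_that("word length must match the span", {
  expect_error(word_input("BAG", config = integration_config(2, 2)), "5")
  cfg4 <- integration_config(2, 2)
  x <- word_input("BEAST", center_stimulus = make_ambiguous("A", "H"), config = cfg4)
  expect_identical(dim(x$cuboid), c(32L, 32L, 5L))
})

test_that("flip_word mirrors a word about its centre", {
  expect_identical(flip_word("BAG"), "GAB")
  expect_identical(flip_word("THE"), "EHT")
  expect_identical(flip_word("BEAST"), "TSAEB")
  expect_error(flip_word("ABCD"), "odd")
})
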