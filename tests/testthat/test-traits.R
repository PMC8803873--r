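test_that("mean fruit-body size is the arithmetic mean with validated inputs", {
  expect_equal(mean_fruit_body_size(20, 60), 40)
  expect_equal(mean_fruit_body_size(5, 5), 5)
  expect_equal(mean_fruit_body_size(0, 0), 0)
  expect_equal(mean_fruit_body_size(c(20, NA), c(60, 10)), c(40, NA))
  expect_error(mean_fruit_body_size(60, 20, species_id = "Fomes fomentarius"),
               "Fomes fomentarius")
  expect_error(mean_fruit_body_size(-1, 5), "negative")
})

test_that("HSL lightness follows the bi-hexcone formula", {
  expect_equal(rgb_to_lightness(c(255, 255, 255)), 100)
  expect_equal(rgb_to_lightness(c(0, 0, 0)), 0)
  expect_equal(rgb_to_lightness(c(255, 0, 0)), 50)
  # greyscale pixels map to v/255 * 100 exactly
  for (v in c(0, 17, 128, 200, 255)) {
    expect_equal(rgb_to_lightness(c(v, v, v)), v / 255 * 100)
  }
  expect_error(rgb_to_lightness(c(300, 0, 0)), "\\[0, 255\\]")
  expect_error(rgb_to_lightness(c(-1, 0, 0)), "\\[0, 255\\]")
})

test_that("species lightness averages pixels and enforces the sampling protocol", {
  px <- matrix(rep(c(255, 255, 255), 9), ncol = 3, byrow = TRUE)
  expect_equal(species_lightness(px), 100)
  mixed <- rbind(matrix(0, 4, 3),
                 matrix(255, 4, 3),
                 matrix(c(255, 0, 0), 1, 3))
  expect_equal(species_lightness(mixed), (0 * 4 + 100 * 4 + 50) / 9)
  # permuting pixels does not change the species value
  set.seed(1)
  expect_equal(species_lightness(mixed[sample(9), ]), species_lightness(mixed))
  expect_warning(species_lightness(matrix(128, 5, 3)), "expected 9")
  expect_error(species_lightness(matrix(numeric(0), 0, 3)), "empty")
})

test_that("lightness extraction from PNG images reproduces pixel values", {
  dir <- withr::local_tempdir()
  img <- array(0, dim = c(4, 4, 3))
  img[1, 1, ] <- 1                  # white -> 100
  img[2, 3, ] <- c(1, 0, 0)         # red   -> 50
  img[3, 2, ] <- 128 / 255          # grey  -> 50.19608
  png::writePNG(img, file.path(dir, "shroom.png"))
  px <- data.frame(species_id = "spX", image_file = "shroom.png",
                   row = c(1, 2, 3), col = c(1, 3, 2))
  expect_warning(out <- extract_species_lightness(px, dir), "differs from 9")
  expect_equal(out$lightness_pct,
               mean(c(100, 50, 128 / 255 * 100)), tolerance = 1e-10)
  expect_equal(out$n_pixels, 3L)
  px_bad <- transform(px, row = 99)
  expect_error(suppressWarnings(extract_species_lightness(px_bad, dir)),
               "outside image")
})

test_that("toughness coding follows the order and fruit-body-type rules", {
  expect_equal(code_toughness("Basidiomycota", "pileate-sessile", "Polyporales"), "tough")
  expect_equal(code_toughness("Basidiomycota", "pileate-sessile", "Gloeophyllales"), "tough")
  expect_equal(code_toughness("Basidiomycota", "pileate-sessile", "Hymenochaetales"), "tough")
  expect_equal(code_toughness("Basidiomycota", "pileate-stipitate", "Agaricales"), "soft")
  expect_equal(code_toughness("Ascomycota", "perithecia"), "tough")
  expect_equal(code_toughness("Ascomycota", "apothecia"), "soft")
  expect_warning(out <- code_toughness("Basidiomycota", "pileate-stipitate", "Russulales"),
                 "Russulales")
  expect_true(is.na(out))
  expect_error(code_toughness("Zygomycota", "perithecia"), "unknown lineage")
})

test_that("toughness coding is idempotent on a generated pool", {
  pool <- generate_species_pool(small_cfg(), seed = 5)
  recoded <- code_toughness(pool$lineage, pool$fb_type, pool$taxon_order)
  expect_equal(recoded, pool$toughness)
})

test_that("the shipped example trait CSV builds cleanly", {
  f <- system.file("extdata", "example_traits.csv", package = "mycotraits")
  tr <- build_trait_table(f)
  expect_equal(nrow(tr), 12)
  expect_equal(tr$size_mm[tr$species_id == "Fomes_fomentarius"], 275)
  expect_equal(tr$toughness[tr$species_id == "Xylaria_hypoxylon"], "tough")
  expect_equal(tr$toughness[tr$species_id == "Mycena_galericulata"], "soft")
  # pre-supplied expert call for an order outside the rule, no warning
  expect_equal(tr$toughness[tr$species_id == "Stereum_hirsutum"], "tough")
})

test_that("trait-table assembly validates, derives size, and applies overrides", {
  tr <- data.frame(species_id = c("a", "b", "c"),
                   lineage = c("Basidiomycota", "Basidiomycota", "Ascomycota"),
                   fb_type = c("pileate-stipitate", "pileate-sessile", "apothecia"),
                   taxon_order = c("Agaricales", "Russulales", NA),
                   size_min_mm = c(20, 10, NA), size_max_mm = c(60, 30, NA),
                   stringsAsFactors = FALSE)
  out <- suppressWarnings(build_trait_table(tr))
  expect_equal(out$size_mm, c(40, 20, NA))
  expect_equal(out$toughness, c("soft", NA, "soft"))
  # unresolved order fixed by an explicit override
  out2 <- suppressWarnings(
    build_trait_table(tr, overrides = data.frame(species_id = "b", toughness = "tough")))
  expect_equal(out2$toughness, c("soft", "tough", "soft"))
  # lightness fill from an extraction table
  out3 <- suppressWarnings(
    build_trait_table(tr, lightness = data.frame(species_id = "a", lightness_pct = 62.5)))
  expect_equal(out3$lightness_pct, c(62.5, NA, NA))
  bad <- tr
  bad$fb_type[3] <- "pileate-sessile"
  expect_error(build_trait_table(bad), "inconsistent with lineage")
  bad2 <- tr
  bad2$lightness_pct <- c(120, 50, 50)
  expect_error(suppressWarnings(build_trait_table(bad2)), "\\[0, 100\\]")
})
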