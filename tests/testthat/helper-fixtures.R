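# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(build)
  }
  .fixture_cache[[name]]
}

# Default synthetic field: 5 treatments x 3 plots x 14 plants = 210 plants.
default_truth <- function() {
  fixture("truth", generate_truth(3, 14, seed = 42))
}

default_layout <- function() {
  fixture("layout", field_layout(default_truth()))
}

default_scene <- function() {
  fixture("scene", render_scene(default_layout(), default_truth(), seed = 7))
}

# A soil-only layout: valid plot rectangles, no plants.
soil_layout <- function(h = 40, w = 40) {
  structure(list(
    plots = data.frame(plot_id = "N0_rep1", treatment = "N0",
                       r0 = 5, c0 = 5, r1 = 20, c1 = 20),
    plants = data.frame(plant_id = character(), plot_id = character(),
                        row = integer(), col = integer()),
    dim = c(h, w), plant_radius_px = 4), class = "field_layout")
}

mask_f1 <- function(pred, truth) {
  tp <- sum(pred & truth)
  2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
}
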