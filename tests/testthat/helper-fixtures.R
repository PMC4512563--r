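## Shared heavyweight fixtures, built once per test run on first use.
.fx <- new.env(parent = emptyenv())

fixture_params <- function(seed = 7L) synth_params(seed = seed)

fixture_slide <- function() {
  if (is.null(.fx$slide)) .fx$slide <- generate_slide(fixture_params())
  .fx$slide
}

fixture_classifier <- function() {
  if (is.null(.fx$clf))
    .fx$clf <- train_synthetic_classifier(params = fixture_params(),
                                          working_downsample = 2L, seed = 42L)
  .fx$clf
}

## full pipeline run on the fixture slide, hemorrhage exclusion enabled
fixture_hotspots <- function() {
  if (is.null(.fx$hs)) {
    p <- fixture_params()
    .fx$hs <- find_hotspots(fixture_slide()$image,
                            fov_width = p$fov[2], fov_height = p$fov[1],
                            working_downsample = p$working_downsample,
                            n = 20L, rho = 0.2,
                            classifier = fixture_classifier(),
                            opening_radius = 100L, stride = 2L, block = 16L)
  }
  .fx$hs
}

fixture_score <- function() {
  if (is.null(.fx$score))
    .fx$score <- score_slide(fixture_hotspots()$selection, fixture_slide()$image)
  .fx$score
}

## small fast slide for CLI-level tests (single section, no hemorrhage)
fixture_small_params <- function(seed = 3L)
  synth_params(slide_size = c(800L, 800L), tissue_blob_count = 1L,
               tissue_radius = c(300, 340), hotspot_count = 2L,
               hotspot_radius = 80, hemorrhage_count = 0L, seed = seed)

## ground-truth tissue mask reduced to working resolution
truth_mask_working <- function(truth, ds)
  ki67hotspot:::block_reduce(truth$tissue_mask * 1, ds) > 0.5
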