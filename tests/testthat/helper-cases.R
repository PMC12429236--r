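# small-grid phantom parameters for fast unit tests
small_params <- function(seed = 1L, ...) {
  args <- list(grid_shape = c(6L, 64L, 64L),
               spacing_mm = c(8, 1.5, 1.5),
               lv_center_range = list(row = c(26, 38), col = c(26, 38)),
               endo_radius_mm = c(8, 12),
               epi_radius_mm = c(15, 19),
               seed = seed)
  do.call(phantom_params, utils::modifyList(args, list(...)))
}

# noise-free phantom whose scar sits a known number of nominal remote-SDs
# above the remote mean (for threshold-recovery oracles)
noisefree_params <- function(sd_nominal = 25, k_scar = 5.5, seed = 1L) {
  phantom_params(grid_shape = c(6L, 64L, 64L),
                 spacing_mm = c(8, 1.5, 1.5),
                 lv_center_range = list(row = c(30, 34), col = c(30, 34)),
                 endo_radius_mm = c(8, 12),
                 epi_radius_mm = c(15, 19),
                 scar_probability = 1,
                 mvo_probability_given_scar = 0,
                 intensity_means = c(background = 50, blood = 320,
                                     myocardium = 200,
                                     scar = 200 + k_scar * sd_nominal,
                                     mvo = 170),
                 noise_sd = 0, seed = seed)
}
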